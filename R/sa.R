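# Shuffle attention: the input (C, H, W) map is split into G groups; each
# group is halved along channels into a channel-attention branch (global
# average pooling -> per-channel sigmoid gate) and a spatial-attention branch
# (group norm -> per-channel affine -> sigmoid gate); branch outputs are
# concatenated, groups are re-assembled, and a channel shuffle interleaves
# channels across groups. Gates multiply the input, so the block preserves
# shape and never amplifies activations.

sigmoid <- function(x) 1 / (1 + exp(-x))

#' Split a feature map into attention groups and branch halves
#'
#' @param f Feature map array, dim `c(C, H, W)` with `C` divisible by `2 G`.
#' @param G Number of groups.
#' @return List of `G` groups, each a list with branch halves `f1`, `f2`
#'   (dim `c(C/(2G), H, W)`); concatenating all halves in order reconstructs
#'   the input exactly.
#' @export
split_groups <- function(f, G) {
  C <- dim(f)[1]
  if (C %% (2 * G) != 0)
    stop(sprintf("channel count %d not divisible by 2*G = %d", C, 2 * G))
  per <- C %/% G
  half <- per %/% 2
  lapply(seq_len(G), function(g) {
    base <- (g - 1) * per
    list(f1 = f[base + seq_len(half), , , drop = FALSE],
         f2 = f[base + half + seq_len(half), , , drop = FALSE])
  })
}

#' Global average pooling
#'
#' Spatial mean per channel: the channel statistic feeding the channel gate.
#'
#' @param f Feature map, dim `c(C, H, W)`.
#' @return Numeric vector of length `C`.
#' @export
global_avg_pool <- function(f) {
  apply(f, 1, mean)
}

#' Channel-attention branch
#'
#' Gates each channel by `sigmoid(W1 * c + b1)` where `c` is the channel's
#' global average; the gate is broadcast over space and multiplies the input.
#'
#' @param f Branch map, dim `c(C', H, W)`.
#' @param W1,b1 Per-channel scale and shift (length `C'`).
#' @return Gated map, same shape.
#' @export
channel_attention <- function(f, W1, b1) {
  C <- dim(f)[1]
  if (length(W1) != C || length(b1) != C) stop("gate parameter length mismatch")
  gate <- sigmoid(W1 * global_avg_pool(f) + b1)
  f * gate  # gate recycles along the fastest (channel) dimension
}

#' Spatial-attention branch
#'
#' Normalizes the branch with group normalization (all branch channels as a
#' single normalization group, over space), applies a per-channel affine and
#' sigmoid gate, and multiplies the input:
#' `sigmoid(W2 * GN(f) + b2) * f`.
#'
#' @param f Branch map, dim `c(C', H, W)`.
#' @param W2,b2 Per-channel scale and shift (length `C'`).
#' @param gn Group-norm parameters: list with `gamma`, `beta` (length `C'`)
#'   and `eps` (default 1e-5).
#' @return Gated map, same shape.
#' @export
spatial_attention <- function(f, W2, b2, gn = list(gamma = rep(1, dim(f)[1]),
                                                   beta = rep(0, dim(f)[1]),
                                                   eps = 1e-5)) {
  C <- dim(f)[1]
  if (length(W2) != C || length(b2) != C) stop("gate parameter length mismatch")
  mu <- mean(f)
  va <- mean((f - mu)^2)
  t <- (f - mu) / sqrt(va + gn$eps)
  u <- t * gn$gamma + gn$beta
  gate <- sigmoid(u * W2 + b2)
  f * gate
}

#' Channel shuffle
#'
#' Reindexes channels by reshaping to (G, C/G), transposing and flattening —
#' a fixed permutation that interleaves channels across groups so information
#' flows between them. A pure permutation: the multiset of channel slices is
#' preserved.
#'
#' @param f Feature map, dim `c(C, H, W)` with `C` divisible by `G`.
#' @param G Number of groups.
#' @return Shuffled map, same shape.
#' @export
channel_shuffle <- function(f, G) {
  C <- dim(f)[1]
  if (C %% G != 0) stop(sprintf("channel count %d not divisible by G = %d", C, G))
  perm <- channel_shuffle_perm(C, G)
  f[perm, , , drop = FALSE]
}

channel_shuffle_perm <- function(C, G) {
  as.vector(matrix(seq_len(C), nrow = G, byrow = TRUE))
}

#' Initialize shuffle-attention parameters
#'
#' Gate weights start at zero and gate biases at one — the reference
#' shuffle-attention initialization — so every gate opens at
#' `sigmoid(1) = 0.731`: the block initially scales all activations by a
#' uniform constant close to identity and never reshapes an untrained
#' network's features asymmetrically (nor unduly attenuates gradients
#' flowing through it). Group-norm affine starts at identity (`gamma = 1`,
#' `beta = 0`).
#'
#' @param C Channel count entering the block (divisible by `2 G`).
#' @param G Number of groups; default 8.
#' @param eps Group-norm epsilon; default 1e-5.
#' @return List of class `sa_params` with one parameter set per group.
#' @export
sa_params <- function(C, G = 8, eps = 1e-5) {
  if (C %% (2 * G) != 0)
    stop(sprintf("channel count %d not divisible by 2*G = %d", C, 2 * G))
  half <- C %/% (2 * G)
  groups <- lapply(seq_len(G), function(g) {
    list(W1 = rep(0, half), b1 = rep(1, half),
         W2 = rep(0, half), b2 = rep(1, half),
         gamma = rep(1, half), beta = rep(0, half))
  })
  structure(list(groups = groups, G = G, C = C, eps = eps), class = "sa_params")
}

sa_param_count <- function(params) {
  sum(vapply(params$groups, function(g) length(unlist(g)), numeric(1)))
}

#' Shuffle-attention forward pass
#'
#' @param f Feature map, dim `c(C, H, W)`.
#' @param G Number of groups.
#' @param params An [sa_params()] object for `(C, G)`.
#' @return Feature map of identical shape.
#' @export
shuffle_attention_forward <- function(f, G, params = sa_params(dim(f)[1], G)) {
  out <- array(0, dim = dim(f))
  per <- dim(f)[1] %/% G
  half <- per %/% 2
  groups <- split_groups(f, G)
  for (g in seq_len(G)) {
    p <- params$groups[[g]]
    y1 <- channel_attention(groups[[g]]$f1, p$W1, p$b1)
    y2 <- spatial_attention(groups[[g]]$f2, p$W2, p$b2,
                            gn = list(gamma = p$gamma, beta = p$beta, eps = params$eps))
    base <- (g - 1) * per
    out[base + seq_len(half), , ] <- y1
    out[base + half + seq_len(half), , ] <- y2
  }
  channel_shuffle(out, G)
}

# Forward with caches for backprop (used by the network graph).
sa_forward_train <- function(f, params) {
  G <- params$G
  per <- dim(f)[1] %/% G
  half <- per %/% 2
  out <- array(0, dim = dim(f))
  caches <- vector("list", G)
  HW <- prod(dim(f)[2:3])
  for (g in seq_len(G)) {
    p <- params$groups[[g]]
    base <- (g - 1) * per
    x1 <- f[base + seq_len(half), , , drop = FALSE]
    x2 <- f[base + half + seq_len(half), , , drop = FALSE]
    # channel branch
    cstat <- global_avg_pool(x1)
    g1 <- sigmoid(p$W1 * cstat + p$b1)
    y1 <- x1 * g1
    # spatial branch
    mu <- mean(x2); va <- mean((x2 - mu)^2)
    inv_sd <- 1 / sqrt(va + params$eps)
    t2 <- (x2 - mu) * inv_sd
    u2 <- t2 * p$gamma + p$beta
    g2 <- sigmoid(u2 * p$W2 + p$b2)
    y2 <- x2 * g2
    out[base + seq_len(half), , ] <- y1
    out[base + half + seq_len(half), , ] <- y2
    caches[[g]] <- list(x1 = x1, cstat = cstat, g1 = g1,
                        x2 = x2, t2 = t2, u2 = u2, g2 = g2,
                        inv_sd = inv_sd, HW = HW)
  }
  perm <- channel_shuffle_perm(dim(f)[1], G)
  list(out = out[perm, , , drop = FALSE], caches = caches, perm = perm)
}

sa_backward <- function(dout, params, cache) {
  G <- params$G
  C <- dim(dout)[1]
  per <- C %/% G
  half <- per %/% 2
  inv <- integer(C); inv[cache$perm] <- seq_len(C)
  d <- dout[inv, , , drop = FALSE]
  dx <- array(0, dim = dim(dout))
  grads <- vector("list", G)
  for (g in seq_len(G)) {
    p <- params$groups[[g]]
    cc <- cache$caches[[g]]
    base <- (g - 1) * per
    dy1 <- d[base + seq_len(half), , , drop = FALSE]
    dy2 <- d[base + half + seq_len(half), , , drop = FALSE]
    # channel branch
    dgate1 <- apply(dy1 * cc$x1, 1, sum)
    dz1 <- cc$g1 * (1 - cc$g1) * dgate1
    dW1 <- dz1 * cc$cstat
    db1 <- dz1
    dc <- p$W1 * dz1
    dx1 <- dy1 * cc$g1 + array(rep(dc / cc$HW, cc$HW), dim = dim(dy1))
    # spatial branch
    dg2 <- dy2 * cc$x2
    dz2 <- cc$g2 * (1 - cc$g2) * dg2
    dW2 <- apply(dz2 * cc$u2, 1, sum)
    db2 <- apply(dz2, 1, sum)
    du <- dz2 * p$W2
    dgamma <- apply(du * cc$t2, 1, sum)
    dbeta <- apply(du, 1, sum)
    dt <- du * p$gamma
    # group-norm backward over the whole branch (one normalization group)
    m_dt <- mean(dt)
    m_dtt <- mean(dt * cc$t2)
    dx2 <- dy2 * cc$g2 + cc$inv_sd * (dt - m_dt - cc$t2 * m_dtt)
    dx[base + seq_len(half), , ] <- dx1
    dx[base + half + seq_len(half), , ] <- dx2
    grads[[g]] <- list(W1 = dW1, b1 = db1, W2 = dW2, b2 = db2,
                       gamma = dgamma, beta = dbeta)
  }
  list(dx = dx, grads = grads)
}
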