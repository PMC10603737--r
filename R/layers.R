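# A small static-graph engine for the detector. Feature maps are (C, H, W)
# arrays (channel fastest). Each node is a named operation with parameter
# environments; forward passes record per-node caches, and backward passes
# walk the graph in reverse, accumulating input gradients and parameter
# gradients. This is deliberately minimal: the graph is fixed at build time
# and every backward rule is written out by hand.

silu <- function(x) x * sigmoid(x)

silu_grad <- function(x) {
  s <- sigmoid(x)
  s * (1 + x * (1 - s))
}

new_param <- function(value) {
  e <- new.env(parent = emptyenv())
  e$value <- value
  e$grad <- value * 0
  e$mom <- value * 0
  e
}

# Per-channel spatial moments of a (C, H, W) array via a C x HW matrix view.
channel_mat <- function(x) {
  d <- dim(x)
  matrix(x, nrow = d[1])
}

# conv node: conv2d [+ per-channel normalization] [+ SiLU].
# Normalization uses the sample's own per-channel spatial statistics at both
# training and inference (instance normalization): training already relies on
# per-sample statistics for batch-size-independent gradient accumulation, so
# inference uses the identical transform rather than a running estimate —
# the network is evaluated exactly as it was trained.
make_conv <- function(cin, cout, k, stride, pad, norm = TRUE, act = TRUE,
                      bias = !norm) {
  fan_in <- cin * k * k
  W <- matrix(stats::rnorm(cout * fan_in, sd = sqrt(2 / fan_in)), cout, fan_in)
  layer <- new.env(parent = emptyenv())
  layer$W <- new_param(W)
  layer$bias <- if (bias) new_param(rep(0, cout)) else NULL
  if (norm) {
    layer$gamma <- new_param(rep(1, cout))
    layer$beta <- new_param(rep(0, cout))
  }
  layer$cfg <- list(cin = cin, cout = cout, k = k, stride = stride, pad = pad,
                    norm = norm, act = act, bias = bias, eps = 1e-5)
  layer
}

conv_node_forward <- function(layer, x, training) {
  cfg <- layer$cfg
  d <- dim(x)
  b <- if (cfg$bias) layer$bias$value else rep(0, cfg$cout)
  z <- conv2d_fw(x, d[1], d[2], d[3], layer$W$value, b,
                 cfg$k, cfg$k, cfg$stride, cfg$pad)
  cache <- list(x = x, xdim = d)
  if (cfg$norm) {
    zm <- channel_mat(z)
    mu <- rowMeans(zm)
    va <- rowMeans(zm^2) - mu^2
    inv_sd <- 1 / sqrt(va + cfg$eps)
    zhat <- (zm - mu) * inv_sd
    pre <- zhat * layer$gamma$value + layer$beta$value
    cache$zhat <- zhat
    cache$inv_sd <- inv_sd
    pre_arr <- array(pre, dim = dim(z))
  } else {
    pre_arr <- z
  }
  cache$pre <- pre_arr
  out <- if (cfg$act) silu(pre_arr) else pre_arr
  list(out = out, cache = cache)
}

conv_node_backward <- function(layer, cache, dout) {
  cfg <- layer$cfg
  dpre <- if (cfg$act) dout * silu_grad(cache$pre) else dout
  if (cfg$norm) {
    dpre_m <- channel_mat(dpre)
    dgamma <- rowSums(dpre_m * cache$zhat)
    dbeta <- rowSums(dpre_m)
    layer$gamma$grad <- layer$gamma$grad + dgamma
    layer$beta$grad <- layer$beta$grad + dbeta
    dzh <- dpre_m * layer$gamma$value
    # per-channel normalization backward (statistics over space)
    m1 <- rowMeans(dzh)
    m2 <- rowMeans(dzh * cache$zhat)
    dz <- (dzh - m1 - cache$zhat * m2) * cache$inv_sd
    dz <- array(dz, dim = dim(dpre))
  } else {
    dz <- dpre
  }
  d <- cache$xdim
  bw <- conv2d_bw(cache$x, d[1], d[2], d[3], layer$W$value, dz,
                  cfg$k, cfg$k, cfg$stride, cfg$pad)
  layer$W$grad <- layer$W$grad + bw$dW
  if (cfg$bias) layer$bias$grad <- layer$bias$grad + bw$db
  bw$dx
}

upsample2_forward <- function(x) {
  d <- dim(x)
  x[, rep(seq_len(d[2]), each = 2), rep(seq_len(d[3]), each = 2), drop = FALSE]
}

upsample2_backward <- function(dout) {
  d <- dim(dout)
  h2 <- d[2] %/% 2; w2 <- d[3] %/% 2
  a <- dout[, seq(1, d[2], 2), , drop = FALSE] + dout[, seq(2, d[2], 2), , drop = FALSE]
  a[, , seq(1, d[3], 2), drop = FALSE] + a[, , seq(2, d[3], 2), drop = FALSE]
}

# ---- graph construction -------------------------------------------------

graph_builder <- function() {
  gb <- new.env(parent = emptyenv())
  gb$nodes <- list()
  gb$add <- function(id, op, inputs, layer = NULL, extra = NULL) {
    gb$nodes[[id]] <- list(id = id, op = op, inputs = inputs,
                           layer = layer, extra = extra)
    id
  }
  gb
}

add_c3 <- function(gb, id, input, cin, cout, n = 1, shortcut = TRUE) {
  hidden <- max(2, cout %/% 2)
  a <- gb$add(paste0(id, "_cv1"), "conv", input,
              make_conv(cin, hidden, 1, 1, 0))
  prev <- a
  for (i in seq_len(n)) {
    m1 <- gb$add(paste0(id, "_m", i, "a"), "conv", prev,
                 make_conv(hidden, hidden, 1, 1, 0))
    m2 <- gb$add(paste0(id, "_m", i, "b"), "conv", m1,
                 make_conv(hidden, hidden, 3, 1, 1))
    prev <- if (shortcut) gb$add(paste0(id, "_m", i, "add"), "add", c(prev, m2))
            else m2
  }
  b <- gb$add(paste0(id, "_cv2"), "conv", input,
              make_conv(cin, hidden, 1, 1, 0))
  cat_id <- gb$add(paste0(id, "_cat"), "cat", c(prev, b))
  gb$add(paste0(id, "_cv3"), "conv", cat_id,
         make_conv(2 * hidden, cout, 1, 1, 0))
}

add_sppf <- function(gb, id, input, c_io) {
  hidden <- c_io %/% 2
  cv1 <- gb$add(paste0(id, "_cv1"), "conv", input, make_conv(c_io, hidden, 1, 1, 0))
  p1 <- gb$add(paste0(id, "_p1"), "maxpool", cv1, extra = list(k = 5, stride = 1, pad = 2))
  p2 <- gb$add(paste0(id, "_p2"), "maxpool", p1, extra = list(k = 5, stride = 1, pad = 2))
  p3 <- gb$add(paste0(id, "_p3"), "maxpool", p2, extra = list(k = 5, stride = 1, pad = 2))
  cat_id <- gb$add(paste0(id, "_cat"), "cat", c(cv1, p1, p2, p3))
  gb$add(paste0(id, "_cv2"), "conv", cat_id, make_conv(4 * hidden, c_io, 1, 1, 0))
}

# ---- graph execution ----------------------------------------------------

forward_graph <- function(nodes, input, training = FALSE, outputs) {
  vals <- list(.input = input)
  caches <- list()
  for (node in nodes) {
    ins <- lapply(node$inputs, function(i) vals[[i]])
    res <- switch(node$op,
      conv = conv_node_forward(node$layer, ins[[1]], training),
      add = list(out = ins[[1]] + ins[[2]], cache = NULL),
      cat = {
        chans <- vapply(ins, function(v) dim(v)[1], numeric(1))
        d <- dim(ins[[1]])
        out <- array(0, dim = c(sum(chans), d[2], d[3]))
        at <- 0
        for (v in ins) {
          out[at + seq_len(dim(v)[1]), , ] <- v
          at <- at + dim(v)[1]
        }
        list(out = out, cache = chans)
      },
      maxpool = {
        d <- dim(ins[[1]])
        mp <- maxpool_fw(ins[[1]], d[1], d[2], d[3],
                         node$extra$k, node$extra$stride, node$extra$pad)
        list(out = mp$out, cache = list(argmax = mp$argmax, xdim = d))
      },
      upsample = list(out = upsample2_forward(ins[[1]]), cache = NULL),
      sa = {
        if (training) {
          r <- sa_forward_train(ins[[1]], node$layer$params$value)
          list(out = r$out, cache = r)
        } else {
          p <- node$layer$params$value
          list(out = shuffle_attention_forward(ins[[1]], p$G, p), cache = NULL)
        }
      },
      stop(sprintf("unknown op %s", node$op))
    )
    vals[[node$id]] <- res$out
    caches[[node$id]] <- res$cache
  }
  list(values = vals[outputs], caches = caches, all_values = vals)
}

backward_graph <- function(nodes, caches, douts) {
  grads <- douts  # named list: node id -> gradient w.r.t. its output
  for (node in rev(nodes)) {
    g <- grads[[node$id]]
    if (is.null(g)) next
    dins <- switch(node$op,
      conv = list(conv_node_backward(node$layer, caches[[node$id]], g)),
      add = list(g, g),
      cat = {
        chans <- caches[[node$id]]
        at <- 0
        out <- vector("list", length(chans))
        for (i in seq_along(chans)) {
          out[[i]] <- g[at + seq_len(chans[i]), , , drop = FALSE]
          at <- at + chans[i]
        }
        out
      },
      maxpool = {
        cc <- caches[[node$id]]
        list(maxpool_bw(cc$argmax, g, cc$xdim[1], cc$xdim[2], cc$xdim[3]))
      },
      upsample = list(upsample2_backward(g)),
      sa = {
        cc <- caches[[node$id]]
        r <- sa_backward(g, node$layer$params$value, cc)
        pg <- node$layer$params$grad
        for (k in seq_along(pg$groups)) {
          for (nm in names(pg$groups[[k]])) {
            pg$groups[[k]][[nm]] <- pg$groups[[k]][[nm]] + r$grads[[k]][[nm]]
          }
        }
        node$layer$params$grad <- pg
        list(r$dx)
      }
    )
    for (i in seq_along(node$inputs)) {
      key <- node$inputs[i]
      if (key == ".input") next
      grads[[key]] <- if (is.null(grads[[key]])) dins[[i]] else grads[[key]] + dins[[i]]
    }
  }
  invisible(NULL)
}

# Collect parameter environments of a node list (for the optimizer).
collect_params <- function(nodes) {
  out <- list()
  for (node in nodes) {
    if (is.null(node$layer)) next
    for (nm in c("W", "bias", "gamma", "beta", "params")) {
      p <- node$layer[[nm]]
      if (!is.null(p)) out[[paste(node$id, nm, sep = ".")]] <- p
    }
  }
  out
}

zero_grads <- function(params) {
  for (p in params) {
    if (is.list(p$grad) && !is.null(p$grad$groups)) {
      for (k in seq_along(p$grad$groups))
        p$grad$groups[[k]] <- lapply(p$grad$groups[[k]], function(v) v * 0)
    } else {
      p$grad <- p$grad * 0
    }
  }
  invisible(NULL)
}

n_param_values <- function(params) {
  sum(vapply(params, function(p) {
    if (is.list(p$value) && !is.null(p$value$groups))
      sa_param_count(p$value)
    else length(p$value)
  }, numeric(1)))
}
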