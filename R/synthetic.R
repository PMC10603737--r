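# Synthetic pen scenes: shaded elliptical animal bodies over a textured
# ground, with exact axis-aligned ground-truth boxes taken from each
# ellipse's own rasterized mask (amodal: overpainting by a later animal does
# not shrink a label). These scenes emulate the statistical shape of crowded
# finishing-pen footage — many similar-sized, overlapping, arbitrarily
# oriented bodies on a low-contrast floor — not its photographic appearance.

#' Scene generator configuration
#'
#' Defaults emulate crowded pen footage: around 15 animals per frame
#' (truncated Poisson, clamped to 5-25), body length roughly 12-22% of the
#' frame side, 2:1 elongation, moderate allowed occlusion, and two
#' camera-angle background styles with illumination jitter.
#'
#' @param image_size Side length in pixels; default 320.
#' @param count_mean Mean animal count; default 15.
#' @param count_range Inclusive truncation range; default `c(5, 25)`.
#' @param size_range Major half-axis as a fraction of the side; default
#'   `c(0.06, 0.11)`.
#' @param aspect_range Minor/major axis ratio; default `c(0.45, 0.65)`.
#' @param orientation_range Body orientation in radians; default `c(0, pi)`.
#' @param max_occlusion Maximum fraction of a new body allowed to overlap
#'   already placed ones; default 0.4.
#' @param style Background preset: `"overhead"` (textured concrete) or
#'   `"oblique"` (striped floor with a vertical light gradient).
#' @param illum_jitter Relative global illumination jitter; default 0.25.
#' @return List of class `scene_config`.
#' @export
scene_config <- function(image_size = 320, count_mean = 15,
                         count_range = c(5, 25),
                         size_range = c(0.06, 0.11),
                         aspect_range = c(0.45, 0.65),
                         orientation_range = c(0, pi),
                         max_occlusion = 0.4,
                         style = c("overhead", "oblique"),
                         illum_jitter = 0.25) {
  style <- match.arg(style)
  structure(list(image_size = image_size, count_mean = count_mean,
                 count_range = count_range, size_range = size_range,
                 aspect_range = aspect_range,
                 orientation_range = orientation_range,
                 max_occlusion = max_occlusion, style = style,
                 illum_jitter = illum_jitter),
            class = "scene_config")
}

# Value-noise background: a coarse random grid bilinearly upsampled.
render_background <- function(S, style, illum) {
  g <- 8
  coarse <- matrix(stats::runif(g * g, -1, 1), g, g)
  noise <- resize_bilinear(array(coarse, dim = c(g, g, 1)), S, S)[, , 1]
  base <- 0.32 + 0.05 * noise
  if (style == "oblique") {
    rows <- matrix((seq_len(S) - 1) / (S - 1), S, S)
    stripes <- 0.03 * sin(2 * pi * rows * 12)
    base <- base + stripes + 0.08 * (1 - rows)
  }
  base <- pmin(pmax(base * illum, 0), 1)
  img <- array(0, dim = c(S, S, 3))
  img[, , 1] <- base * 1.02
  img[, , 2] <- base
  img[, , 3] <- base * 0.96
  pmin(img, 1)
}

# Rasterize one ellipse on the pixel grid (pixel centres at (j-0.5, i-0.5)).
# Returns the lit-pixel index ranges and the local boolean mask.
rasterize_ellipse <- function(S, cx, cy, a, b, theta) {
  ex <- sqrt(a^2 * cos(theta)^2 + b^2 * sin(theta)^2)
  ey <- sqrt(a^2 * sin(theta)^2 + b^2 * cos(theta)^2)
  rows <- max(1, floor(cy - ey)):min(S, ceiling(cy + ey) + 1)
  cols <- max(1, floor(cx - ex)):min(S, ceiling(cx + ex) + 1)
  xs <- cols - 0.5; ys <- rows - 0.5
  X <- outer(rep(1, length(rows)), xs) - cx
  Y <- outer(ys, rep(1, length(cols))) - cy
  u <- (X * cos(theta) + Y * sin(theta)) / a
  v <- (-X * sin(theta) + Y * cos(theta)) / b
  r2 <- u^2 + v^2
  list(rows = rows, cols = cols, mask = r2 <= 1, r2 = r2, v = v)
}

#' Render one synthetic pen scene
#'
#' Places a seeded random number of shaded elliptical bodies over a textured
#' background, rejecting placements whose overlap with already placed bodies
#' exceeds the configured occlusion cap (bounded retries; if placement
#' becomes infeasible a degraded-density warning is raised and the scene is
#' emitted with fewer animals). Each label is the tight axis-aligned bounding
#' box of its own rendered ellipse mask, in normalized YOLO form.
#'
#' @param cfg A [scene_config()].
#' @param seed Integer seed; the same seed reproduces the scene bit-exactly.
#' @return Sample list: `image` (S x S x 3), `boxes` (normalized center
#'   annotations, class 0), `id`, and `meta` (ellipse parameters, achieved
#'   count, occlusion statistics).
#' @export
render_scene <- function(cfg, seed = 0L) {
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(seed)

  S <- cfg$image_size
  illum <- 1 + stats::runif(1, -cfg$illum_jitter, cfg$illum_jitter)
  img <- render_background(S, cfg$style, illum)

  n <- stats::rpois(1, cfg$count_mean)
  n <- min(max(n, cfg$count_range[1]), cfg$count_range[2])

  occupied <- matrix(FALSE, S, S)
  boxes <- matrix(numeric(0), 0, 4)
  ellipses <- list()
  occl <- numeric(0)
  placed <- 0
  for (i in seq_len(n)) {
    ok <- FALSE
    for (try in seq_len(30)) {
      a <- stats::runif(1, cfg$size_range[1], cfg$size_range[2]) * S
      b <- a * stats::runif(1, cfg$aspect_range[1], cfg$aspect_range[2])
      theta <- stats::runif(1, cfg$orientation_range[1], cfg$orientation_range[2])
      ex <- sqrt(a^2 * cos(theta)^2 + b^2 * sin(theta)^2)
      ey <- sqrt(a^2 * sin(theta)^2 + b^2 * cos(theta)^2)
      if (2 * ex + 2 >= S || 2 * ey + 2 >= S) next
      cx <- stats::runif(1, ex + 1, S - ex - 1)
      cy <- stats::runif(1, ey + 1, S - ey - 1)
      ras <- rasterize_ellipse(S, cx, cy, a, b, theta)
      if (!any(ras$mask)) next
      own <- sum(ras$mask)
      overlap <- sum(ras$mask & occupied[ras$rows, ras$cols])
      if (overlap / own > cfg$max_occlusion) next
      # shaded body: top-lit with edge falloff, slightly pink-gray
      base <- stats::runif(1, 0.55, 0.78)
      light <- 1 - 0.25 * ras$v * sign(cos(theta)) - 0.2 * ras$r2
      tint <- c(1.06, 0.97, 0.94)
      for (ch in 1:3) {
        plane <- img[ras$rows, ras$cols, ch]
        val <- pmin(pmax(base * light * tint[ch], 0), 1)
        plane[ras$mask] <- val[ras$mask]
        img[ras$rows, ras$cols, ch] <- plane
      }
      occupied[ras$rows, ras$cols] <- occupied[ras$rows, ras$cols] | ras$mask
      lit_rows <- ras$rows[apply(ras$mask, 1, any)]
      lit_cols <- ras$cols[apply(ras$mask, 2, any)]
      boxes <- rbind(boxes, c(min(lit_cols) - 1, min(lit_rows) - 1,
                              max(lit_cols), max(lit_rows)))
      ellipses[[length(ellipses) + 1]] <-
        list(cx = cx, cy = cy, a = a, b = b, theta = theta)
      occl <- c(occl, overlap / own)
      placed <- placed + 1
      ok <- TRUE
      break
    }
    if (!ok) {
      warning(sprintf("scene %d: placement infeasible after retries; density degraded to %d animals",
                      seed, placed))
      break
    }
  }

  list(image = img,
       boxes = corner_to_yolo(boxes, S, S, 0L),
       id = sprintf("scene_%06d", seed),
       meta = list(ellipses = ellipses, count = placed,
                   occlusion = occl, seed = seed, style = cfg$style))
}

#' Generate a synthetic detection dataset on disk
#'
#' Writes PNG images, YOLO-TXT labels and a YAML manifest with a train/test
#' split (default split ratio 86/14, mirroring a ~6:1 train:test farm-data
#' split). Every source of randomness derives from `seed` and the per-scene
#' seeds are recorded in the manifest.
#'
#' @param cfg A [scene_config()].
#' @param n_train,n_test Number of scenes per split (each >= 1).
#' @param out_dir Output directory (created; must be empty unless `force`).
#' @param seed Master seed.
#' @param force Overwrite a non-empty directory.
#' @return The manifest (invisibly also written to `manifest.yaml`).
#' @export
generate_dataset <- function(cfg, n_train, n_test, out_dir, seed = 0L,
                             force = FALSE) {
  stopifnot(n_train >= 1, n_test >= 1)
  if (dir.exists(out_dir) && length(list.files(out_dir)) > 0 && !force)
    stop("output directory exists and is not empty (use force = TRUE)")
  dir.create(file.path(out_dir, "images"), recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(out_dir, "labels"), recursive = TRUE, showWarnings = FALSE)

  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(seed)
  n <- n_train + n_test
  scene_seeds <- sample.int(2^31 - 2, n)

  stems <- character(n); counts <- integer(n)
  for (i in seq_len(n)) {
    sc <- render_scene(cfg, scene_seeds[i])
    stem <- sprintf("scene_%04d", i)
    save_image(sc$image, file.path(out_dir, "images", paste0(stem, ".png")))
    write_yolo_labels(sc$boxes, file.path(out_dir, "labels", paste0(stem, ".txt")))
    stems[i] <- stem; counts[i] <- nrow(sc$boxes)
  }
  manifest <- list(
    image_size = cfg$image_size, seed = seed, style = cfg$style,
    n_train = n_train, n_test = n_test,
    mean_count = mean(counts),
    train = as.list(stems[seq_len(n_train)]),
    test = as.list(stems[n_train + seq_len(n_test)]),
    scene_seeds = as.list(scene_seeds)
  )
  yaml::write_yaml(manifest, file.path(out_dir, "manifest.yaml"))
  invisible(manifest)
}

#' Read a dataset manifest
#' @param dir Dataset directory containing `manifest.yaml`.
#' @return Manifest list with `train`/`test` stems.
#' @export
read_manifest <- function(dir) {
  yaml::read_yaml(file.path(dir, "manifest.yaml"))
}

load_split <- function(dir, split = "train") {
  man <- read_manifest(dir)
  stems <- unlist(man[[split]])
  lapply(stems, function(stem) {
    list(image = load_image(file.path(dir, "images", paste0(stem, ".png"))),
         boxes = read_yolo_labels(file.path(dir, "labels", paste0(stem, ".txt"))),
         id = stem)
  })
}

#' Estimate anchor priors by k-means with IoU distance
#'
#' Lloyd iterations on box (w, h) pairs under the distance
#' `1 - IoU(box, anchor)` with boxes aligned at a common corner — the
#' standard way to pick detector anchor priors from training labels. Output
#' is `k * scales` anchors sorted by ascending area, ready to be split into
#' per-scale triplets (small boxes to the fine stride).
#'
#' @param wh n x 2 matrix (or data.frame with `w`, `h`) of box sizes in
#'   pixels; needs at least `k * scales` rows.
#' @param k Anchors per scale; default 3.
#' @param scales Number of detection scales; default 3.
#' @param seed Seed for the initialization.
#' @param iters Maximum Lloyd iterations; default 100.
#' @return `k * scales` x 2 matrix of (w, h) anchors, area-ascending.
#' @export
kmeans_anchors <- function(wh, k = 3, scales = 3, seed = 0L, iters = 100) {
  if (is.data.frame(wh)) wh <- cbind(wh$w, wh$h)
  wh <- as.matrix(wh)
  kk <- k * scales
  if (nrow(wh) < kk) stop(sprintf("need at least %d boxes for %d anchors", kk, kk))

  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(seed)

  iou_wh <- function(boxes, centers) {
    iw <- outer(boxes[, 1], centers[, 1], pmin)
    ih <- outer(boxes[, 2], centers[, 2], pmin)
    inter <- iw * ih
    uni <- outer(boxes[, 1] * boxes[, 2], centers[, 1] * centers[, 2], `+`) - inter
    inter / uni
  }

  centers <- wh[sample.int(nrow(wh), kk), , drop = FALSE]
  assign_prev <- rep(0L, nrow(wh))
  for (it in seq_len(iters)) {
    d <- 1 - iou_wh(wh, centers)
    assign_now <- max.col(-d, ties.method = "first")
    if (all(assign_now == assign_prev)) break
    assign_prev <- assign_now
    for (j in seq_len(kk)) {
      idx <- which(assign_now == j)
      if (length(idx) == 0) {
        centers[j, ] <- wh[sample.int(nrow(wh), 1), ]
      } else {
        centers[j, ] <- colMeans(wh[idx, , drop = FALSE])
      }
    }
  }
  centers <- centers[order(centers[, 1] * centers[, 2]), , drop = FALSE]
  dimnames(centers) <- list(NULL, c("w", "h"))
  centers
}
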