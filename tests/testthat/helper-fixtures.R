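# Shared fixtures: all built in code, seeded.

# Pixel-rasterization IoU oracle: count lit pixels on a canvas. Boxes are
# integer-coordinate, half-open, so a pixel (i, j) is inside iff
# x1 <= j-1 < x2 etc.
raster_iou <- function(a, b, canvas = 64) {
  grid_a <- matrix(FALSE, canvas, canvas)
  grid_b <- matrix(FALSE, canvas, canvas)
  fill <- function(g, bx) {
    if (bx[3] > bx[1] && bx[4] > bx[2])
      g[(bx[2] + 1):bx[4], (bx[1] + 1):bx[3]] <- TRUE
    g
  }
  grid_a <- fill(grid_a, a); grid_b <- fill(grid_b, b)
  inter <- sum(grid_a & grid_b); uni <- sum(grid_a | grid_b)
  if (uni == 0) 0 else inter / uni
}

random_int_box <- function(canvas = 64) {
  x <- sort(sample(0:canvas, 2)); y <- sort(sample(0:canvas, 2))
  c(x[1], y[1], x[2], y[2])
}

# Exhaustive threshold-enumeration AP oracle: for every distinct confidence
# cutoff compute (recall, precision), then integrate the running maximum of
# precision over each recall increment by brute force.
ap_oracle <- function(conf, tp, n_gt) {
  ord <- order(-conf)
  tp <- tp[ord]; conf <- conf[ord]
  cuts <- sort(unique(conf), decreasing = TRUE)
  pts <- t(vapply(cuts, function(th) {
    keep <- conf >= th
    tpk <- sum(tp[keep]); fpk <- sum(keep) - tpk
    c(r = tpk / n_gt, p = if (tpk + fpk > 0) tpk / (tpk + fpk) else 0)
  }, numeric(2)))
  pts <- pts[order(pts[, "r"]), , drop = FALSE]
  ap <- 0; r_prev <- 0
  for (i in seq_len(nrow(pts))) {
    p_max <- max(pts[i:nrow(pts), "p"])
    ap <- ap + (pts[i, "r"] - r_prev) * p_max
    r_prev <- pts[i, "r"]
  }
  ap
}

# Brute-force greedy NMS oracle (explicit loop, no shared code with nms()).
nms_oracle <- function(dets, thresh) {
  ord <- order(-dets$conf, seq_len(nrow(dets)))
  kept <- integer(0)
  for (i in ord) {
    ok <- TRUE
    for (j in kept) {
      if (box_iou(as.numeric(dets[i, c("x1", "y1", "x2", "y2")]),
                  as.numeric(dets[j, c("x1", "y1", "x2", "y2")])) > thresh) {
        ok <- FALSE; break
      }
    }
    if (ok) kept <- c(kept, i)
  }
  sort(kept)
}

# A quick synthetic sample at a small canvas for pipeline tests.
small_scene_cfg <- function(size = 128) {
  scene_config(image_size = size)
}

random_detections <- function(n, canvas = 50) {
  if (n == 0) return(detections_empty())
  x1 <- runif(n, 0, canvas - 10); y1 <- runif(n, 0, canvas - 10)
  w <- runif(n, 2, 15); h <- runif(n, 2, 15)
  data.frame(x1 = x1, y1 = y1, x2 = pmin(x1 + w, canvas),
             y2 = pmin(y1 + h, canvas),
             conf = round(runif(n), 3), class_id = 0L)
}

detections_empty <- function() {
  data.frame(x1 = numeric(), y1 = numeric(), x2 = numeric(), y2 = numeric(),
             conf = numeric(), class_id = integer())
}
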