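# Images are H x W x 3 arrays of doubles in [0, 1] (row-major, origin
# top-left). Annotations travel as data.frames in normalized center form
# (class_id, cx, cy, w, h in [0,1], relative to image width/height) — the
# YOLO-TXT convention — and are converted to pixel corner form at the
# geometry boundary.

#' Read a YOLO-TXT label file
#'
#' One object per non-empty line, whitespace-separated: `class cx cy w h`
#' with normalized center coordinates. A sixth column, when present, is read
#' as a detection confidence (the interchange format for detector output).
#'
#' @param path Label file path.
#' @return data.frame with columns `class_id, cx, cy, w, h` (and `conf` when
#'   present), rows in file order; zero rows for an empty file.
#' @export
read_yolo_labels <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  recs <- lapply(seq_along(lines), function(i) {
    parts <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    if (!length(parts) %in% c(5L, 6L))
      stop(sprintf("%s: line %d: expected 5 or 6 fields, got %d",
                   path, i, length(parts)))
    vals <- suppressWarnings(as.numeric(parts))
    if (any(is.na(vals)))
      stop(sprintf("%s: line %d: non-numeric field", path, i))
    vals
  })
  n6 <- any(vapply(recs, length, integer(1)) == 6L)
  out <- data.frame(
    class_id = vapply(recs, function(r) as.integer(r[1]), integer(1)),
    cx = vapply(recs, `[`, numeric(1), 2),
    cy = vapply(recs, `[`, numeric(1), 3),
    w = vapply(recs, `[`, numeric(1), 4),
    h = vapply(recs, `[`, numeric(1), 5)
  )
  if (n6) out$conf <- vapply(recs, function(r) if (length(r) == 6) r[6] else NA_real_, numeric(1))
  if (nrow(out) == 0) {
    out <- data.frame(class_id = integer(), cx = numeric(), cy = numeric(),
                      w = numeric(), h = numeric())
  }
  out
}

#' Write YOLO-TXT labels
#'
#' Canonical 6-decimal fixed-point formatting, newline-terminated, one object
#' per line; byte output is deterministic for a given input. Coordinates must
#' lie in the unit square with positive width/height.
#'
#' @param records data.frame with `class_id, cx, cy, w, h` (optional `conf`).
#' @param path Output path.
#' @export
write_yolo_labels <- function(records, path) {
  if (nrow(records) > 0) {
    coords <- as.matrix(records[, c("cx", "cy", "w", "h")])
    if (any(coords < 0) || any(coords > 1) ||
        any(records$w <= 0) || any(records$h <= 0))
      stop("normalized coordinates must lie in [0,1] with positive w, h")
  }
  fmt <- function(x) sprintf("%.6f", x)
  lines <- character(nrow(records))
  has_conf <- "conf" %in% names(records)
  for (i in seq_len(nrow(records))) {
    lines[i] <- paste(records$class_id[i], fmt(records$cx[i]), fmt(records$cy[i]),
                      fmt(records$w[i]), fmt(records$h[i]))
    if (has_conf) lines[i] <- paste(lines[i], fmt(records$conf[i]))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Convert normalized center annotations to pixel corner boxes
#'
#' @param records Annotation data.frame (`cx, cy, w, h` normalized).
#' @param width,height Image size in pixels.
#' @return n x 4 matrix of corner boxes in pixels.
#' @export
yolo_to_corner <- function(records, width, height) {
  if (nrow(records) == 0) return(matrix(numeric(0), 0, 4,
                                        dimnames = list(NULL, c("x1", "y1", "x2", "y2"))))
  m <- cbind(records$cx * width, records$cy * height,
             records$w * width, records$h * height)
  out <- box_convert(m, "corner")
  as_box_matrix(out)
}

#' Convert pixel corner boxes to normalized center annotations
#'
#' @param boxes n x 4 corner boxes in pixels.
#' @param width,height Image size in pixels.
#' @param class_id Class per box (recycled).
#' @return Annotation data.frame in normalized center form.
#' @export
corner_to_yolo <- function(boxes, width, height, class_id = 0L) {
  boxes <- as_box_matrix(boxes)
  if (nrow(boxes) == 0) return(data.frame(class_id = integer(), cx = numeric(),
                                          cy = numeric(), w = numeric(), h = numeric()))
  ctr <- as_box_matrix(box_convert(boxes, "center"))
  data.frame(class_id = as.integer(rep_len(class_id, nrow(boxes))),
             cx = ctr[, 1] / width, cy = ctr[, 2] / height,
             w = ctr[, 3] / width, h = ctr[, 4] / height)
}

#' Load an RGB image from PNG
#' @param path PNG file path.
#' @return H x W x 3 array in `[0, 1]`.
#' @export
load_image <- function(path) {
  img <- png::readPNG(path)
  if (length(dim(img)) == 2) img <- array(rep(img, 3), dim = c(dim(img), 3))
  img[, , 1:3, drop = FALSE]
}

#' Save an RGB image as PNG
#' @param image H x W x 3 array in `[0, 1]`.
#' @param path Output path.
#' @export
save_image <- function(image, path) {
  png::writePNG(pmin(pmax(image, 0), 1), path)
  invisible(path)
}

# Bilinear resampling to a new grid; sample positions are pixel centers,
# consistent with the half-open pixel convention used everywhere else.
resize_bilinear <- function(image, out_h, out_w) {
  in_h <- dim(image)[1]; in_w <- dim(image)[2]; nc <- dim(image)[3]
  sy <- in_h / out_h; sx <- in_w / out_w
  ys <- (seq_len(out_h) - 0.5) * sy - 0.5
  xs <- (seq_len(out_w) - 0.5) * sx - 0.5
  y0 <- pmin(pmax(floor(ys), 0), in_h - 1); y1 <- pmin(y0 + 1, in_h - 1)
  x0 <- pmin(pmax(floor(xs), 0), in_w - 1); x1 <- pmin(x0 + 1, in_w - 1)
  wy <- pmin(pmax(ys - y0, 0), 1); wx <- pmin(pmax(xs - x0, 0), 1)
  out <- array(0, dim = c(out_h, out_w, nc))
  for (ch in seq_len(nc)) {
    m <- image[, , ch]
    a <- m[y0 + 1, x0 + 1, drop = FALSE]; b <- m[y0 + 1, x1 + 1, drop = FALSE]
    cc <- m[y1 + 1, x0 + 1, drop = FALSE]; d <- m[y1 + 1, x1 + 1, drop = FALSE]
    top <- a * outer(rep(1, out_h), 1 - wx) + b * outer(rep(1, out_h), wx)
    bot <- cc * outer(rep(1, out_h), 1 - wx) + d * outer(rep(1, out_h), wx)
    out[, , ch] <- top * outer(1 - wy, rep(1, out_w)) + bot * outer(wy, rep(1, out_w))
  }
  out
}

#' Letterbox an image to a square network input
#'
#' Aspect-preserving bilinear resize followed by symmetric mid-gray padding
#' to `target x target`. Boxes are remapped through the same scale and offset,
#' so the geometric map is exactly invertible (see
#' [letterbox_invert_boxes()]).
#'
#' @param image H x W x 3 array.
#' @param boxes Annotation data.frame in normalized center form (relative to
#'   `image`); may have zero rows.
#' @param target Output side length in pixels; default 320.
#' @param pad_value Padding intensity; default 114/255.
#' @return List with `image` (target x target x 3), `boxes` (normalized to
#'   the letterboxed frame), and `info` (scale, pad_x, pad_y, orig_w, orig_h,
#'   target) for inversion.
#' @export
letterbox <- function(image, boxes = NULL, target = 320, pad_value = 114 / 255) {
  h <- dim(image)[1]; w <- dim(image)[2]
  scale <- min(target / w, target / h)
  new_w <- round(w * scale); new_h <- round(h * scale)
  resized <- resize_bilinear(image, new_h, new_w)
  pad_x <- (target - new_w) / 2; pad_y <- (target - new_h) / 2
  out <- array(pad_value, dim = c(target, target, dim(image)[3]))
  y_off <- floor(pad_y); x_off <- floor(pad_x)
  out[y_off + seq_len(new_h), x_off + seq_len(new_w), ] <- resized
  info <- list(scale = scale, pad_x = x_off, pad_y = y_off,
               orig_w = w, orig_h = h, target = target,
               new_w = new_w, new_h = new_h)
  new_boxes <- NULL
  if (!is.null(boxes)) {
    if (nrow(boxes) > 0) {
      px <- yolo_to_corner(boxes, w, h)
      px <- px * scale
      px[, c(1, 3)] <- px[, c(1, 3)] + x_off
      px[, c(2, 4)] <- px[, c(2, 4)] + y_off
      new_boxes <- corner_to_yolo(px, target, target, boxes$class_id)
    } else new_boxes <- boxes
  }
  list(image = out, boxes = new_boxes, info = info)
}

#' Invert the letterbox box mapping
#'
#' @param boxes Normalized center annotations in the letterboxed frame.
#' @param info The `info` element returned by [letterbox()].
#' @return Annotations normalized to the original image.
#' @export
letterbox_invert_boxes <- function(boxes, info) {
  if (nrow(boxes) == 0) return(boxes)
  px <- yolo_to_corner(boxes, info$target, info$target)
  px[, c(1, 3)] <- (px[, c(1, 3)] - info$pad_x) / info$scale
  px[, c(2, 4)] <- (px[, c(2, 4)] - info$pad_y) / info$scale
  corner_to_yolo(px, info$orig_w, info$orig_h, boxes$class_id)
}

hsv_to_rgb <- function(h, s, v) {
  h6 <- (h %% 1) * 6
  i <- floor(h6)
  f <- h6 - i
  p <- v * (1 - s); q <- v * (1 - s * f); t <- v * (1 - s * (1 - f))
  r <- ifelse(i == 0, v, ifelse(i == 1, q, ifelse(i == 2, p,
       ifelse(i == 3, p, ifelse(i == 4, t, v)))))
  g <- ifelse(i == 0, t, ifelse(i == 1, v, ifelse(i == 2, v,
       ifelse(i == 3, q, ifelse(i == 4, p, p)))))
  b <- ifelse(i == 0, p, ifelse(i == 1, p, ifelse(i == 2, t,
       ifelse(i == 3, v, ifelse(i == 4, v, q)))))
  list(r = r, g = g, b = b)
}

#' Augmentation configuration
#'
#' Magnitudes follow common detector-training practice: multiplicative
#' saturation/value jitter, a small additive hue shift, mirror flips, global
#' scale/translation, and 4-image mosaic composition. All are optional
#' switches.
#'
#' @param hsv Logical; HSV color jitter.
#' @param hsv_gains Hue/saturation/value gains; default `c(0.015, 0.7, 0.4)`.
#' @param flip Logical; random horizontal flip (probability `flip_prob`).
#' @param flip_prob Default 0.5.
#' @param affine Logical; random uniform scale and translation.
#' @param scale_gain Scale drawn from `[1 - g, 1 + g]`; default 0.5.
#' @param translate_frac Translation up to this fraction of the side; default 0.1.
#' @param mosaic Logical; 4-image mosaic (needs a `pool` of extra samples).
#' @param min_box_area Minimum surviving box area in px^2 after clipping;
#'   default 4.
#' @return List of class `augment_config`.
#' @export
augment_config <- function(hsv = TRUE, hsv_gains = c(0.015, 0.7, 0.4),
                           flip = TRUE, flip_prob = 0.5,
                           affine = TRUE, scale_gain = 0.5, translate_frac = 0.1,
                           mosaic = FALSE, min_box_area = 4) {
  structure(list(hsv = hsv, hsv_gains = hsv_gains, flip = flip,
                 flip_prob = flip_prob, affine = affine,
                 scale_gain = scale_gain, translate_frac = translate_frac,
                 mosaic = mosaic, min_box_area = min_box_area),
            class = "augment_config")
}

apply_hsv_jitter <- function(image, gains) {
  u <- stats::runif(3, -1, 1)
  h <- dim(image)[1]; w <- dim(image)[2]
  rgb <- matrix(c(image[, , 1], image[, , 2], image[, , 3]), nrow = 3, byrow = TRUE)
  hsv <- grDevices::rgb2hsv(rgb, maxColorValue = 1)
  hh <- (hsv[1, ] + u[1] * gains[1]) %% 1
  ss <- pmin(pmax(hsv[2, ] * (1 + u[2] * gains[2]), 0), 1)
  vv <- pmin(pmax(hsv[3, ] * (1 + u[3] * gains[3]), 0), 1)
  out <- hsv_to_rgb(hh, ss, vv)
  array(c(out$r, out$g, out$b), dim = c(h, w, 3))
}

# Nearest-neighbour inverse-mapped affine: output pixel centre (x, y) takes
# the source pixel containing ((x - tx) / s, (y - ty) / s).
apply_affine <- function(image, boxes_px, scale, tx, ty, pad_value = 114 / 255) {
  h <- dim(image)[1]; w <- dim(image)[2]
  xs <- ((seq_len(w) - 0.5) - tx) / scale
  ys <- ((seq_len(h) - 0.5) - ty) / scale
  xi <- floor(xs) + 1; yi <- floor(ys) + 1
  ok_x <- xi >= 1 & xi <= w; ok_y <- yi >= 1 & yi <= h
  out <- array(pad_value, dim = dim(image))
  if (any(ok_x) && any(ok_y)) {
    out[which(ok_y), which(ok_x), ] <- image[yi[ok_y], xi[ok_x], , drop = FALSE]
  }
  if (nrow(boxes_px) > 0) {
    boxes_px[, c(1, 3)] <- boxes_px[, c(1, 3)] * scale + tx
    boxes_px[, c(2, 4)] <- boxes_px[, c(2, 4)] * scale + ty
  }
  list(image = out, boxes = boxes_px)
}

clip_and_filter_boxes <- function(boxes_px, class_id, width, height, min_area) {
  if (nrow(boxes_px) == 0)
    return(list(boxes = boxes_px, class_id = class_id, dropped = 0L))
  clipped <- boxes_px
  clipped[, c(1, 3)] <- pmin(pmax(clipped[, c(1, 3)], 0), width)
  clipped[, c(2, 4)] <- pmin(pmax(clipped[, c(2, 4)], 0), height)
  area <- pmax(clipped[, 3] - clipped[, 1], 0) * pmax(clipped[, 4] - clipped[, 2], 0)
  keep <- area >= min_area
  list(boxes = clipped[keep, , drop = FALSE], class_id = class_id[keep],
       dropped = sum(!keep))
}

#' Augment a training sample
#'
#' Applies the enabled operations in a fixed order — mosaic (when a pool of
#' extra samples is supplied), HSV jitter, horizontal flip, scale/translate —
#' each drawing from a seeded RNG so the output is bit-identical under the
#' same seed. Boxes are remapped through every geometric op and clipped to
#' the frame; boxes falling below `min_box_area` are dropped and the count
#' recorded in the `dropped` attribute.
#'
#' @param sample List with `image` (H x W x 3) and `boxes` (normalized center
#'   annotations).
#' @param config An [augment_config()].
#' @param seed Integer seed.
#' @param pool Optional list of extra samples for the mosaic (3 are drawn).
#' @return Augmented sample (same structure), with attribute `dropped`.
#' @export
augment <- function(sample, config = augment_config(), seed = 0L, pool = NULL) {
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(seed)

  image <- sample$image
  h <- dim(image)[1]; w <- dim(image)[2]
  boxes_px <- yolo_to_corner(sample$boxes, w, h)
  class_id <- sample$boxes$class_id
  dropped <- 0L

  if (isTRUE(config$mosaic) && !is.null(pool) && length(pool) >= 3) {
    picks <- pool[sample.int(length(pool), 3)]
    tiles <- c(list(sample), picks)
    xc <- round(stats::runif(1, 0.25, 0.75) * w)
    yc <- round(stats::runif(1, 0.25, 0.75) * h)
    canvas <- array(114 / 255, dim = dim(image))
    all_boxes <- list(); all_cls <- list()
    regions <- list(c(1, 1, xc, yc), c(xc + 1, 1, w, yc),
                    c(1, yc + 1, xc, h), c(xc + 1, yc + 1, w, h))
    for (q in 1:4) {
      r <- regions[[q]]
      if (r[3] < r[1] || r[4] < r[2]) next
      t_img <- tiles[[q]]$image
      if (!all(dim(t_img)[1:2] == c(h, w))) t_img <- resize_bilinear(t_img, h, w)
      canvas[r[2]:r[4], r[1]:r[3], ] <- t_img[r[2]:r[4], r[1]:r[3], , drop = FALSE]
      bpx <- yolo_to_corner(tiles[[q]]$boxes, w, h)
      if (nrow(bpx) > 0) {
        bpx[, 1] <- pmax(bpx[, 1], r[1] - 1); bpx[, 3] <- pmin(bpx[, 3], r[3])
        bpx[, 2] <- pmax(bpx[, 2], r[2] - 1); bpx[, 4] <- pmin(bpx[, 4], r[4])
        ok <- bpx[, 3] > bpx[, 1] & bpx[, 4] > bpx[, 2]
        all_boxes[[q]] <- bpx[ok, , drop = FALSE]
        all_cls[[q]] <- tiles[[q]]$boxes$class_id[ok]
        dropped <- dropped + sum(!ok)
      }
    }
    image <- canvas
    boxes_px <- do.call(rbind, c(all_boxes, list(matrix(numeric(0), 0, 4))))
    class_id <- unlist(c(all_cls, list(integer(0))))
  }

  if (isTRUE(config$hsv)) image <- apply_hsv_jitter(image, config$hsv_gains)

  if (isTRUE(config$flip) && stats::runif(1) < config$flip_prob) {
    image <- image[, rev(seq_len(w)), , drop = FALSE]
    if (nrow(boxes_px) > 0) {
      x1 <- w - boxes_px[, 3]; x2 <- w - boxes_px[, 1]
      boxes_px[, 1] <- x1; boxes_px[, 3] <- x2
    }
  }

  if (isTRUE(config$affine)) {
    s <- stats::runif(1, 1 - config$scale_gain, 1 + config$scale_gain)
    tx <- stats::runif(1, -config$translate_frac, config$translate_frac) * w
    ty <- stats::runif(1, -config$translate_frac, config$translate_frac) * h
    res <- apply_affine(image, boxes_px, s, tx, ty)
    image <- res$image; boxes_px <- res$boxes
  }

  cf <- clip_and_filter_boxes(boxes_px, class_id, w, h, config$min_box_area)
  dropped <- dropped + cf$dropped
  out <- list(image = image,
              boxes = corner_to_yolo(cf$boxes, w, h, cf$class_id),
              id = sample$id)
  attr(out, "dropped") <- dropped
  out
}
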