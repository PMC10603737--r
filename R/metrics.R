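# Detections are data.frames with columns x1, y1, x2, y2 (pixel corner form),
# conf, class_id, and optionally image (id/stem) when spanning several images.

detection_frame <- function(x1 = numeric(), y1 = numeric(), x2 = numeric(),
                            y2 = numeric(), conf = numeric(),
                            class_id = integer(), image = NULL) {
  d <- data.frame(x1 = x1, y1 = y1, x2 = x2, y2 = y2,
                  conf = conf, class_id = as.integer(class_id))
  if (!is.null(image)) d$image <- image
  d
}

#' Greedy non-maximum suppression
#'
#' Keeps detections in order of descending confidence and suppresses any
#' remaining detection whose IoU with an already kept one exceeds
#' `iou_thresh`. Ties in confidence are broken by input order, so the result
#' is deterministic and independent of the order the candidates arrive in.
#'
#' @param dets Detection data.frame (columns `x1, y1, x2, y2, conf`, optional
#'   `class_id`). NMS is applied per class when `class_id` is present.
#' @param iou_thresh Suppression threshold; default 0.45.
#' @return The kept subset of `dets`, ordered by descending confidence.
#' @export
nms <- function(dets, iou_thresh = 0.45) {
  if (nrow(dets) == 0) return(dets)
  stopifnot(all(is.finite(dets$conf)))
  cls <- if ("class_id" %in% names(dets)) dets$class_id else rep(0L, nrow(dets))
  keep_all <- integer(0)
  for (cl in sort(unique(cls))) {
    idx <- which(cls == cl)
    ord <- idx[order(-dets$conf[idx], idx)]
    boxes <- as.matrix(dets[ord, c("x1", "y1", "x2", "y2")])
    kept <- logical(length(ord))
    for (i in seq_along(ord)) {
      if (i > 1 && any(kept[seq_len(i - 1)])) {
        prev <- which(kept[seq_len(i - 1)])
        ious <- iou_matrix(boxes[i, , drop = FALSE], boxes[prev, , drop = FALSE])
        if (any(ious > iou_thresh)) next
      }
      kept[i] <- TRUE
    }
    keep_all <- c(keep_all, ord[kept])
  }
  out <- dets[keep_all[order(-dets$conf[keep_all], keep_all)], , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Count animals from post-NMS detections
#'
#' The detector counts by detection: the animal count for an image is the
#' number of surviving detections at or above the confidence threshold.
#'
#' @param dets Detection data.frame after NMS.
#' @param conf_thresh Minimum confidence; default 0.25.
#' @return Integer count.
#' @export
count_detections <- function(dets, conf_thresh = 0.25) {
  if (nrow(dets) == 0) return(0L)
  sum(dets$conf >= conf_thresh)
}

#' Counting accuracy over a set of images
#'
#' Default mode `"relative"` scores the mean relative count error:
#' `100 * (1 - mean(|pred - gt| / gt))`, floored at 0. Mode `"exact"` is the
#' percentage of images whose predicted count matches exactly. The relative
#' form credits near misses on crowded pens; the exact form is stricter.
#'
#' @param pred_counts,gt_counts Equal-length integer vectors; all
#'   `gt_counts > 0`.
#' @param mode `"relative"` (default) or `"exact"`.
#' @return Accuracy in percent.
#' @export
counting_accuracy <- function(pred_counts, gt_counts, mode = c("relative", "exact")) {
  mode <- match.arg(mode)
  if (length(pred_counts) != length(gt_counts))
    stop("pred_counts and gt_counts must have the same length")
  if (any(gt_counts <= 0)) stop("all ground-truth counts must be positive")
  if (mode == "relative") {
    max(0, 100 * (1 - mean(abs(pred_counts - gt_counts) / gt_counts)))
  } else {
    100 * mean(pred_counts == gt_counts)
  }
}

#' Match detections to ground truths at an IoU threshold
#'
#' Greedy single-class matching: detections are visited in descending
#' confidence and claim the unmatched ground truth with the highest IoU;
#' the claim counts as a true positive when that IoU exceeds `iou_thresh`.
#' Each ground truth can be matched at most once, so duplicate detections of
#' one animal yield false positives.
#'
#' @param dets Detection data.frame (one class).
#' @param gts n x 4 matrix or data.frame of ground-truth corner boxes.
#' @param iou_thresh Matching threshold; default 0.5.
#' @return List with `tp`, `fp`, `fn`, logical `det_tp` per detection (in
#'   descending-confidence order), `det_order`, and `matches`
#'   (det index, gt index, IoU).
#' @export
match_detections <- function(dets, gts, iou_thresh = 0.5) {
  gts <- if (is.data.frame(gts)) as.matrix(gts[, c("x1", "y1", "x2", "y2")]) else as_box_matrix(gts)
  n_gt <- nrow(gts)
  n_det <- nrow(dets)
  ord <- order(-dets$conf, seq_len(n_det))
  det_tp <- logical(n_det)
  gt_used <- logical(n_gt)
  matches <- list()
  if (n_det > 0 && n_gt > 0) {
    iom <- iou_matrix(as.matrix(dets[ord, c("x1", "y1", "x2", "y2")]), gts)
    for (i in seq_len(n_det)) {
      avail <- which(!gt_used)
      if (length(avail) == 0) break
      j <- avail[which.max(iom[i, avail])]
      if (iom[i, j] > iou_thresh) {
        det_tp[i] <- TRUE
        gt_used[j] <- TRUE
        matches[[length(matches) + 1]] <- c(det = ord[i], gt = j, iou = iom[i, j])
      }
    }
  }
  tp <- sum(det_tp)
  list(tp = tp, fp = n_det - tp, fn = n_gt - tp,
       det_tp = det_tp, det_order = ord,
       matches = if (length(matches)) do.call(rbind, matches) else
         matrix(numeric(0), 0, 3, dimnames = list(NULL, c("det", "gt", "iou"))))
}

#' Precision, recall and F1 from match counts
#'
#' `P = TP/(TP+FP)`, `R = TP/(TP+FN)`, `F1 = 2PR/(P+R)`; all three are 0 by
#' convention when their denominator vanishes.
#'
#' @param m A match result from [match_detections()], or a list with `tp`,
#'   `fp`, `fn`.
#' @return Named numeric vector `c(precision, recall, f1)`.
#' @export
precision_recall_f1 <- function(m) {
  p <- if (m$tp + m$fp > 0) m$tp / (m$tp + m$fp) else 0
  r <- if (m$tp + m$fn > 0) m$tp / (m$tp + m$fn) else 0
  f1 <- if (p + r > 0) 2 * p * r / (p + r) else 0
  c(precision = p, recall = r, f1 = f1)
}

#' Average precision from ranked detections
#'
#' Area under the monotone precision envelope of the precision-recall curve
#' (the all-points interpolation of the integral `AP = \int_0^1 P(R) dR`).
#' True-positive flags must correspond to detections sorted by descending
#' confidence across all images. AP is defined over confidence thresholds,
#' so detections sharing a confidence value enter together; pass `conf` to
#' group such ties (without it every detection is its own threshold, which
#' differs only when ties exist).
#'
#' @param det_tp Logical vector: TP flag per ranked detection.
#' @param n_gt Total number of ground truths (> 0).
#' @param mode `"all_points"` (default) or `"101_point"` for the 101-point
#'   sampled approximation used as a cross-check.
#' @param conf Optional confidence per ranked detection (non-increasing,
#'   aligned with `det_tp`) used to group tied detections.
#' @return AP in `[0, 1]`.
#' @export
average_precision <- function(det_tp, n_gt, mode = c("all_points", "101_point"),
                              conf = NULL) {
  mode <- match.arg(mode)
  if (n_gt <= 0) stop("average precision is undefined without ground truths")
  if (length(det_tp) == 0) return(0)
  tp_cum <- cumsum(det_tp)
  fp_cum <- cumsum(!det_tp)
  if (!is.null(conf)) {
    stopifnot(length(conf) == length(det_tp))
    # keep only the last rank of each tied-confidence block: the PR point
    # where all detections at that threshold have entered
    last <- c(conf[-1] != conf[-length(conf)], TRUE)
    tp_cum <- tp_cum[last]
    fp_cum <- fp_cum[last]
  }
  recall <- tp_cum / n_gt
  precision <- tp_cum / (tp_cum + fp_cum)
  # monotone envelope from the right
  env <- rev(cummax(rev(precision)))
  if (mode == "all_points") {
    dr <- diff(c(0, recall))
    sum(dr * env)
  } else {
    r_grid <- seq(0, 1, length.out = 101)
    p_at <- vapply(r_grid, function(r) {
      ok <- recall >= r
      if (any(ok)) max(env[ok]) else 0
    }, numeric(1))
    mean(p_at)
  }
}

#' Mean average precision across classes
#'
#' @param aps Numeric vector of per-class AP values (length >= 1).
#' @return Arithmetic mean.
#' @export
mean_ap <- function(aps) {
  if (length(aps) == 0) stop("mean_ap needs at least one class AP")
  mean(aps)
}

#' Relative improvement between two reported percentages
#'
#' `100 * (a - b) / b`, rounded to two decimals — the comparison arithmetic
#' used in model-versus-baseline report tables.
#'
#' @param a New value (percent or score).
#' @param b Baseline value; must be positive.
#' @return Relative improvement in percent, two decimals.
#' @export
relative_improvement <- function(a, b) {
  if (any(b <= 0)) stop("baseline must be positive")
  round(100 * (a - b) / b, 2)
}

#' Evaluate detections against ground truth across images
#'
#' Runs the full evaluation stack: per-image greedy matching at `iou_thresh`
#' for precision/recall/F1 (detections at `conf_thresh`), ranked matching of
#' all detections for AP/mAP, and per-image detection counts for counting
#' accuracy.
#'
#' @param dets Detection data.frame with an `image` column (post-NMS).
#' @param gts Ground-truth data.frame with columns `x1, y1, x2, y2`,
#'   `class_id`, `image`.
#' @param images Optional character vector of image ids to evaluate (images
#'   with no detections still count); defaults to the ids present in `gts`.
#' @param iou_thresh Matching IoU threshold; default 0.5.
#' @param conf_thresh Confidence threshold for P/R/F1 and counting; default 0.25.
#' @param counting_mode Passed to [counting_accuracy()].
#' @return Object of class `metrics_report`.
#' @export
evaluate_detections <- function(dets, gts, images = NULL,
                                iou_thresh = 0.5, conf_thresh = 0.25,
                                counting_mode = "relative") {
  if (is.null(images)) images <- unique(as.character(gts$image))
  if (!"class_id" %in% names(gts)) gts$class_id <- 0L
  if (nrow(dets) > 0 && !"class_id" %in% names(dets)) dets$class_id <- 0L
  classes <- sort(unique(gts$class_id))

  tp <- fp <- fn <- 0
  aps <- numeric(length(classes))
  for (ci in seq_along(classes)) {
    cl <- classes[ci]
    flags <- logical(0); confs <- numeric(0); n_gt <- 0
    for (im in images) {
      g <- gts[gts$image == im & gts$class_id == cl, , drop = FALSE]
      d <- dets[dets$image == im & dets$class_id == cl, , drop = FALSE]
      n_gt <- n_gt + nrow(g)
      # thresholded matching for P/R/F1
      dthr <- d[d$conf >= conf_thresh, , drop = FALSE]
      m <- match_detections(dthr, g, iou_thresh)
      tp <- tp + m$tp; fp <- fp + m$fp; fn <- fn + m$fn
      # unthresholded ranked flags for AP
      ma <- match_detections(d, g, iou_thresh)
      flags <- c(flags, ma$det_tp)
      confs <- c(confs, d$conf[ma$det_order])
    }
    ord <- order(-confs)
    aps[ci] <- if (n_gt > 0)
      average_precision(flags[ord], n_gt, conf = confs[ord]) else NA_real_
  }

  prf <- precision_recall_f1(list(tp = tp, fp = fp, fn = fn))
  pred_counts <- vapply(images, function(im) {
    d <- dets[dets$image == im, , drop = FALSE]
    count_detections(d, conf_thresh)
  }, numeric(1))
  gt_counts <- vapply(images, function(im) sum(gts$image == im), numeric(1))
  ok <- gt_counts > 0
  cacc <- if (any(ok)) counting_accuracy(pred_counts[ok], gt_counts[ok], counting_mode) else NA_real_

  structure(list(
    precision = unname(prf["precision"]), recall = unname(prf["recall"]),
    f1 = unname(prf["f1"]),
    ap = stats::setNames(aps, paste0("class_", classes)),
    map = mean_ap(aps[!is.na(aps)]),
    counting_accuracy = cacc,
    tp = tp, fp = fp, fn = fn,
    pred_counts = unname(pred_counts), gt_counts = unname(gt_counts),
    iou_thresh = iou_thresh, conf_thresh = conf_thresh
  ), class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("Detection metrics (IoU > %.2f, conf >= %.2f)\n",
              x$iou_thresh, x$conf_thresh))
  cat(sprintf("  Counting Accuracy : %6.1f %%\n", x$counting_accuracy))
  cat(sprintf("  Precision         : %6.1f %%\n", 100 * x$precision))
  cat(sprintf("  Recall            : %6.1f %%\n", 100 * x$recall))
  cat(sprintf("  F1 Score          : %6.2f\n", x$f1))
  cat(sprintf("  mAP               : %6.1f %%\n", 100 * x$map))
  invisible(x)
}

round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  floor(x * p + 0.5) / p
}

#' Model comparison table with relative improvements
#'
#' Builds the standard comparison layout (Counting Accuracy, Precision,
#' Recall, F1, mAP per model) and appends, for each non-baseline model, the
#' relative improvement of every column over the baseline model.
#'
#' @param reports Named list of `metrics_report` objects (or lists with the
#'   same fields); names are the model labels.
#' @param baseline Label of the baseline model; default first entry.
#' @return A data.frame with one row per model; improvement columns are
#'   `NA` for the baseline row.
#' @export
comparison_table <- function(reports, baseline = names(reports)[1]) {
  stopifnot(baseline %in% names(reports))
  row <- function(r) c(
    counting_accuracy = r$counting_accuracy,
    precision = 100 * r$precision,
    recall = 100 * r$recall,
    f1 = round_half_up(r$f1, 2),
    map = 100 * r$map
  )
  tab <- as.data.frame(do.call(rbind, lapply(reports, row)))
  tab$model <- names(reports)
  base <- tab[tab$model == baseline, ]
  for (col in c("counting_accuracy", "precision", "recall", "f1", "map")) {
    imp <- rep(NA_real_, nrow(tab))
    for (i in seq_len(nrow(tab))) {
      if (tab$model[i] != baseline && base[[col]] > 0)
        imp[i] <- relative_improvement(tab[[col]][i], base[[col]])
    }
    tab[[paste0(col, "_gain")]] <- imp
  }
  tab[, c("model", "counting_accuracy", "precision", "recall", "f1", "map",
          paste0(c("counting_accuracy", "precision", "recall", "f1", "map"), "_gain"))]
}
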