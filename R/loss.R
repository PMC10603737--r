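# Target assignment and the composite grid loss
#   Loss = L_loc + L_cls + L_conf
# with Focal-CIoU localization over positive slots, per-class binary
# cross-entropy classification, and objectness BCE with a lambda_noobj
# down-weight on the (dominant) negative slots. Probabilities are clamped at
# 1e-7 before logs.

PROB_CLAMP <- 1e-7

clamp_prob <- function(p) pmin(pmax(p, PROB_CLAMP), 1 - PROB_CLAMP)

bce <- function(pred, target) {
  pred <- clamp_prob(pred)
  -(target * log(pred) + (1 - target) * log(1 - pred))
}

#' Assign ground truths to grid/anchor slots
#'
#' Every ground truth is assigned, on each scale, to the cell containing its
#' center and to every anchor whose width and height are both within a factor
#' 4 of the box (the size-ratio filter matching the bounded decode
#' transform). Collisions on a slot are resolved deterministically: the first
#' ground truth in input order keeps the slot.
#'
#' @param annotations Annotation data.frame in normalized center form
#'   (`class_id, cx, cy, w, h`), all boxes within the unit square.
#' @param cfg A [detector_config()].
#' @param ratio_thresh Anchor/box size-ratio threshold; default 4.
#' @param neighbor_cells Additionally assign the two adjacent cells nearest
#'   the object center (the bounded decode transform can still reach the
#'   center from them). Default FALSE: center-cell assignment only.
#' @return Object of class `grid_target`: per-scale positive-slot tables
#'   (`anchor, row, col, gt`), grid geometry, the ground-truth pixel boxes
#'   and classes, and the total slot count.
#' @export
assign_targets <- function(annotations, cfg, ratio_thresh = 4,
                           neighbor_cells = FALSE) {
  S <- cfg$input_size
  if (nrow(annotations) > 0) {
    half_w <- annotations$w / 2; half_h <- annotations$h / 2
    if (any(annotations$cx - half_w < -1e-9) || any(annotations$cx + half_w > 1 + 1e-9) ||
        any(annotations$cy - half_h < -1e-9) || any(annotations$cy + half_h > 1 + 1e-9))
      stop("ground-truth box outside the image frame")
  }
  boxes_px <- yolo_to_corner(annotations, S, S)
  wh <- if (nrow(annotations) > 0)
    cbind(annotations$w * S, annotations$h * S) else matrix(numeric(0), 0, 2)

  scales <- vector("list", 3)
  n_slots <- 0
  for (s in 1:3) {
    stride <- cfg$strides[s]
    g <- S %/% stride
    anchors <- scale_anchors(cfg, s)
    taken <- new.env(parent = emptyenv())
    pos <- list()
    for (i in seq_len(nrow(annotations))) {
      fx <- annotations$cx[i] * g; fy <- annotations$cy[i] * g
      col <- min(floor(fx), g - 1)  # 0-based cell
      row <- min(floor(fy), g - 1)
      cells <- list(c(row, col))
      if (neighbor_cells) {
        # the two adjacent cells nearest the center also own the object:
        # their bounded decode offsets can still reach it, and the extra
        # positives speed up short training runs considerably
        col2 <- col + if (fx - col < 0.5) -1L else 1L
        row2 <- row + if (fy - row < 0.5) -1L else 1L
        if (col2 >= 0 && col2 < g) cells <- c(cells, list(c(row, col2)))
        if (row2 >= 0 && row2 < g) cells <- c(cells, list(c(row2, col)))
      }
      for (a in 1:3) {
        rw <- wh[i, 1] / anchors[a, 1]; rh <- wh[i, 2] / anchors[a, 2]
        ratio <- max(rw, 1 / rw, rh, 1 / rh)
        if (ratio > ratio_thresh) next
        for (cell in cells) {
          key <- paste(a, cell[1], cell[2])
          if (!is.null(taken[[key]])) next
          taken[[key]] <- i
          pos[[length(pos) + 1]] <- c(anchor = a, row = cell[1],
                                      col = cell[2], gt = i)
        }
      }
    }
    pos <- if (length(pos)) as.data.frame(do.call(rbind, pos)) else
      data.frame(anchor = integer(), row = integer(), col = integer(), gt = integer())
    scales[[s]] <- list(grid = g, stride = stride, anchors = anchors, pos = pos)
    n_slots <- n_slots + 3 * g * g
  }
  structure(list(scales = scales, boxes_px = boxes_px,
                 class_id = annotations$class_id, n_slots = n_slots,
                 n_gt = nrow(annotations)),
            class = "grid_target")
}

#' Classification loss over positive slots
#'
#' Sum of per-class binary cross-entropies between predicted class
#' probabilities and one-hot ground truth; 0 when there are no positives.
#'
#' @param pred_probs n_pos x n_classes matrix of predicted probabilities.
#' @param target_class Integer vector (0-based class ids), length n_pos.
#' @return Non-negative scalar.
#' @export
class_loss <- function(pred_probs, target_class) {
  pred_probs <- as.matrix(pred_probs)
  if (nrow(pred_probs) == 0) return(0)
  onehot <- matrix(0, nrow(pred_probs), ncol(pred_probs))
  onehot[cbind(seq_len(nrow(pred_probs)), target_class + 1L)] <- 1
  sum(bce(pred_probs, onehot))
}

#' Objectness (confidence) loss
#'
#' BCE over positive slots plus `lambda_noobj` times BCE over negative
#' slots; the negative target is 0 and the positive target `vbar` is the
#' calibrated confidence (IoU with the assigned box, or 1).
#'
#' @param pred_conf Predicted confidences for all slots.
#' @param obj_mask Logical: TRUE at positive slots.
#' @param vbar Target confidence per positive slot (recycled).
#' @param lambda_noobj Negative-slot weight; default 0.5.
#' @return Non-negative scalar.
#' @export
confidence_loss <- function(pred_conf, obj_mask, vbar = 1, lambda_noobj = 0.5) {
  pos <- sum(bce(pred_conf[obj_mask], rep_len(vbar, sum(obj_mask))))
  neg <- sum(bce(pred_conf[!obj_mask], 0))
  (if (sum(obj_mask)) pos else 0) + lambda_noobj * (if (sum(!obj_mask)) neg else 0)
}

#' Localization loss over positive slots
#'
#' Sum of Focal-CIoU losses between decoded predictions and their assigned
#' ground truths; `gamma = 0` gives the plain CIoU sum (the ablation arm
#' without focal weighting).
#'
#' @param pred_boxes n x 4 decoded corner boxes at positive slots.
#' @param gt_boxes n x 4 assigned ground-truth corner boxes.
#' @param gamma Focal exponent; default 0.5.
#' @return Non-negative scalar; 0 with no positives.
#' @export
locality_loss <- function(pred_boxes, gt_boxes, gamma = 0.5) {
  pred_boxes <- as_box_matrix(pred_boxes)
  if (nrow(pred_boxes) == 0) return(0)
  sum(focal_ciou_loss(pred_boxes, gt_boxes, gamma = gamma))
}

#' Compose the total loss
#'
#' @param loc,cls,conf Finite, non-negative components.
#' @return List of class `loss_breakdown` with `loc`, `cls`, `conf`,
#'   `total = loc + cls + conf`.
#' @export
total_loss <- function(loc, cls, conf) {
  parts <- c(loc = loc, cls = cls, conf = conf)
  if (any(!is.finite(parts)))
    stop("non-finite loss component: training diverged")
  structure(list(loc = loc, cls = cls, conf = conf,
                 total = loc + cls + conf),
            class = "loss_breakdown")
}

# Extract per-slot quantities from raw head outputs for one scale.
slot_index <- function(n_attr, a, attr) (a - 1) * n_attr + attr

#' Composite detection loss for one image
#'
#' Evaluates localization, classification and confidence terms on the raw
#' head outputs against an assignment from [assign_targets()]. The target
#' confidence at positive slots is, by default, the IoU between the decoded
#' prediction and its assigned box (recomputed each call, not differentiated
#' through), matching the `pr(obj) x IoU` confidence semantics; set
#' `vbar_mode = "one"` for fixed-1 targets.
#'
#' @param raw List of three head output arrays.
#' @param target A `grid_target`.
#' @param cfg The matching [detector_config()].
#' @param gamma Focal-CIoU exponent; default 0.5 (0 = plain CIoU).
#' @param lambda_noobj Negative-slot confidence weight; default 0.5.
#' @param vbar_mode `"iou"` (default) or `"one"`.
#' @return A `loss_breakdown`.
#' @export
detection_loss <- function(raw, target, cfg, gamma = 0.5, lambda_noobj = 0.5,
                           vbar_mode = c("iou", "one")) {
  vbar_mode <- match.arg(vbar_mode)
  n_attr <- 5 + cfg$num_classes
  loc <- 0; cls <- 0; conf <- 0
  for (s in 1:3) {
    sc <- target$scales[[s]]
    r <- raw[[s]]
    pos <- sc$pos
    if (nrow(pos) > 0) {
      pred_boxes <- matrix(0, nrow(pos), 4)
      probs <- matrix(0, nrow(pos), cfg$num_classes)
      for (i in seq_len(nrow(pos))) {
        a <- pos$anchor[i]; rw <- pos$row[i]; cl <- pos$col[i]
        t4 <- r[slot_index(n_attr, a, 1:4), rw + 1, cl + 1]
        pred_boxes[i, ] <- decode_slot(t4, sc$anchors[a, ], sc$stride, rw, cl)
        probs[i, ] <- sigmoid(r[slot_index(n_attr, a, 5 + seq_len(cfg$num_classes)),
                                rw + 1, cl + 1])
      }
      gt_boxes <- target$boxes_px[pos$gt, , drop = FALSE]
      loc <- loc + locality_loss(pred_boxes, gt_boxes, gamma)
      cls <- cls + class_loss(probs, target$class_id[pos$gt])
      vbar_pos <- if (vbar_mode == "iou")
        pmax(box_iou(pred_boxes, gt_boxes), 0) else rep(1, nrow(pos))
    }
    for (a in 1:3) {
      p <- sigmoid(r[slot_index(n_attr, a, 5), , ])
      mask_m <- matrix(FALSE, sc$grid, sc$grid)
      vbar_m <- matrix(0, sc$grid, sc$grid)
      rows_a <- which(pos$anchor == a)
      for (i in rows_a) {
        mask_m[pos$row[i] + 1, pos$col[i] + 1] <- TRUE
        vbar_m[pos$row[i] + 1, pos$col[i] + 1] <- vbar_pos[i]
      }
      conf <- conf + confidence_loss(as.vector(p), as.vector(mask_m),
                                     as.vector(vbar_m)[as.vector(mask_m)],
                                     lambda_noobj)
    }
  }
  total_loss(loc, cls, conf)
}

# Lean scalar IoU / CIoU for the training hot path (no validation, no S3):
# semantics identical to box_iou / ciou_loss on single positive-size boxes.
iou_scalar <- function(p, g) {
  iw <- min(p[3], g[3]) - max(p[1], g[1])
  if (iw <= 0) return(0)
  ih <- min(p[4], g[4]) - max(p[2], g[2])
  if (ih <= 0) return(0)
  inter <- iw * ih
  inter / ((p[3] - p[1]) * (p[4] - p[2]) + (g[3] - g[1]) * (g[4] - g[2]) - inter)
}

ciou_scalar <- function(p, g) {
  iou <- iou_scalar(p, g)
  rho2 <- ((p[1] + p[3]) - (g[1] + g[3]))^2 / 4 + ((p[2] + p[4]) - (g[2] + g[4]))^2 / 4
  cw <- max(p[3], g[3]) - min(p[1], g[1])
  ch <- max(p[4], g[4]) - min(p[2], g[2])
  c2 <- cw^2 + ch^2
  dv <- atan((g[3] - g[1]) / (g[4] - g[2])) - atan((p[3] - p[1]) / (p[4] - p[2]))
  v <- (4 / pi^2) * dv^2
  alpha <- if (v == 0) 0 else v / (1 - iou + v)
  1 - iou + (if (c2 > 0) rho2 / c2 else 0) + alpha * v
}

# Loss + gradients w.r.t. the raw head outputs, for the trainer. The
# objectness and class gradients are analytic BCE gradients; the box
# gradient is a central finite difference of the CIoU term through the
# decode transform (the focal weight IoU^gamma is held constant per step).
# Gradients are scaled by 1 / n_slots so magnitudes are independent of the
# grid resolution; the reported breakdown keeps the raw sums.
detection_loss_grad <- function(raw, target, cfg, gamma = 0.5,
                                lambda_noobj = 0.5, vbar_mode = "iou",
                                fd_step = 1e-4,
                                term_gains = c(loc = 1, cls = 1, conf = 1),
                                neg_gain = 8) {
  n_attr <- 5 + cfg$num_classes
  # Per-term normalization for optimization: localization and class
  # gradients are averaged over positive slots, objectness over all slots,
  # then weighted by the term gains. The reported breakdown keeps the plain
  # component sums.
  n_pos_total <- sum(vapply(target$scales, function(s) nrow(s$pos), numeric(1)))
  norm_pos <- if (n_pos_total > 0) 1 / n_pos_total else 0
  n_neg_total <- target$n_slots - n_pos_total
  norm_neg <- if (n_neg_total > 0) 1 / n_neg_total else 0
  g_cls <- term_gains[["cls"]] * norm_pos
  g_conf_pos <- term_gains[["conf"]] * norm_pos
  g_conf_neg <- term_gains[["conf"]] * lambda_noobj * neg_gain * norm_neg
  loc <- 0; cls <- 0; conf <- 0
  douts <- vector("list", 3)
  # first pass: localization losses/gradients per scale, so the focal
  # normalizer (sum of IoU^gamma weights) spans all scales
  loc_res <- vector("list", 3)
  sum_wfocal <- 0
  for (s in 1:3) {
    sc <- target$scales[[s]]
    pos <- sc$pos
    if (nrow(pos) == 0) next
    r <- raw[[s]]
    t4s <- matrix(0, nrow(pos), 4)
    for (i in seq_len(nrow(pos)))
      t4s[i, ] <- r[slot_index(n_attr, pos$anchor[i], 1:4),
                    pos$row[i] + 1, pos$col[i] + 1]
    gts <- target$boxes_px[pos$gt, , drop = FALSE]
    loc_res[[s]] <- loc_grad_scale(t4s, sc$anchors[pos$anchor, , drop = FALSE],
                                   sc$stride, pos$row, pos$col, gts, gamma,
                                   fd_step, identical(vbar_mode, "iou"))
    sum_wfocal <- sum_wfocal + sum(loc_res[[s]]$wfocal)
  }
  # normalize the localization gradient by the total focal weight: the focal
  # factor redistributes the regression signal across positives without
  # shrinking its overall scale
  g_loc <- if (sum_wfocal > 0) term_gains[["loc"]] / sum_wfocal else 0
  for (s in 1:3) {
    sc <- target$scales[[s]]
    r <- raw[[s]]
    dr <- array(0, dim = dim(r))
    pos <- sc$pos
    n_pos <- nrow(pos)
    vbar_pos <- numeric(0)
    if (n_pos > 0) {
      lr <- loc_res[[s]]
      loc <- loc + sum(lr$loss)
      vbar_pos <- lr$vbar
      for (i in seq_len(n_pos)) {
        sl <- slot_index(n_attr, pos$anchor[i], 1:4)
        dr[sl, pos$row[i] + 1, pos$col[i] + 1] <-
          dr[sl, pos$row[i] + 1, pos$col[i] + 1] + lr$g4[i, ] * g_loc
      }
      for (cidx in seq_len(cfg$num_classes)) {
        for (i in seq_len(n_pos)) {
          a <- pos$anchor[i]; rw <- pos$row[i]; cl <- pos$col[i]
          lg2 <- r[slot_index(n_attr, a, 5 + cidx), rw + 1, cl + 1]
          p <- sigmoid(lg2)
          y <- as.numeric(target$class_id[pos$gt[i]] == cidx - 1)
          cls <- cls + bce(p, y)
          dr[slot_index(n_attr, a, 5 + cidx), rw + 1, cl + 1] <- (p - y) * g_cls
        }
      }
    }
    # confidence term over all slots, per anchor plane
    for (a in 1:3) {
      p <- sigmoid(r[slot_index(n_attr, a, 5), , ])
      vbar_m <- matrix(0, sc$grid, sc$grid)
      mask_m <- matrix(FALSE, sc$grid, sc$grid)
      rows_a <- which(pos$anchor == a)
      for (i in rows_a) {
        vbar_m[pos$row[i] + 1, pos$col[i] + 1] <- vbar_pos[i]
        mask_m[pos$row[i] + 1, pos$col[i] + 1] <- TRUE
      }
      w_m <- ifelse(mask_m, 1, lambda_noobj)
      conf <- conf + sum(w_m * bce(p, vbar_m))
      gw_m <- ifelse(mask_m, g_conf_pos, g_conf_neg)
      dr[slot_index(n_attr, a, 5), , ] <- gw_m * (clamp_grad(p) * (p - vbar_m))
    }
    douts[[s]] <- dr
  }
  list(breakdown = total_loss(loc, cls, conf), douts = douts)
}

# BCE gradient through the sigmoid is (p - target); the clamp only matters
# in the saturated tails where log() would overflow — inside the clamp band
# the gradient is zeroed to match the clamped loss.
clamp_grad <- function(p) {
  as.numeric(p > PROB_CLAMP & p < 1 - PROB_CLAMP)
}
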