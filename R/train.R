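# Training: SGD with momentum on the composite grid loss, cosine
# learning-rate decay with linear warmup, per-image gradient accumulation
# into batches. Deterministic under a fixed seed (single-threaded; every
# random draw comes from the run seed).

#' Training run configuration
#'
#' Defaults follow the reference training setup (100 epochs, batch 16,
#' initial learning rate 0.01, momentum 0.937); the `arm` selects the
#' ablation variant: `"plain"` (no attention, plain CIoU), `"sa"` (attention
#' only), `"fc"` (Focal-CIoU only), `"sa_fc"` (both).
#'
#' @param epochs Training epochs; default 100.
#' @param batch_size Images per optimizer step; default 16.
#' @param lr Initial learning rate; default 0.01.
#' @param momentum SGD momentum; default 0.937.
#' @param weight_decay L2 penalty on convolution weights; default 5e-4.
#' @param warmup_epochs Linear warmup span; default 3.
#' @param lr_final_frac Final cosine LR as a fraction of `lr`; default 0.01.
#' @param gamma Focal-CIoU exponent used by the `fc` arms; default 0.5.
#' @param lambda_noobj Negative-confidence weight; default 0.5.
#' @param vbar_mode Positive confidence target: `"iou"` or `"one"`.
#' @param arm Ablation arm: `"plain"`, `"sa"`, `"fc"` or `"sa_fc"`.
#' @param augment Apply data augmentation during training; default TRUE.
#' @param augment_cfg An [augment_config()].
#' @param conf_thresh,nms_iou Post-processing thresholds for evaluation.
#' @param neighbor_cells Also assign each object to its two nearest adjacent
#'   cells during training (extra positives). Off by default: in short
#'   desk-scale runs the extra positives were observed to cost precision.
#' @param ema_decay Exponential-moving-average decay for the returned model
#'   weights (the standard one-stage-detector training practice); the decay
#'   ramps in as `ema_decay * (1 - exp(-step / ema_tau))`. Set 0 to return
#'   the raw final weights.
#' @param ema_tau Ramp time constant of the EMA decay, in optimizer steps.
#' @param seed Run seed.
#' @return List of class `run_config`.
#' @export
run_config <- function(epochs = 100, batch_size = 16, lr = 0.01,
                       momentum = 0.937, weight_decay = 5e-4,
                       warmup_epochs = 3, lr_final_frac = 0.01,
                       gamma = 0.5, lambda_noobj = 0.5,
                       vbar_mode = "iou",
                       arm = c("sa_fc", "plain", "sa", "fc"),
                       augment = TRUE, augment_cfg = augment_config(),
                       conf_thresh = 0.25, nms_iou = 0.45,
                       neighbor_cells = FALSE, ema_decay = 0.999,
                       ema_tau = 500, seed = 0L) {
  arm <- match.arg(arm)
  stopifnot(epochs >= 0, batch_size >= 1)
  structure(list(epochs = epochs, batch_size = batch_size, lr = lr,
                 momentum = momentum, weight_decay = weight_decay,
                 warmup_epochs = warmup_epochs, lr_final_frac = lr_final_frac,
                 gamma = gamma, lambda_noobj = lambda_noobj,
                 vbar_mode = vbar_mode, arm = arm,
                 augment = augment, augment_cfg = augment_cfg,
                 conf_thresh = conf_thresh, nms_iou = nms_iou,
                 neighbor_cells = neighbor_cells,
                 ema_decay = ema_decay, ema_tau = ema_tau,
                 seed = as.integer(seed)),
            class = "run_config")
}

# ---- weight EMA ---------------------------------------------------------

ema_init <- function(params) lapply(params, function(p) p$value)

ema_update <- function(ema, params, d) {
  for (nm in names(params)) {
    v <- params[[nm]]$value
    if (is.list(v) && !is.null(v$groups)) {
      for (k in seq_along(v$groups))
        for (f in names(v$groups[[k]]))
          ema[[nm]]$groups[[k]][[f]] <-
            d * ema[[nm]]$groups[[k]][[f]] + (1 - d) * v$groups[[k]][[f]]
    } else {
      ema[[nm]] <- d * ema[[nm]] + (1 - d) * v
    }
  }
  ema
}

ema_apply <- function(params, ema) {
  for (nm in names(params)) params[[nm]]$value <- ema[[nm]]
  invisible(NULL)
}

arm_settings <- function(rc) {
  list(sa = rc$arm %in% c("sa", "sa_fc"),
       gamma = if (rc$arm %in% c("fc", "sa_fc")) rc$gamma else 0)
}

sgd_step <- function(params, lr, momentum, weight_decay) {
  for (nm in names(params)) {
    p <- params[[nm]]
    if (is.list(p$value) && !is.null(p$value$groups)) {
      for (k in seq_along(p$value$groups)) {
        for (f in names(p$value$groups[[k]])) {
          g <- p$grad$groups[[k]][[f]]
          p$mom$groups[[k]][[f]] <- momentum * p$mom$groups[[k]][[f]] + g
          p$value$groups[[k]][[f]] <- p$value$groups[[k]][[f]] - lr * p$mom$groups[[k]][[f]]
        }
      }
    } else {
      g <- p$grad
      if (weight_decay > 0 && endsWith(nm, ".W")) g <- g + weight_decay * p$value
      p$mom <- momentum * p$mom + g
      p$value <- p$value - lr * p$mom
    }
  }
  invisible(NULL)
}

lr_at <- function(rc, step, steps_per_epoch) {
  total <- rc$epochs * steps_per_epoch
  warm <- rc$warmup_epochs * steps_per_epoch
  if (warm > 0 && step <= warm) return(rc$lr * step / warm)
  tmax <- max(total - warm, 1)
  tcur <- min(step - warm, tmax)
  lr_min <- rc$lr * rc$lr_final_frac
  lr_min + 0.5 * (rc$lr - lr_min) * (1 + cos(pi * tcur / tmax))
}

#' Train a detector
#'
#' Runs seeded SGD-with-momentum on the composite loss over a list of
#' samples. The model architecture follows the run's ablation arm (with or
#' without shuffle attention) and its loss uses the arm's focal exponent.
#' Per-epoch mean loss components are logged; the returned model carries the
#' final weights and the history records the epoch at which validation would
#' be consulted (model selection is left to the caller via `evaluate_model`).
#'
#' @param rc A [run_config()].
#' @param samples List of samples (`image` H x W x 3 sized to the detector
#'   input, `boxes` normalized annotations).
#' @param det_cfg A [detector_config()]; its `sa_insertions` are overridden
#'   by the arm.
#' @param verbose Print per-epoch loss lines.
#' @return List with `model`, `history` (data.frame epoch/loc/cls/conf/total),
#'   and the resolved `det_cfg`.
#' @export
train_detector <- function(rc, samples, det_cfg, verbose = FALSE) {
  arm <- arm_settings(rc)
  det_cfg$sa_insertions <- if (arm$sa) c("p3", "p4", "p5") else character(0)
  model <- build_detector(det_cfg, seed = rc$seed)

  targets <- lapply(samples, function(s)
    assign_targets(s$boxes, det_cfg, neighbor_cells = rc$neighbor_cells))
  n <- length(samples)
  steps_per_epoch <- max(1, ceiling(n / rc$batch_size))
  history <- data.frame(epoch = integer(), loc = numeric(), cls = numeric(),
                        conf = numeric(), total = numeric(), lr = numeric())
  if (rc$epochs == 0)
    return(list(model = model, history = history, det_cfg = det_cfg))

  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(rc$seed + 1L)

  ema <- if (rc$ema_decay > 0) ema_init(model$params) else NULL
  step <- 0
  for (epoch in seq_len(rc$epochs)) {
    ord <- sample.int(n)
    sums <- c(loc = 0, cls = 0, conf = 0, total = 0)
    for (b in seq_len(steps_per_epoch)) {
      idx <- ord[((b - 1) * rc$batch_size + 1):min(b * rc$batch_size, n)]
      idx <- idx[!is.na(idx)]
      zero_grads(model$params)
      for (i in idx) {
        s <- samples[[i]]
        tg <- targets[[i]]
        if (rc$augment) {
          aug_seed <- sample.int(2^31 - 2, 1)
          s <- augment(s, rc$augment_cfg, seed = aug_seed)
          tg <- assign_targets(s$boxes, det_cfg,
                               neighbor_cells = rc$neighbor_cells)
        }
        x <- image_to_tensor(s$image)
        fw <- forward_detector(model, x, training = TRUE)
        lg <- detection_loss_grad(fw$raw, tg, det_cfg, gamma = arm$gamma,
                                  lambda_noobj = rc$lambda_noobj,
                                  vbar_mode = rc$vbar_mode)
        douts <- stats::setNames(lg$douts, model$heads)
        scale <- 1 / length(idx)
        douts <- lapply(douts, function(d) d * scale)
        backward_graph(model$nodes, fw$caches, douts)
        bd <- lg$breakdown
        sums <- sums + c(bd$loc, bd$cls, bd$conf, bd$total) / n
      }
      step <- step + 1
      lr_now <- lr_at(rc, step, steps_per_epoch)
      sgd_step(model$params, lr_now, rc$momentum, rc$weight_decay)
      if (!is.null(ema)) {
        d <- rc$ema_decay * (1 - exp(-step / rc$ema_tau))
        ema <- ema_update(ema, model$params, d)
      }
    }
    if (any(!is.finite(sums))) stop("non-finite loss: training diverged")
    history <- rbind(history, data.frame(epoch = epoch, loc = sums["loc"],
                                         cls = sums["cls"], conf = sums["conf"],
                                         total = sums["total"], lr = lr_at(rc, step, steps_per_epoch)))
    if (verbose)
      message(sprintf("epoch %3d  loc %8.3f  cls %8.3f  conf %8.3f  total %8.3f",
                      epoch, sums["loc"], sums["cls"], sums["conf"], sums["total"]))
  }
  rownames(history) <- NULL
  if (!is.null(ema)) ema_apply(model$params, ema)
  list(model = model, history = history, det_cfg = det_cfg)
}

#' Detect objects in one image
#'
#' Forward pass in inference mode, decode, confidence filter, NMS.
#'
#' @param model A trained detector.
#' @param image H x W x 3 array already sized to the detector input (use
#'   [letterbox()] otherwise).
#' @param conf_thresh Confidence threshold; default 0.25.
#' @param nms_iou NMS IoU threshold; default 0.45.
#' @return Detection data.frame in input pixel coordinates.
#' @export
predict_image <- function(model, image, conf_thresh = 0.25, nms_iou = 0.45) {
  x <- image_to_tensor(image)
  fw <- forward_detector(model, x, training = FALSE)
  dets <- decode_predictions(fw$raw, model$cfg, conf_thresh = conf_thresh)
  nms(dets, nms_iou)
}

#' Evaluate a detector on a sample set
#'
#' @param model A trained detector.
#' @param samples List of samples with ground-truth boxes.
#' @param conf_thresh,nms_iou Post-processing thresholds.
#' @param iou_thresh Matching threshold for the metrics; default 0.5.
#' @param counting_mode Passed to [counting_accuracy()].
#' @return A `metrics_report`.
#' @export
evaluate_model <- function(model, samples, conf_thresh = 0.25, nms_iou = 0.45,
                           iou_thresh = 0.5, counting_mode = "relative") {
  S <- model$cfg$input_size
  dets <- list(); gts <- list()
  # keep low-confidence detections (floor 0.01) so the PR curve has range
  dec_thresh <- min(0.01, conf_thresh)
  for (s in samples) {
    d <- predict_image(model, s$image, conf_thresh = dec_thresh, nms_iou = nms_iou)
    if (nrow(d) > 0) d$image <- s$id
    dets[[length(dets) + 1]] <- d
    g <- yolo_to_corner(s$boxes, S, S)
    if (nrow(g) > 0) {
      gdf <- as.data.frame(g)
      names(gdf) <- c("x1", "y1", "x2", "y2")
      gdf$class_id <- s$boxes$class_id
      gdf$image <- s$id
      gts[[length(gts) + 1]] <- gdf
    }
  }
  dets <- do.call(rbind, dets[vapply(dets, nrow, numeric(1)) > 0])
  if (is.null(dets)) dets <- detection_frame(image = character())
  gts <- do.call(rbind, gts)
  evaluate_detections(dets, gts, images = vapply(samples, `[[`, "", "id"),
                      iou_thresh = iou_thresh, conf_thresh = conf_thresh,
                      counting_mode = counting_mode)
}

#' Ground-truth-based oracle detector with controllable corruption
#'
#' Returns the labels of each sample as detections, optionally dropping each
#' object independently with probability `drop_rate`, jittering box corners
#' by a fraction of the box size, and adding spurious boxes at rate
#' `fp_rate` per image. With all rates 0 this is the perfect detector used
#' to validate the metrics stack end to end; with `drop_rate = d` its recall
#' is `1 - d` in expectation.
#'
#' @param samples List of samples.
#' @param image_size Pixel size of the (square) images.
#' @param drop_rate Per-object miss probability.
#' @param jitter Corner jitter as a fraction of box width/height.
#' @param fp_rate Expected spurious detections per image.
#' @param seed RNG seed.
#' @return Detection data.frame with an `image` column.
#' @export
oracle_detector <- function(samples, image_size, drop_rate = 0, jitter = 0,
                            fp_rate = 0, seed = 0L) {
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(seed)
  out <- list()
  for (s in samples) {
    g <- yolo_to_corner(s$boxes, image_size, image_size)
    if (nrow(g) > 0) {
      keep <- stats::runif(nrow(g)) >= drop_rate
      g <- g[keep, , drop = FALSE]
      if (jitter > 0 && nrow(g) > 0) {
        w <- g[, 3] - g[, 1]; h <- g[, 4] - g[, 2]
        g[, 1] <- g[, 1] + stats::runif(nrow(g), -jitter, jitter) * w
        g[, 3] <- g[, 3] + stats::runif(nrow(g), -jitter, jitter) * w
        g[, 2] <- g[, 2] + stats::runif(nrow(g), -jitter, jitter) * h
        g[, 4] <- g[, 4] + stats::runif(nrow(g), -jitter, jitter) * h
        g[, c(1, 3)] <- t(apply(g[, c(1, 3), drop = FALSE], 1, sort))
        g[, c(2, 4)] <- t(apply(g[, c(2, 4), drop = FALSE], 1, sort))
      }
    }
    n_fp <- if (fp_rate > 0) stats::rpois(1, fp_rate) else 0
    fps <- if (n_fp > 0) {
      sz <- stats::runif(n_fp, 0.05, 0.2) * image_size
      cx <- stats::runif(n_fp, sz, image_size - sz)
      cy <- stats::runif(n_fp, sz, image_size - sz)
      cbind(cx - sz / 2, cy - sz / 2, cx + sz / 2, cy + sz / 2)
    } else matrix(numeric(0), 0, 4)
    boxes <- rbind(g, fps)
    if (nrow(boxes) > 0) {
      d <- data.frame(x1 = boxes[, 1], y1 = boxes[, 2],
                      x2 = boxes[, 3], y2 = boxes[, 4],
                      conf = stats::runif(nrow(boxes), 0.6, 1),
                      class_id = 0L, image = s$id)
      out[[length(out) + 1]] <- d
    }
  }
  if (length(out) == 0) return(detection_frame(image = character()))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
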