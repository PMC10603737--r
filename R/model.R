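# The detector: YOLOv5-style backbone (Conv/C3/SPPF with optional
# shuffle-attention after each backbone C3 stage), FPN top-down + PAN
# bottom-up neck, and three 1x1-convolution heads predicting, per grid cell
# and anchor, the box offsets (tx, ty, tw, th), an objectness logit and class
# logits.

new_sa_param <- function(value) {
  zero <- value
  for (k in seq_along(zero$groups))
    zero$groups[[k]] <- lapply(zero$groups[[k]], function(v) v * 0)
  e <- new.env(parent = emptyenv())
  e$value <- value
  e$grad <- zero
  e$mom <- zero
  e
}

make_sa_layer <- function(C, G) {
  layer <- new.env(parent = emptyenv())
  layer$params <- new_sa_param(sa_params(C, G))
  layer$cfg <- list(C = C, G = G)
  layer
}

default_anchors <- function(input_size) {
  base <- matrix(c(10, 13, 16, 30, 33, 23,
                   30, 61, 62, 45, 59, 119,
                   116, 90, 156, 198, 373, 326),
                 ncol = 2, byrow = TRUE)
  a <- base * input_size / 640
  dimnames(a) <- list(NULL, c("w", "h"))
  a
}

#' Detector configuration
#'
#' @param input_size Square network input in pixels (divisible by 32);
#'   default 320.
#' @param width_multiple Channel-width multiplier on the base stage widths
#'   (64, 128, 256, 512, 1024); default 0.25.
#' @param depth_multiple Depth multiplier on the base C3 repeat counts;
#'   default 0.33.
#' @param num_classes Number of object classes; default 1 ("pig").
#' @param anchors 9 x 2 matrix of (w, h) anchor priors in input pixels,
#'   area-ascending (rows 1-3 at stride 8, 4-6 at 16, 7-9 at 32). Default:
#'   standard small/medium/large priors scaled to the input size; replace
#'   with [kmeans_anchors()] output for a specific dataset.
#' @param sa_insertions Backbone stages receiving a shuffle-attention block
#'   after their C3 stage; subset of `c("p3", "p4", "p5")`. Empty vector
#'   gives the plain baseline arm.
#' @param sa_groups Shuffle-attention group count; default 8 (must divide
#'   half the stage's channel width).
#' @return List of class `detector_config`.
#' @export
detector_config <- function(input_size = 320, width_multiple = 0.25,
                            depth_multiple = 0.33, num_classes = 1,
                            anchors = NULL,
                            sa_insertions = c("p3", "p4", "p5"),
                            sa_groups = 8) {
  if (input_size %% 32 != 0) stop("input_size must be divisible by 32")
  if (is.null(anchors)) anchors <- default_anchors(input_size)
  anchors <- as.matrix(anchors)
  if (nrow(anchors) != 9 || ncol(anchors) != 2)
    stop("anchors must be a 9 x 2 matrix (3 per scale)")
  structure(list(input_size = input_size, width_multiple = width_multiple,
                 depth_multiple = depth_multiple, num_classes = num_classes,
                 anchors = anchors, strides = c(8, 16, 32),
                 sa_insertions = sa_insertions, sa_groups = sa_groups),
            class = "detector_config")
}

#' Tiny desk-scale preset
#'
#' A configuration small enough to train on one CPU core in minutes:
#' 160 px input, one-eighth width, minimal depth.
#' @param ... Overrides forwarded to [detector_config()].
#' @export
tiny_config <- function(...) {
  detector_config(input_size = 160, width_multiple = 0.125,
                  depth_multiple = 0.2, ...)
}

cfg_channels <- function(cfg) {
  base <- c(64, 128, 256, 512, 1024)
  ch <- pmax(4, 4 * round(base * cfg$width_multiple / 4))
  stats::setNames(ch, c("c1", "c2", "c3", "c4", "c5"))
}

cfg_depth <- function(cfg) {
  max(1, round(3 * cfg$depth_multiple))
}

#' Build the detector
#'
#' Assembles the full graph (backbone with optional shuffle-attention
#' insertions, FPN+PAN neck, three heads) with seeded He-normal weight
#' initialization. Objectness biases start low (about 8 expected objects per
#' scale) so early training is not swamped by false objectness.
#'
#' @param cfg A [detector_config()].
#' @param seed Initialization seed.
#' @return Model object (list with `nodes`, `cfg`, `heads`, `params`).
#' @export
build_detector <- function(cfg, seed = 0L) {
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(seed)

  ch <- cfg_channels(cfg)
  n <- cfg_depth(cfg)
  gb <- graph_builder()

  # backbone
  stem <- gb$add("stem", "conv", ".input", make_conv(3, ch["c1"], 6, 2, 2))
  b2c <- gb$add("b2_conv", "conv", stem, make_conv(ch["c1"], ch["c2"], 3, 2, 1))
  b2 <- add_c3(gb, "b2_c3", b2c, ch["c2"], ch["c2"], n)
  b3c <- gb$add("b3_conv", "conv", b2, make_conv(ch["c2"], ch["c3"], 3, 2, 1))
  p3 <- add_c3(gb, "b3_c3", b3c, ch["c3"], ch["c3"], n)
  if ("p3" %in% cfg$sa_insertions)
    p3 <- gb$add("sa_p3", "sa", p3, make_sa_layer(ch["c3"], cfg$sa_groups))
  b4c <- gb$add("b4_conv", "conv", p3, make_conv(ch["c3"], ch["c4"], 3, 2, 1))
  p4 <- add_c3(gb, "b4_c3", b4c, ch["c4"], ch["c4"], n)
  if ("p4" %in% cfg$sa_insertions)
    p4 <- gb$add("sa_p4", "sa", p4, make_sa_layer(ch["c4"], cfg$sa_groups))
  b5c <- gb$add("b5_conv", "conv", p4, make_conv(ch["c4"], ch["c5"], 3, 2, 1))
  p5c3 <- add_c3(gb, "b5_c3", b5c, ch["c5"], ch["c5"], n)
  p5in <- if ("p5" %in% cfg$sa_insertions)
    gb$add("sa_p5", "sa", p5c3, make_sa_layer(ch["c5"], cfg$sa_groups)) else p5c3
  p5 <- add_sppf(gb, "sppf", p5in, ch["c5"])

  # neck: FPN (top-down) then PAN (bottom-up)
  lat5 <- gb$add("n_lat5", "conv", p5, make_conv(ch["c5"], ch["c4"], 1, 1, 0))
  up5 <- gb$add("n_up5", "upsample", lat5)
  cat4 <- gb$add("n_cat4", "cat", c(up5, p4))
  fpn4 <- add_c3(gb, "n_c3_4", cat4, 2 * ch["c4"], ch["c4"], n, shortcut = FALSE)
  lat4 <- gb$add("n_lat4", "conv", fpn4, make_conv(ch["c4"], ch["c3"], 1, 1, 0))
  up4 <- gb$add("n_up4", "upsample", lat4)
  cat3 <- gb$add("n_cat3", "cat", c(up4, p3))
  out3 <- add_c3(gb, "n_c3_3", cat3, 2 * ch["c3"], ch["c3"], n, shortcut = FALSE)
  down3 <- gb$add("p_down3", "conv", out3, make_conv(ch["c3"], ch["c3"], 3, 2, 1))
  pcat4 <- gb$add("p_cat4", "cat", c(down3, lat4))
  out4 <- add_c3(gb, "p_c3_4", pcat4, 2 * ch["c3"], ch["c4"], n, shortcut = FALSE)
  down4 <- gb$add("p_down4", "conv", out4, make_conv(ch["c4"], ch["c4"], 3, 2, 1))
  pcat5 <- gb$add("p_cat5", "cat", c(down4, lat5))
  out5 <- add_c3(gb, "p_c3_5", pcat5, 2 * ch["c4"], ch["c5"], n, shortcut = FALSE)

  # heads: plain 1x1 convolutions with bias
  n_attr <- 5 + cfg$num_classes
  heads <- character(3)
  head_in <- c(out3, out4, out5)
  head_ch <- ch[c("c3", "c4", "c5")]
  for (s in 1:3) {
    layer <- make_conv(head_ch[s], 3 * n_attr, 1, 1, 0,
                       norm = FALSE, act = FALSE, bias = TRUE)
    # small head weights: at the start every slot decodes to its anchor
    # prior at the cell center, the best-calibrated initial guess
    layer$W$value <- layer$W$value * 0.1
    grid <- cfg$input_size / cfg$strides[s]
    b <- rep(0, 3 * n_attr)
    obj_idx <- (0:2) * n_attr + 5
    b[obj_idx] <- log(8 / grid^2)  # expect ~8 objects per scale at start
    layer$bias$value <- b
    heads[s] <- gb$add(paste0("head_p", s + 2), "conv", head_in[s], layer)
  }

  nodes <- gb$nodes
  list(nodes = nodes, cfg = cfg, heads = heads,
       params = collect_params(nodes))
}

#' Run the detector forward
#'
#' @param model A built detector.
#' @param input Image tensor, dim `c(3, input_size, input_size)` in `[0, 1]`.
#' @param training Use per-sample normalization statistics and keep caches
#'   for backpropagation.
#' @return List with `raw` (three head output arrays, fine-to-coarse) and,
#'   when `training`, `caches`.
#' @export
forward_detector <- function(model, input, training = FALSE) {
  d <- dim(input)
  if (length(d) != 3 || d[1] != 3 || d[2] != model$cfg$input_size ||
      d[3] != model$cfg$input_size)
    stop("input must be a (3, S, S) tensor matching cfg$input_size")
  res <- forward_graph(model$nodes, input, training, model$heads)
  out <- list(raw = res$values[model$heads])
  if (training) out$caches <- res$caches
  out
}

#' Convert an H x W x 3 image to a network input tensor
#' @param image H x W x 3 array in `[0, 1]`.
#' @return Array with dim `c(3, H, W)`.
#' @export
image_to_tensor <- function(image) {
  aperm(image, c(3, 1, 2))
}

#' Predicted confidence semantics
#'
#' The calibration target of the objectness output: the probability that an
#' object is present times the localization quality,
#' `confidence = pr(obj) * IoU`.
#'
#' @param p_obj Object-presence probability in `[0, 1]`.
#' @param iou_with_gt IoU with the matched ground truth in `[0, 1]`.
#' @return The product.
#' @export
confidence_score <- function(p_obj, iou_with_gt) {
  stopifnot(all(p_obj >= 0 & p_obj <= 1), all(iou_with_gt >= 0 & iou_with_gt <= 1))
  p_obj * iou_with_gt
}

scale_anchors <- function(cfg, s) {
  cfg$anchors[(s - 1) * 3 + 1:3, , drop = FALSE]
}

# Decode transform: sigmoid-bounded center offsets within an expanded cell
# and a quadratic-bounded size transform,
#   bx = (2*sigmoid(tx) - 0.5 + col) * stride
#   bw = anchor_w * (2*sigmoid(tw))^2          (bounded by 4 * anchor)
# At zero logits a slot decodes to its cell center at the anchor prior size.

#' Decode raw head outputs into detections
#'
#' @param raw List of three head output arrays from [forward_detector()].
#' @param cfg The matching [detector_config()].
#' @param conf_thresh Drop detections below this confidence before returning
#'   (0 keeps everything); default 0.
#' @return Detection data.frame (`x1, y1, x2, y2, conf, class_id`) in input
#'   pixel coordinates; `conf` is `sigmoid(objectness) * max class
#'   probability`.
#' @export
decode_predictions <- function(raw, cfg, conf_thresh = 0) {
  n_attr <- 5 + cfg$num_classes
  out <- list()
  for (s in seq_along(raw)) {
    r <- raw[[s]]
    gh <- dim(r)[2]; gw <- dim(r)[3]
    stride <- cfg$input_size / gh
    anchors <- scale_anchors(cfg, s)
    col0 <- matrix(rep(0:(gw - 1), each = gh), gh, gw)
    row0 <- matrix(rep(0:(gh - 1), gw), gh, gw)
    for (a in 1:3) {
      base <- (a - 1) * n_attr
      tx <- r[base + 1, , ]; ty <- r[base + 2, , ]
      tw <- r[base + 3, , ]; th <- r[base + 4, , ]
      obj <- sigmoid(r[base + 5, , ])
      cls <- array(sigmoid(r[base + 5 + seq_len(cfg$num_classes), , ]),
                   dim = c(cfg$num_classes, gh, gw))
      bx <- (2 * sigmoid(tx) - 0.5 + col0) * stride
      by <- (2 * sigmoid(ty) - 0.5 + row0) * stride
      bw <- anchors[a, 1] * (2 * sigmoid(tw))^2
      bh <- anchors[a, 2] * (2 * sigmoid(th))^2
      best_cls <- apply(cls, c(2, 3), which.max)
      best_p <- apply(cls, c(2, 3), max)
      conf <- obj * best_p
      keep <- conf >= conf_thresh
      if (!any(keep)) next
      out[[length(out) + 1]] <- data.frame(
        x1 = (bx - bw / 2)[keep], y1 = (by - bh / 2)[keep],
        x2 = (bx + bw / 2)[keep], y2 = (by + bh / 2)[keep],
        conf = conf[keep], class_id = as.integer(best_cls[keep] - 1L),
        scale = s, anchor = a
      )
    }
  }
  if (length(out) == 0)
    return(detection_frame())
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

logit <- function(p, eps = 1e-7) {
  p <- pmin(pmax(p, eps), 1 - eps)
  log(p / (1 - p))
}

# Inverse of the decode transform for one ground-truth box on one slot.
encode_box <- function(box_px, anchor, stride, row0, col0) {
  ctr <- box_convert(box_px, "center")
  tx <- logit(((ctr[1] / stride) - col0 + 0.5) / 2)
  ty <- logit(((ctr[2] / stride) - row0 + 0.5) / 2)
  tw <- logit(sqrt(ctr[3] / (4 * anchor[1])))
  th <- logit(sqrt(ctr[4] / (4 * anchor[2])))
  c(tx, ty, tw, th)
}

decode_slot <- function(t4, anchor, stride, row0, col0) {
  bx <- (2 * sigmoid(t4[1]) - 0.5 + col0) * stride
  by <- (2 * sigmoid(t4[2]) - 0.5 + row0) * stride
  bw <- anchor[1] * (2 * sigmoid(t4[3]))^2
  bh <- anchor[2] * (2 * sigmoid(t4[4]))^2
  c(bx - bw / 2, by - bh / 2, bx + bw / 2, by + bh / 2)
}

#' Count trainable parameter values in a model
#' @param model A built detector.
#' @return Integer count of scalar parameters.
#' @export
count_parameters <- function(model) {
  n_param_values(model$params)
}

# ---- checkpoint serialization ------------------------------------------

param_state <- function(model) {
  state <- list()
  for (node in model$nodes) {
    if (is.null(node$layer)) next
    entry <- list()
    for (nm in c("W", "bias", "gamma", "beta", "params"))
      if (!is.null(node$layer[[nm]])) entry[[nm]] <- node$layer[[nm]]$value
    state[[node$id]] <- entry
  }
  state
}

restore_param_state <- function(model, state) {
  for (node in model$nodes) {
    if (is.null(node$layer) || is.null(state[[node$id]])) next
    entry <- state[[node$id]]
    for (nm in c("W", "bias", "gamma", "beta", "params"))
      if (!is.null(entry[[nm]])) node$layer[[nm]]$value <- entry[[nm]]
  }
  invisible(model)
}

#' Save a model checkpoint
#'
#' Single-file, versioned serialization of the configuration and all
#' parameter state.
#'
#' @param model A built detector.
#' @param path Output file.
#' @export
save_checkpoint <- function(model, path) {
  saveRDS(list(format_version = 1L, cfg = unclass(model$cfg),
               state = param_state(model)), path)
  invisible(path)
}

#' Load a model checkpoint
#' @param path Checkpoint file written by [save_checkpoint()].
#' @return A rebuilt detector with restored parameters.
#' @export
load_checkpoint <- function(path) {
  ck <- readRDS(path)
  if (is.null(ck$format_version) || ck$format_version != 1L)
    stop("unsupported checkpoint format")
  cfg <- do.call(detector_config, ck$cfg[c("input_size", "width_multiple",
                                           "depth_multiple", "num_classes",
                                           "anchors", "sa_insertions",
                                           "sa_groups")])
  model <- build_detector(cfg, seed = 0L)
  restore_param_state(model, ck$state)
  model
}
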