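#' @useDynLib pigdetect, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# Boxes are length-4 numeric vectors or n x 4 matrices.
# Corner form: (x1, y1, x2, y2), origin top-left, half-open pixel intervals
# [x1, x2) x [y1, y2), so width = x2 - x1 with no +1.
# Center form: (cx, cy, w, h).

as_box_matrix <- function(b) {
  if (is.null(dim(b))) b <- matrix(as.numeric(b), nrow = 1)
  if (ncol(b) != 4) stop("a box needs exactly 4 coordinates")
  storage.mode(b) <- "double"
  b
}

validate_corner <- function(b, require_positive = FALSE) {
  b <- as_box_matrix(b)
  if (any(b[, 3] < b[, 1]) || any(b[, 4] < b[, 2]))
    stop("invalid box: x2 >= x1 and y2 >= y1 required")
  if (require_positive && (any(b[, 3] <= b[, 1]) || any(b[, 4] <= b[, 2])))
    stop("invalid box: positive width and height required")
  b
}

#' Convert boxes between corner and center form
#'
#' Boxes live in pixel coordinates with the origin at the top-left corner and
#' half-open intervals, so a corner box `(x1, y1, x2, y2)` has width `x2 - x1`.
#' The center form is `(cx, cy, w, h)`. The conversion is exact (affine), so a
#' round trip reproduces the input on representable values.
#'
#' @param b Numeric length-4 vector or n x 4 matrix of boxes.
#' @param to Target convention, `"corner"` or `"center"`.
#' @return Boxes in the target convention, same shape as the input.
#' @examples
#' box_convert(c(1, 1, 2, 2), to = "corner")  # -> 0 0 2 2
#' @export
box_convert <- function(b, to = c("corner", "center")) {
  to <- match.arg(to)
  was_vec <- is.null(dim(b))
  m <- as_box_matrix(b)
  out <- if (to == "corner") {
    cbind(m[, 1] - m[, 3] / 2, m[, 2] - m[, 4] / 2,
          m[, 1] + m[, 3] / 2, m[, 2] + m[, 4] / 2)
  } else {
    cbind((m[, 1] + m[, 3]) / 2, (m[, 2] + m[, 4]) / 2,
          m[, 3] - m[, 1], m[, 4] - m[, 2])
  }
  colnames(out) <- if (to == "corner") c("x1", "y1", "x2", "y2") else c("cx", "cy", "w", "h")
  if (was_vec) drop(out) else out
}

box_area <- function(b) {
  m <- as_box_matrix(b)
  pmax(m[, 3] - m[, 1], 0) * pmax(m[, 4] - m[, 2], 0)
}

#' Intersection over union of two boxes
#'
#' `|A intersect B| / |A union B|` for axis-aligned corner-form boxes.
#' Degenerate pairs whose union has zero area return 0 by convention.
#'
#' @param a,b Corner-form boxes (length-4 vectors or aligned n x 4 matrices).
#' @return IoU value(s) in `[0, 1]`.
#' @export
box_iou <- function(a, b) {
  a <- validate_corner(a); b <- validate_corner(b)
  iw <- pmax(pmin(a[, 3], b[, 3]) - pmax(a[, 1], b[, 1]), 0)
  ih <- pmax(pmin(a[, 4], b[, 4]) - pmax(a[, 2], b[, 2]), 0)
  inter <- iw * ih
  uni <- box_area(a) + box_area(b) - inter
  ifelse(uni > 0, inter / uni, 0)
}

#' Pairwise IoU matrix
#'
#' @param A m x 4 corner-form boxes.
#' @param B n x 4 corner-form boxes.
#' @return m x n matrix of IoU values.
#' @export
iou_matrix <- function(A, B) {
  A <- validate_corner(A); B <- validate_corner(B)
  m <- nrow(A); n <- nrow(B)
  if (m == 0L || n == 0L) return(matrix(0, m, n))
  iw <- pmax(outer(A[, 3], B[, 3], pmin) - outer(A[, 1], B[, 1], pmax), 0)
  ih <- pmax(outer(A[, 4], B[, 4], pmin) - outer(A[, 2], B[, 2], pmax), 0)
  inter <- iw * ih
  uni <- outer(box_area(A), box_area(B), `+`) - inter
  out <- inter / uni
  out[uni <= 0] <- 0
  out
}

#' Aspect-ratio consistency term of the CIoU loss
#'
#' Measures disagreement between the aspect ratios of a predicted and a
#' ground-truth box via the squared arctan gap,
#' `v = (4 / pi^2) * (atan(wgt / hgt) - atan(w / h))^2`, which lies in
#' `[0, 1]`. With `as_printed = TRUE` the square on the arctan difference is
#' dropped (an alternative sometimes seen in print); that variant can be
#' negative and is provided for comparison only.
#'
#' @param pred,gt Corner-form boxes with positive width and height.
#' @param as_printed Use the unsquared arctan difference variant.
#' @return Aspect term `v`.
#' @export
aspect_term_v <- function(pred, gt, as_printed = FALSE) {
  pred <- validate_corner(pred, require_positive = TRUE)
  gt <- validate_corner(gt, require_positive = TRUE)
  w <- pred[, 3] - pred[, 1]; h <- pred[, 4] - pred[, 2]
  wg <- gt[, 3] - gt[, 1]; hg <- gt[, 4] - gt[, 2]
  d <- atan(wg / hg) - atan(w / h)
  if (as_printed) (4 / pi^2) * d else (4 / pi^2) * d^2
}

#' Aspect-term weight of the CIoU loss
#'
#' `alpha = v / (1 - iou + v)`, defined as 0 when `v = 0` (including the
#' `iou = 1, v = 0` corner where the denominator vanishes).
#'
#' @param v Aspect term, `v >= 0`.
#' @param iou IoU in `[0, 1]`.
#' @return Weight in `[0, 1]`.
#' @export
alpha_weight <- function(v, iou) {
  den <- 1 - iou + v
  ifelse(v == 0, 0, v / den)
}

#' Complete-IoU (CIoU) loss with a full breakdown
#'
#' `L_CIoU = 1 - IoU + rho^2 / c^2 + alpha * v`, where `rho` is the distance
#' between the two box centers, `c` the diagonal of the minimum enclosing
#' rectangle of both boxes, `v` the aspect-consistency term and `alpha` its
#' adaptive weight. Returns all intermediate quantities so each penalty can be
#' inspected (and the ablation against plain IoU expressed).
#'
#' @param pred,gt Corner-form boxes with positive width and height.
#' @param as_printed Use the unsquared aspect-term variant (see
#'   [aspect_term_v()]).
#' @return An object of class `ciou_breakdown`: list with `iou`,
#'   `center_dist_sq`, `enclosing_diag_sq`, `v`, `alpha`, `loss`.
#' @export
ciou_loss <- function(pred, gt, as_printed = FALSE) {
  pred <- validate_corner(pred, require_positive = TRUE)
  gt <- validate_corner(gt, require_positive = TRUE)
  iou <- box_iou(pred, gt)
  pc <- box_convert(pred, "center"); gc_ <- box_convert(gt, "center")
  pc <- as_box_matrix(pc); gc_ <- as_box_matrix(gc_)
  rho2 <- unname((pc[, 1] - gc_[, 1])^2 + (pc[, 2] - gc_[, 2])^2)
  cw <- pmax(pred[, 3], gt[, 3]) - pmin(pred[, 1], gt[, 1])
  ch <- pmax(pred[, 4], gt[, 4]) - pmin(pred[, 2], gt[, 2])
  c2 <- cw^2 + ch^2
  v <- aspect_term_v(pred, gt, as_printed = as_printed)
  alpha <- alpha_weight(v, iou)
  loss <- 1 - iou + ifelse(c2 > 0, rho2 / c2, 0) + alpha * v
  structure(
    list(iou = iou, center_dist_sq = rho2, enclosing_diag_sq = c2,
         v = v, alpha = alpha, loss = loss),
    class = "ciou_breakdown"
  )
}

#' Focal-CIoU loss
#'
#' CIoU loss reweighted by the overlap itself: `IoU^gamma * L_CIoU`. Boxes
#' that already overlap their target well ("positive-leaning" predictions)
#' contribute more, countering the dominance of poorly overlapping samples.
#' Disjoint boxes get weight `0^gamma = 0` for any `gamma > 0`, a documented
#' consequence of the focal form; `gamma = 0` recovers the plain CIoU loss.
#' During training the focal weight is treated as a constant scaling factor
#' per step (it is not differentiated through).
#'
#' @param pred,gt Corner-form boxes with positive width and height.
#' @param gamma Focal exponent, `>= 0`; default 0.5.
#' @param as_printed Passed to [ciou_loss()].
#' @return Loss value(s), `>= 0` for the squared aspect form.
#' @export
focal_ciou_loss <- function(pred, gt, gamma = 0.5, as_printed = FALSE) {
  stopifnot(gamma >= 0)
  br <- ciou_loss(pred, gt, as_printed = as_printed)
  br$iou^gamma * br$loss
}

#' @export
print.ciou_breakdown <- function(x, ...) {
  cat("CIoU breakdown\n")
  cat(sprintf("  IoU          : %s\n", paste(signif(x$iou, 6), collapse = " ")))
  cat(sprintf("  rho^2 / c^2  : %s\n",
              paste(signif(x$center_dist_sq / pmax(x$enclosing_diag_sq, .Machine$double.eps), 6),
                    collapse = " ")))
  cat(sprintf("  v, alpha     : %s | %s\n",
              paste(signif(x$v, 6), collapse = " "),
              paste(signif(x$alpha, 6), collapse = " ")))
  cat(sprintf("  loss         : %s\n", paste(signif(x$loss, 6), collapse = " ")))
  invisible(x)
}
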