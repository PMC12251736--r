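#' Intersection-over-union with full breakdown
#'
#' Computes the intersection area, union area and IoU of two corner-form
#' boxes. The intersection is clamped to zero unless the boxes genuinely
#' overlap (`x2I > x1I` and `y2I > y1I`), so touching or disjoint boxes give
#' exactly `I = 0`.
#'
#' @param pred,gt corner-form boxes ([bbox] or length-4 numeric `x1,y1,x2,y2`).
#' @return A list with `intersection_area`, `union_area`, `iou` and
#'   `degenerate` (TRUE when both boxes have zero area, in which case
#'   `iou = 0` is returned rather than 0/0).
#' @examples
#' iou_breakdown(bbox(0, 0, 10, 10), bbox(5, 5, 15, 15))$iou  # 1/7
#' @export
iou_breakdown <- function(pred, gt) {
  p <- as_box(pred, "pred"); g <- as_box(gt, "gt")
  x1i <- max(p[1], g[1]); x2i <- min(p[3], g[3])
  y1i <- max(p[2], g[2]); y2i <- min(p[4], g[4])
  I <- if (x2i > x1i && y2i > y1i) (x2i - x1i) * (y2i - y1i) else 0
  ap <- (p[3] - p[1]) * (p[4] - p[2])
  ag <- (g[3] - g[1]) * (g[4] - g[2])
  u <- ap + ag - I
  degenerate <- u <= 0
  list(intersection_area = I,
       union_area = u,
       iou = if (degenerate) 0 else I / u,
       degenerate = degenerate)
}

#' Vectorized IoU between paired rows of two box matrices
#' @param pred,gt n x 4 corner-form matrices (paired row-wise).
#' @return Numeric vector of IoU values; degenerate pairs give 0.
#' @export
iou_pairs <- function(pred, gt) {
  p <- as_box_matrix(pred, "pred"); g <- as_box_matrix(gt, "gt")
  xi <- pmin(p[, 3], g[, 3]) - pmax(p[, 1], g[, 1])
  yi <- pmin(p[, 4], g[, 4]) - pmax(p[, 2], g[, 2])
  I <- ifelse(xi > 0 & yi > 0, xi * yi, 0)
  u <- (p[, 3] - p[, 1]) * (p[, 4] - p[, 2]) +
       (g[, 3] - g[, 1]) * (g[, 4] - g[, 2]) - I
  ifelse(u > 0, I / u, 0)
}

#' All-pairs IoU matrix
#' @param a n x 4 and @param b m x 4 corner-form matrices.
#' @return n x m matrix of IoU values.
#' @export
iou_matrix <- function(a, b) {
  a <- as_box_matrix(a, "a"); b <- as_box_matrix(b, "b")
  n <- nrow(a); m <- nrow(b)
  xi <- pmin(matrix(a[, 3], n, m), matrix(b[, 3], n, m, byrow = TRUE)) -
        pmax(matrix(a[, 1], n, m), matrix(b[, 1], n, m, byrow = TRUE))
  yi <- pmin(matrix(a[, 4], n, m), matrix(b[, 4], n, m, byrow = TRUE)) -
        pmax(matrix(a[, 2], n, m), matrix(b[, 2], n, m, byrow = TRUE))
  I <- ifelse(xi > 0 & yi > 0, xi * yi, 0)
  u <- matrix((a[, 3] - a[, 1]) * (a[, 4] - a[, 2]), n, m) +
       matrix((b[, 3] - b[, 1]) * (b[, 4] - b[, 2]), n, m, byrow = TRUE) - I
  out <- ifelse(u > 0, I / u, 0)
  dim(out) <- c(n, m)
  out
}

# epsilon guarding the alpha denominator (1 - IoU + v) and c^2; the
# identical-box case would otherwise divide by zero.
.loss_eps <- 1e-7

#' Complete-IoU (CIoU) regression loss
#'
#' `L = 1 - IoU + rho^2 / c^2 + alpha * v`, where `rho^2` is the squared
#' distance between box centres, `c^2` the squared diagonal of the smallest
#' enclosing box, `v = (4 / pi^2) (atan(w_gt / h_gt) - atan(w / h))^2`
#' measures aspect-ratio mismatch and `alpha = v / (1 - IoU + v)` is its
#' trade-off weight. A zero-width or zero-height predicted box uses the
#' degenerate ratio limit `atan -> pi/2` (sign of the ratio) rather than
#' faulting; an epsilon (`1e-7`) guards the `alpha` denominator and `c^2`.
#'
#' @inheritParams iou_breakdown
#' @return A list with `iou`, `center_dist_sq`, `enclosing_diag_sq`, `v`,
#'   `alpha`, `loss`.
#' @examples
#' ciou_loss(bbox(0, 0, 10, 10), bbox(10, 0, 20, 10))$loss  # 1.2
#' @export
ciou_loss <- function(pred, gt) {
  p <- as_box(pred, "pred"); g <- as_box(gt, "gt")
  if ((g[3] - g[1]) * (g[4] - g[2]) <= 0)
    stop("ciou_loss: ground-truth box must have positive area")
  iou <- iou_breakdown(p, g)$iou
  rho2 <- ((p[1] + p[3]) / 2 - (g[1] + g[3]) / 2)^2 +
          ((p[2] + p[4]) / 2 - (g[2] + g[4]) / 2)^2
  c2 <- (max(p[3], g[3]) - min(p[1], g[1]))^2 +
        (max(p[4], g[4]) - min(p[2], g[2]))^2
  v <- ciou_v(p[3] - p[1], p[4] - p[2], g[3] - g[1], g[4] - g[2])
  alpha <- if (v == 0) 0 else v / (1 - iou + v + .loss_eps)
  list(iou = iou, center_dist_sq = rho2, enclosing_diag_sq = c2, v = v,
       alpha = alpha,
       loss = 1 - iou + rho2 / (c2 + .loss_eps) + alpha * v)
}

# Aspect-ratio term; atan(w/h) with h = 0 treated as the ratio limit pi/2.
ciou_v <- function(w, h, wg, hg) {
  ratio_atan <- function(w, h) {
    if (h > 0) atan(w / h) else if (w > 0) pi / 2 else 0
  }
  4 / pi^2 * (ratio_atan(wg, hg) - ratio_atan(w, h))^2
}

#' Minimum-point-distance IoU (MPDIoU) regression loss
#'
#' `MPDIoU = IoU - d1^2 / (h^2 + w^2) - d2^2 / (h^2 + w^2)` where `d1^2` and
#' `d2^2` are the squared distances between the two boxes' top-left and
#' bottom-right corners and `(w, h)` is the size of the image on which the
#' boxes live. The loss is `1 - MPDIoU`. For boxes contained in the image,
#' `MPDIoU` lies in `[-2, 1]` and the loss in `[0, 3]`; `MPDIoU <= IoU`
#' always, with equality only when both corner pairs coincide.
#'
#' @inheritParams iou_breakdown
#' @param image_w,image_h image width and height in pixels (positive). These
#'   should be the size of the tensor on which the boxes are expressed (the
#'   network input size during training).
#' @return A list with `iou`, `d1_sq`, `d2_sq`, `mpdiou`, `loss`.
#' @examples
#' mpdiou_loss(bbox(0, 0, 10, 10), bbox(5, 5, 15, 15), 20, 20)$mpdiou
#' @export
mpdiou_loss <- function(pred, gt, image_w, image_h) {
  if (!is.numeric(image_w) || !is.numeric(image_h) ||
      image_w <= 0 || image_h <= 0)
    stop("mpdiou_loss: image dimensions must be positive")
  p <- as_box(pred, "pred"); g <- as_box(gt, "gt")
  iou <- iou_breakdown(p, g)$iou
  d1 <- (p[1] - g[1])^2 + (p[2] - g[2])^2
  d2 <- (p[3] - g[3])^2 + (p[4] - g[4])^2
  D <- image_h^2 + image_w^2
  mpd <- iou - d1 / D - d2 / D
  list(iou = iou, d1_sq = unname(d1), d2_sq = unname(d2),
       mpdiou = unname(mpd), loss = unname(1 - mpd))
}

#' Batched CIoU / MPDIoU losses
#'
#' Vectorized over paired rows; agrees with the scalar forms element-wise.
#'
#' @param pred,gt n x 4 corner-form matrices, paired row-wise.
#' @param image_w,image_h image size (MPDIoU only).
#' @return Numeric vector of per-pair losses.
#' @export
mpdiou_loss_batch <- function(pred, gt, image_w, image_h) {
  if (image_w <= 0 || image_h <= 0)
    stop("mpdiou_loss_batch: image dimensions must be positive")
  p <- as_box_matrix(pred, "pred"); g <- as_box_matrix(gt, "gt")
  iou <- iou_pairs(p, g)
  D <- image_h^2 + image_w^2
  d1 <- (p[, 1] - g[, 1])^2 + (p[, 2] - g[, 2])^2
  d2 <- (p[, 3] - g[, 3])^2 + (p[, 4] - g[, 4])^2
  1 - (iou - d1 / D - d2 / D)
}

#' @rdname mpdiou_loss_batch
#' @export
ciou_loss_batch <- function(pred, gt) {
  p <- as_box_matrix(pred, "pred"); g <- as_box_matrix(gt, "gt")
  iou <- iou_pairs(p, g)
  rho2 <- ((p[, 1] + p[, 3]) - (g[, 1] + g[, 3]))^2 / 4 +
          ((p[, 2] + p[, 4]) - (g[, 2] + g[, 4]))^2 / 4
  c2 <- (pmax(p[, 3], g[, 3]) - pmin(p[, 1], g[, 1]))^2 +
        (pmax(p[, 4], g[, 4]) - pmin(p[, 2], g[, 2]))^2
  w <- p[, 3] - p[, 1]; h <- p[, 4] - p[, 2]
  wg <- g[, 3] - g[, 1]; hg <- g[, 4] - g[, 2]
  v <- 4 / pi^2 * (atan2(wg, hg) - atan2(w, h))^2
  alpha <- ifelse(v == 0, 0, v / (1 - iou + v + .loss_eps))
  1 - iou + rho2 / (c2 + .loss_eps) + alpha * v
}

## ---- analytic gradients (internal; used by the training loss) ----------

# d IoU / d pred for paired rows; subgradient convention: ties take the
# active branch of max/min.  Returns n x 4 matrix.
iou_grad_pairs <- function(p, g) {
  xi1 <- pmax(p[, 1], g[, 1]); xi2 <- pmin(p[, 3], g[, 3])
  yi1 <- pmax(p[, 2], g[, 2]); yi2 <- pmin(p[, 4], g[, 4])
  wI <- xi2 - xi1; hI <- yi2 - yi1
  live <- wI > 0 & hI > 0
  I <- ifelse(live, wI * hI, 0)
  ap <- (p[, 3] - p[, 1]) * (p[, 4] - p[, 2])
  ag <- (g[, 3] - g[, 1]) * (g[, 4] - g[, 2])
  u <- ap + ag - I
  wp <- p[, 3] - p[, 1]; hp <- p[, 4] - p[, 2]
  # dI/d pred coordinate (zero when that coordinate is not the active bound)
  dI <- cbind(ifelse(live & p[, 1] >= g[, 1], -hI, 0),
              ifelse(live & p[, 2] >= g[, 2], -wI, 0),
              ifelse(live & p[, 3] <= g[, 3],  hI, 0),
              ifelse(live & p[, 4] <= g[, 4],  wI, 0))
  dAp <- cbind(-hp, -wp, hp, wp)
  ok <- u > 0
  grad <- matrix(0, nrow(p), 4)
  iou <- ifelse(ok, I / u, 0)
  for (j in 1:4)
    grad[, j] <- ifelse(ok, (dI[, j] * u - I * (dAp[, j] - dI[, j])) / u^2, 0)
  list(iou = iou, grad = grad)
}

# d L_MPDIoU / d pred (n x 4); L = 1 - iou + (d1^2 + d2^2) / D
mpdiou_loss_grad <- function(p, g, image_w, image_h) {
  ig <- iou_grad_pairs(p, g)
  D <- image_h^2 + image_w^2
  dcorner <- 2 * (p - g) / D
  list(loss = 1 - (ig$iou - ((p[, 1] - g[, 1])^2 + (p[, 2] - g[, 2])^2 +
                             (p[, 3] - g[, 3])^2 + (p[, 4] - g[, 4])^2) / D),
       grad = -ig$grad + dcorner)
}

# d L_CIoU / d pred (n x 4); alpha treated as a constant (standard practice).
ciou_loss_grad <- function(p, g) {
  ig <- iou_grad_pairs(p, g)
  iou <- ig$iou
  cx <- (p[, 1] + p[, 3]) / 2; cy <- (p[, 2] + p[, 4]) / 2
  gx <- (g[, 1] + g[, 3]) / 2; gy <- (g[, 2] + g[, 4]) / 2
  rho2 <- (cx - gx)^2 + (cy - gy)^2
  cw <- pmax(p[, 3], g[, 3]) - pmin(p[, 1], g[, 1])
  ch <- pmax(p[, 4], g[, 4]) - pmin(p[, 2], g[, 2])
  c2 <- cw^2 + ch^2 + .loss_eps
  w <- p[, 3] - p[, 1]; h <- p[, 4] - p[, 2]
  wg <- g[, 3] - g[, 1]; hg <- g[, 4] - g[, 2]
  dth <- atan2(wg, hg) - atan2(w, h)
  v <- 4 / pi^2 * dth^2
  alpha <- ifelse(v == 0, 0, v / (1 - iou + v + .loss_eps))
  # rho^2 / c^2 term
  drho <- cbind((cx - gx), (cy - gy), (cx - gx), (cy - gy)) / c2
  dc2 <- cbind(ifelse(p[, 1] <= g[, 1], -2 * cw, 0),
               ifelse(p[, 2] <= g[, 2], -2 * ch, 0),
               ifelse(p[, 3] >= g[, 3],  2 * cw, 0),
               ifelse(p[, 4] >= g[, 4],  2 * ch, 0))
  dpen <- drho - (rho2 / c2^2) * dc2
  # alpha * v term: dv/d(w,h) via d atan2(w,h) = (h, -w)/(w^2+h^2)
  denom <- w^2 + h^2
  datan_w <- ifelse(denom > 0,  h / denom, 0)
  datan_h <- ifelse(denom > 0, -w / denom, 0)
  dv_w <- -8 / pi^2 * dth * datan_w
  dv_h <- -8 / pi^2 * dth * datan_h
  dv <- cbind(-dv_w, -dv_h, dv_w, dv_h)
  loss <- 1 - iou + rho2 / c2 + alpha * v
  list(loss = loss, grad = -ig$grad + dpen + alpha * dv)
}
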