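# Independent oracles used across the suite.

# Pixel-rasterization IoU for integer-coordinate boxes: count unit cells
# covered by each box and by both.
raster_iou <- function(a, b) {
  grid_max <- max(a[c(3, 4)], b[c(3, 4)])
  cells_a <- matrix(FALSE, grid_max, grid_max)
  cells_b <- cells_a
  if (a[3] > a[1] && a[4] > a[2])
    cells_a[(a[2] + 1):a[4], (a[1] + 1):a[3]] <- TRUE
  if (b[3] > b[1] && b[4] > b[2])
    cells_b[(b[2] + 1):b[4], (b[1] + 1):b[3]] <- TRUE
  I <- sum(cells_a & cells_b)
  U <- sum(cells_a | cells_b)
  if (U == 0) 0 else I / U
}

# Rank-by-rank average-precision oracle: walks the ranked list, records
# (recall, precision) points, and integrates with an explicit inner
# maximum instead of the envelope recursion.
ap_bruteforce <- function(conf, is_tp, n_gt) {
  if (n_gt == 0) return(NA_real_)
  if (!length(conf)) return(0)
  ord <- order(conf, decreasing = TRUE)
  is_tp <- is_tp[ord]
  rec <- cumsum(is_tp) / n_gt
  prec <- cumsum(is_tp) / seq_along(is_tp)
  ap <- 0
  prev_r <- 0
  for (k in seq_along(rec)) {
    dr <- rec[k] - prev_r
    if (dr > 0) ap <- ap + dr * max(prec[k:length(prec)])
    prev_r <- rec[k]
  }
  ap
}

# Random corner-form box within a w x h canvas.
random_box <- function(w = 100, h = 100, min_side = 0.5) {
  x <- sort(runif(2, 0, w)); y <- sort(runif(2, 0, h))
  if (x[2] - x[1] < min_side) x[2] <- min(x[1] + min_side, w)
  if (y[2] - y[1] < min_side) y[2] <- min(y[1] + min_side, h)
  c(x[1], y[1], x[2], y[2])
}

# Tiny random detection scenario for evaluation tests.
random_eval_case <- function(n_img = 3, n_classes = 3, seed = 1) {
  set.seed(seed)
  gts <- NULL; preds <- NULL
  for (im in seq_len(n_img)) {
    for (g in seq_len(sample(0:4, 1))) {
      b <- random_box(100, 100, 5)
      gts <- rbind(gts, data.frame(image_id = im,
                                   class = sample(n_classes, 1) - 1,
                                   x1 = b[1], y1 = b[2], x2 = b[3],
                                   y2 = b[4]))
    }
    for (p in seq_len(sample(0:6, 1))) {
      b <- random_box(100, 100, 5)
      preds <- rbind(preds, data.frame(image_id = im,
                                       class = sample(n_classes, 1) - 1,
                                       confidence = runif(1),
                                       x1 = b[1], y1 = b[2], x2 = b[3],
                                       y2 = b[4]))
    }
  }
  list(preds = preds, gts = gts)
}
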