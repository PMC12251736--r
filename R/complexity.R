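# Background-complexity metrics: colour-histogram entropy, dominant-colour
# proportion, and Canny edge density, with a thresholded simple/complex
# classification.

# 2-D convolution with replicate (clamped) border padding — symmetric under
# mirroring and 90-degree rotation, which keeps the edge metrics invariant
# to those transforms.
conv2_replicate <- function(m, k) {
  kh <- nrow(k); kw <- ncol(k)
  oh <- (kh - 1L) %/% 2L; ow <- (kw - 1L) %/% 2L
  H <- nrow(m); W <- ncol(m)
  out <- matrix(0, H, W)
  for (i in seq_len(kh)) {
    ri <- pmin(pmax(seq_len(H) + i - 1L - oh, 1L), H)
    for (j in seq_len(kw)) {
      ci <- pmin(pmax(seq_len(W) + j - 1L - ow, 1L), W)
      if (k[i, j] != 0) out <- out + k[i, j] * m[ri, ci]
    }
  }
  out
}

# Canny-style edge map on a [0,1] grayscale matrix: 3x3 Gaussian smoothing,
# Sobel gradients, orientation-quantized non-maximum suppression, and
# double-threshold hysteresis (low/high on the 8-bit gradient-magnitude
# scale, 8-connected linking).
canny_edges <- function(gray, low = 100, high = 200) {
  g <- conv2_replicate(gray, matrix(c(1, 2, 1, 2, 4, 2, 1, 2, 1) / 16, 3, 3))
  gx <- conv2_replicate(g, matrix(c(-1, -2, -1, 0, 0, 0, 1, 2, 1), 3, 3))
  gy <- conv2_replicate(g, t(matrix(c(-1, -2, -1, 0, 0, 0, 1, 2, 1), 3, 3)))
  mag <- sqrt(gx^2 + gy^2) * 255            # 8-bit magnitude scale
  ang <- atan2(gy, gx)                       # quantize to 4 directions
  dir <- (round(ang / (pi / 4)) %% 4)
  H <- nrow(mag); W <- ncol(mag)
  shift <- function(m, dy, dx) {
    ri <- pmin(pmax(seq_len(H) + dy, 1L), H)
    ci <- pmin(pmax(seq_len(W) + dx, 1L), W)
    m[ri, ci]
  }
  # gx is the vertical (row) derivative here, so direction 0 compares
  # along rows; the pairs below are the two neighbours along the gradient.
  n1 <- shift(mag, 1L, 0L);  n2 <- shift(mag, -1L, 0L)
  m1 <- shift(mag, 1L, 1L);  m2 <- shift(mag, -1L, -1L)
  p1 <- shift(mag, 0L, 1L);  p2 <- shift(mag, 0L, -1L)
  q1 <- shift(mag, -1L, 1L); q2 <- shift(mag, 1L, -1L)
  keep <- (dir == 0 & mag >= n1 & mag >= n2) |
          (dir == 1 & mag >= m1 & mag >= m2) |
          (dir == 2 & mag >= p1 & mag >= p2) |
          (dir == 3 & mag >= q1 & mag >= q2)
  thin <- mag * keep
  strong <- thin >= high
  weak <- thin >= low & !strong
  # hysteresis: grow strong edges through connected weak pixels
  edges <- strong
  repeat {
    grow <- weak & (shift(edges, 1, 0) | shift(edges, -1, 0) |
                    shift(edges, 0, 1) | shift(edges, 0, -1) |
                    shift(edges, 1, 1) | shift(edges, 1, -1) |
                    shift(edges, -1, 1) | shift(edges, -1, -1))
    if (!any(grow & !edges)) break
    edges <- edges | grow
    weak <- weak & !grow
  }
  edges
}

#' Background-complexity metrics of an image
#'
#' Quantizes the RGB cube into `bins^3` colour cells and reports the
#' Shannon entropy (bits) of the colour histogram, the proportion of
#' pixels in the most frequent colour cell, and the proportion of edge
#' pixels found by a Canny-style detector (3x3 Gaussian smoothing, Sobel
#' gradients, non-maximum suppression, double-threshold hysteresis at
#' `edge_low`/`edge_high` on the 8-bit gradient scale).
#'
#' @param image `[H, W, 3]` array in `[0, 1]` (at least 8x8), or a PNG path.
#' @param bins per-channel quantization levels (default 4, i.e. 64 colour
#'   cells).
#' @param edge_low,edge_high hysteresis thresholds (default 100/200).
#' @return A `complexity_report` list with `entropy_bits`,
#'   `color_proportion`, `edge_proportion` and `label` (NA until
#'   [classify_background()] sets it).
#' @export
complexity_metrics <- function(image, bins = 4L, edge_low = 100,
                               edge_high = 200) {
  if (is.character(image)) image <- read_image(image)
  d <- dim(image)
  if (length(d) != 3L || d[3] < 3L)
    stop("complexity_metrics: image must be an RGB [H, W, 3] array")
  if (d[1] < 8L || d[2] < 8L)
    stop("complexity_metrics: image must be at least 8x8")
  q <- function(ch) pmin(floor(ch * bins), bins - 1L)
  cell <- q(image[, , 1]) + bins * q(image[, , 2]) + bins^2 * q(image[, , 3])
  counts <- tabulate(as.integer(cell) + 1L, nbins = bins^3)
  p <- counts[counts > 0] / sum(counts)
  entropy <- -sum(p * log2(p))
  color_prop <- max(counts) / sum(counts)
  gray <- 0.299 * image[, , 1] + 0.587 * image[, , 2] + 0.114 * image[, , 3]
  edges <- canny_edges(gray, edge_low, edge_high)
  structure(list(entropy_bits = entropy,
                 color_proportion = color_prop,
                 edge_proportion = mean(edges),
                 label = NA_character_,
                 bins = bins),
            class = "complexity_report")
}

#' Classify an image background as simple or complex
#'
#' The decision rule treats each condition as independently sufficient for
#' a simple background: dominant-colour proportion above
#' `color_proportion_min` (default 60%) or edge proportion below
#' `edge_proportion_max` (default 1.5%); otherwise the background is
#' complex. Entropy is reported alongside but carries no threshold.
#'
#' @inheritParams complexity_metrics
#' @param color_proportion_min dominant-colour threshold, fraction.
#' @param edge_proportion_max edge-density threshold, fraction.
#' @return A `complexity_report` with the `label` field set.
#' @export
classify_background <- function(image, color_proportion_min = 0.60,
                                edge_proportion_max = 0.015, bins = 4L,
                                edge_low = 100, edge_high = 200) {
  stopifnot(color_proportion_min > 0, color_proportion_min < 1,
            edge_proportion_max > 0, edge_proportion_max < 1)
  rep <- complexity_metrics(image, bins, edge_low, edge_high)
  rep$label <- if (rep$color_proportion > color_proportion_min ||
                   rep$edge_proportion < edge_proportion_max)
    "simple" else "complex"
  rep
}

#' @export
print.complexity_report <- function(x, ...) {
  cat(sprintf(
    "<complexity: entropy %.3f bits, dominant colour %.1f%%, edges %.2f%%%s>\n",
    x$entropy_bits, 100 * x$color_proportion, 100 * x$edge_proportion,
    if (is.na(x$label)) "" else paste0(", ", x$label)))
  invisible(x)
}

#' Batch background-complexity report for a directory of images
#'
#' @param input_dir directory of PNG images.
#' @param ... thresholds passed to [classify_background()].
#' @return A data.frame with one row per image: `path, entropy_bits,
#'   color_proportion, edge_proportion, label`.
#' @export
complexity_report <- function(input_dir, ...) {
  files <- sort(list.files(input_dir, pattern = "\\.png$",
                           full.names = TRUE))
  rows <- lapply(files, function(f) {
    r <- classify_background(f, ...)
    data.frame(path = f, entropy_bits = r$entropy_bits,
               color_proportion = r$color_proportion,
               edge_proportion = r$edge_proportion, label = r$label)
  })
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}
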