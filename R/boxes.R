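#' Axis-aligned bounding box in corner form
#'
#' Constructs a corner-form box `(x1, y1, x2, y2)` in continuous pixel
#' coordinates. Corner form is the canonical representation throughout the
#' package; conversions from the normalized YOLO centre form are explicit
#' via [yolo_to_corners()] / [corners_to_yolo()].
#'
#' @param x1,y1 top-left corner (pixels).
#' @param x2,y2 bottom-right corner (pixels); requires `x2 >= x1`, `y2 >= y1`.
#' @return A numeric vector of class `bbox` with elements `x1, y1, x2, y2`.
#' @examples
#' b <- bbox(0, 0, 10, 10)
#' bbox_area(b)
#' @export
bbox <- function(x1, y1, x2, y2) {
  b <- c(x1 = as.numeric(x1), y1 = as.numeric(y1),
         x2 = as.numeric(x2), y2 = as.numeric(y2))
  if (anyNA(b)) stop("bbox: coordinates must be finite numbers")
  if (b[3] < b[1] || b[4] < b[2])
    stop("bbox: corner-form invariant violated (x2 >= x1 and y2 >= y1)")
  class(b) <- "bbox"
  b
}

#' @export
print.bbox <- function(x, ...) {
  cat(sprintf("<bbox (%.6g, %.6g) -- (%.6g, %.6g)  w=%.6g h=%.6g>\n",
              x[1], x[2], x[3], x[4], x[3] - x[1], x[4] - x[2]))
  invisible(x)
}

#' @rdname bbox
#' @param b a `bbox` or length-4 numeric.
#' @export
bbox_area <- function(b) (b[[3]] - b[[1]]) * (b[[4]] - b[[2]])

# Coerce scalar box input (bbox object or length-4 vector) to numeric.
as_box <- function(b, arg = "box") {
  b <- as.numeric(b)
  if (length(b) != 4L || anyNA(b))
    stop(sprintf("%s must be a length-4 numeric (x1, y1, x2, y2)", arg))
  if (b[3] < b[1] || b[4] < b[2])
    stop(sprintf("%s violates the corner-form invariant", arg))
  b
}

# Coerce batched box input to an n x 4 matrix (columns x1, y1, x2, y2).
as_box_matrix <- function(b, arg = "boxes") {
  if (is.null(dim(b))) b <- matrix(as.numeric(b), ncol = 4L, byrow = TRUE)
  b <- as.matrix(b)
  if (ncol(b) != 4L) stop(sprintf("%s must have 4 columns", arg))
  storage.mode(b) <- "double"
  b
}

#' Convert between YOLO centre form and corner form
#'
#' YOLO label files store `(cx, cy, w, h)` normalized to `[0, 1]` by the
#' image size. These helpers convert to and from pixel corner form.
#'
#' @param m matrix (or vector) with columns `cx, cy, w, h` (normalized) for
#'   `yolo_to_corners`, or `x1, y1, x2, y2` (pixels) for `corners_to_yolo`.
#' @param image_w,image_h image width and height in pixels.
#' @return A matrix with 4 columns in the target representation.
#' @export
yolo_to_corners <- function(m, image_w, image_h) {
  m <- as_box_matrix_raw(m)
  cx <- m[, 1] * image_w; cy <- m[, 2] * image_h
  w <- m[, 3] * image_w;  h <- m[, 4] * image_h
  cbind(x1 = cx - w / 2, y1 = cy - h / 2, x2 = cx + w / 2, y2 = cy + h / 2)
}

#' @rdname yolo_to_corners
#' @export
corners_to_yolo <- function(m, image_w, image_h) {
  m <- as_box_matrix_raw(m)
  cbind(cx = (m[, 1] + m[, 3]) / 2 / image_w,
        cy = (m[, 2] + m[, 4]) / 2 / image_h,
        w = (m[, 3] - m[, 1]) / image_w,
        h = (m[, 4] - m[, 2]) / image_h)
}

as_box_matrix_raw <- function(m) {
  if (is.null(dim(m))) m <- matrix(as.numeric(m), ncol = 4L, byrow = TRUE)
  m <- as.matrix(m)
  if (ncol(m) != 4L) stop("expected 4 columns")
  storage.mode(m) <- "double"
  m
}

#' Clip boxes to image bounds
#' @param m n x 4 corner-form matrix.
#' @param image_w,image_h image size in pixels.
#' @return Clipped matrix.
#' @export
clip_boxes <- function(m, image_w, image_h) {
  m <- as_box_matrix_raw(m)
  m[, c(1, 3)] <- pmin(pmax(m[, c(1, 3)], 0), image_w)
  m[, c(2, 4)] <- pmin(pmax(m[, c(2, 4)], 0), image_h)
  m
}
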