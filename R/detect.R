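# Inference: decode the head outputs, threshold, suppress, clip.

#' Greedy non-maximum suppression
#'
#' Standard class-wise greedy NMS: detections are visited in decreasing
#' confidence order and any later same-class detection overlapping a kept
#' one with IoU above `iou_thr` is discarded.
#'
#' @param boxes n x 4 corner-form matrix.
#' @param scores numeric confidences.
#' @param classes integer class ids (same-class suppression only); omit for
#'   class-agnostic NMS.
#' @param iou_thr overlap threshold (default 0.45).
#' @return Integer indices of the kept detections, in confidence order.
#' @export
nms <- function(boxes, scores, classes = NULL, iou_thr = 0.45) {
  boxes <- as_box_matrix_raw(boxes)
  n <- nrow(boxes)
  if (n == 0L) return(integer(0))
  if (is.null(classes)) classes <- rep(0L, n)
  ord <- order(scores, decreasing = TRUE)
  keep <- integer(0)
  alive <- rep(TRUE, n)
  for (i in ord) {
    if (!alive[i]) next
    keep <- c(keep, i)
    rest <- ord[alive[ord] & classes[ord] == classes[i] & ord != i]
    if (length(rest)) {
      ious <- iou_matrix(boxes[rest, , drop = FALSE],
                         boxes[i, , drop = FALSE])[, 1]
      alive[rest[ious > iou_thr]] <- FALSE
    }
    alive[i] <- FALSE
  }
  keep
}

# Decode all levels of a single-sample head output into candidate
# detections (corner boxes in input pixels + per-class scores).
decode_predictions <- function(preds, reg_max, strides = c(8L, 16L, 32L)) {
  boxes <- NULL; scores <- NULL
  for (li in seq_along(preds)) {
    d <- dim(preds[[li]]$box)
    hw <- d[1] * d[2]
    zb <- preds[[li]]$box
    dim(zb) <- c(hw, d[3])
    zc <- preds[[li]]$cls
    dim(zc) <- c(hw, dim(preds[[li]]$cls)[3])
    an <- anchor_centers(d[1], d[2], strides[li])
    dec <- decode_dists(zb, reg_max)
    boxes <- rbind(boxes, dist_to_boxes(dec$dist, an, strides[li]))
    scores <- rbind(scores, sigmoid(zc))
  }
  list(boxes = boxes, scores = scores)
}

#' Run detection on one image
#'
#' Resizes the image to the model's input size, runs a forward pass,
#' decodes the anchor-free head, applies the confidence threshold and
#' class-wise NMS, and returns boxes in the original image's pixel
#' coordinates, clipped to its bounds and sorted by confidence.
#'
#' @param model a trained `leaf_model`.
#' @param image `[H, W, 3]` array in `[0, 1]`, or a PNG file path.
#' @param conf_thr minimum class confidence (default 0.25).
#' @param iou_thr NMS overlap threshold (default 0.45).
#' @return A data.frame with `x1, y1, x2, y2, class_id, confidence`
#'   (class ids are 0-based, as in YOLO label files).
#' @export
detect <- function(model, image, conf_thr = 0.25, iou_thr = 0.45) {
  if (is.character(image)) image <- read_image(image)
  h0 <- dim(image)[1]; w0 <- dim(image)[2]
  sz <- model$cfg$input_size
  x <- resize_image(image, sz, sz)
  preds <- model_forward(model, array(x, c(sz, sz, 3, 1)), training = FALSE)
  dec <- decode_predictions(preds, model$cfg$reg_max)
  conf <- rowmax(dec$scores)
  cls <- max.col(dec$scores, "first") - 1L
  sel <- which(conf >= conf_thr)
  empty <- data.frame(x1 = numeric(0), y1 = numeric(0), x2 = numeric(0),
                      y2 = numeric(0), class_id = integer(0),
                      confidence = numeric(0))
  if (!length(sel)) return(empty)
  boxes <- dec$boxes[sel, , drop = FALSE]
  keep <- nms(boxes, conf[sel], cls[sel], iou_thr)
  boxes <- boxes[keep, , drop = FALSE]
  # map back to original resolution and clip
  boxes[, c(1, 3)] <- boxes[, c(1, 3)] * w0 / sz
  boxes[, c(2, 4)] <- boxes[, c(2, 4)] * h0 / sz
  boxes <- clip_boxes(boxes, w0, h0)
  data.frame(x1 = boxes[, 1], y1 = boxes[, 2], x2 = boxes[, 3],
             y2 = boxes[, 4], class_id = cls[sel][keep],
             confidence = conf[sel][keep])
}

#' Nearest-neighbour image resize
#' @param img `[H, W, C]` array; @param h,w target size.
#' @return Resized array.
#' @export
resize_image <- function(img, h, w) {
  d <- dim(img)
  if (d[1] == h && d[2] == w) return(img)
  ri <- pmin(pmax(ceiling(seq_len(h) / h * d[1]), 1L), d[1])
  ci <- pmin(pmax(ceiling(seq_len(w) / w * d[2]), 1L), d[2])
  img[ri, ci, , drop = FALSE]
}
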