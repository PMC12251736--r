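# Composite detection loss: distribution-decoded box regression
# (CIoU or MPDIoU), binary cross-entropy classification, and the
# distribution-focal term, over a static centre-prior + top-k assignment.

# Anchor centres (input-pixel coords) of an Hl x Wl grid at the given
# stride, in the [HW] cell order of the flattened feature map (row index
# fastest, matching R's column-major array layout).
anchor_centers <- function(hl, wl, stride) {
  cy <- (seq_len(hl) - 0.5) * stride
  cx <- (seq_len(wl) - 0.5) * stride
  cbind(x = rep(cx, each = hl), y = rep(cy, times = wl))
}

rowmax <- function(m) m[cbind(seq_len(nrow(m)), max.col(m, "first"))]

# Softmax-expectation decode of one sample's box logits at one level.
# z: [HW, 4R] matrix.  Returns prob [HW, 4R] and dist [HW, 4]
# (stride units; side order left, top, right, bottom).
decode_dists <- function(z, reg_max) {
  hw <- nrow(z)
  bins <- 0:(reg_max - 1)
  prob <- z
  dist <- matrix(0, hw, 4L)
  for (s in 1:4) {
    idx <- ((s - 1L) * reg_max + 1L):(s * reg_max)
    zs <- z[, idx, drop = FALSE]
    ez <- exp(zs - rowmax(zs))
    p <- ez / rowSums(ez)
    prob[, idx] <- p
    dist[, s] <- p %*% bins
  }
  list(prob = prob, dist = dist)
}

# Decoded corner boxes (input pixels) from distances at anchors.
dist_to_boxes <- function(dist, anchors, stride) {
  cbind(anchors[, 1] - dist[, 1] * stride,
        anchors[, 2] - dist[, 2] * stride,
        anchors[, 1] + dist[, 3] * stride,
        anchors[, 2] + dist[, 4] * stride)
}

# Static centre-prior + top-k assignment of ground-truth boxes to grid
# cells.  For one image: gt is an n x 5 matrix (class, x1, y1, x2, y2 in
# input pixels).  A cell is a candidate for a GT when its anchor centre
# lies inside the GT box and all four side distances are representable
# within the distribution range; candidates are ranked by the IoU between
# the GT and a square prior box of side 5*stride centred on the anchor,
# and the best k kept per GT.  A cell claimed by several GTs goes to the
# one with the higher ranking metric.  The assignment depends only on the
# geometry, never on the predictions, so toggling the box-loss kind leaves
# it unchanged.
assign_targets <- function(gt, levels, reg_max, topk = 10L) {
  out <- list()
  if (is.null(gt) || nrow(gt) == 0L) return(out)
  cand <- NULL
  for (li in seq_along(levels)) {
    lv <- levels[[li]]
    an <- lv$anchors; s <- lv$stride
    for (g in seq_len(nrow(gt))) {
      b <- gt[g, 2:5]
      inside <- an[, 1] > b[1] & an[, 1] < b[3] & an[, 2] > b[2] & an[, 2] < b[4]
      if (!any(inside)) next
      ids <- which(inside)
      l <- (an[ids, 1] - b[1]) / s; t <- (an[ids, 2] - b[2]) / s
      r <- (b[3] - an[ids, 1]) / s; bt <- (b[4] - an[ids, 2]) / s
      ok <- pmax(l, t, r, bt) < reg_max - 1 + 1e-9
      ids <- ids[ok]
      if (!length(ids)) next
      prior <- cbind(an[ids, 1] - 2.5 * s, an[ids, 2] - 2.5 * s,
                     an[ids, 1] + 2.5 * s, an[ids, 2] + 2.5 * s)
      metric <- iou_pairs(prior, matrix(b, length(ids), 4, byrow = TRUE))
      cand <- rbind(cand, cbind(level = li, cell = ids, gt = g,
                                metric = metric))
    }
  }
  if (is.null(cand)) return(out)
  # keep top-k per GT, then resolve cell conflicts by metric
  keep <- unlist(lapply(split(seq_len(nrow(cand)), cand[, "gt"]), function(ix) {
    ix[order(cand[ix, "metric"], decreasing = TRUE)][
      seq_len(min(topk, length(ix)))]
  }))
  cand <- cand[keep, , drop = FALSE]
  key <- paste(cand[, "level"], cand[, "cell"])
  best <- tapply(seq_len(nrow(cand)), key, function(ix)
    ix[which.max(cand[ix, "metric"])])
  cand[unlist(best), , drop = FALSE]
}

#' Composite detection loss
#'
#' Computes the weighted sum of the box-regression loss (mean CIoU or
#' MPDIoU over assigned prediction/target pairs, per the configured
#' `box_loss_kind`), the binary cross-entropy classification loss, and the
#' distribution-focal loss over the decoded side distances. MPDIoU is
#' normalized by the squared diagonal of the network input
#' (`input_size^2 * 2`), the tensor on which the boxes are expressed.
#'
#' @param preds head outputs from [model_forward()].
#' @param targets list (length batch) of per-image label matrices with
#'   columns `class, cx, cy, w, h` (YOLO-normalized), or a single matrix
#'   for a batch of one.
#' @param cfg the [model_config()] used to build the model.
#' @param input_size pixel size of the network input the predictions refer
#'   to (defaults to the config's).
#' @return A list with `box_loss`, `cls_loss`, `dfl_loss` and `total`
#'   (`total = w_box*box + w_cls*cls + w_dfl*dfl` with the configured
#'   weights).
#' @export
compute_detection_loss <- function(preds, targets, cfg,
                                   input_size = NULL) {
  detection_loss_full(preds, targets, cfg, input_size)$breakdown
}

# Full version returning head-output gradients for the training loop.
detection_loss_full <- function(preds, targets, cfg, input_size = NULL) {
  if (is.null(input_size)) input_size <- cfg$input_size
  if (is.matrix(targets) || is.data.frame(targets)) targets <- list(targets)
  R <- cfg$reg_max
  nc <- cfg$num_classes
  wts <- cfg$loss_weights
  strides <- c(8L, 16L, 32L)
  nlv <- length(preds)
  N <- dim(preds[[1]]$box)[4]
  levels <- lapply(seq_len(nlv), function(li) {
    d <- dim(preds[[li]]$box)
    list(h = d[1], w = d[2], stride = strides[li],
         anchors = anchor_centers(d[1], d[2], strides[li]))
  })
  dy <- lapply(seq_len(nlv), function(li)
    list(box = array(0, dim(preds[[li]]$box)),
         cls = array(0, dim(preds[[li]]$cls))))
  box_sum <- 0; dfl_sum <- 0; cls_sum <- 0; npos_tot <- 0L

  per_img <- vector("list", N)
  for (n in seq_len(N)) {
    gt <- targets[[n]]
    gtm <- NULL
    if (!is.null(gt) && NROW(gt) > 0) {
      gt <- as.matrix(gt)
      corners <- yolo_to_corners(gt[, 2:5, drop = FALSE],
                                 input_size, input_size)
      gtm <- cbind(gt[, 1], corners)
    }
    per_img[[n]] <- assign_targets(gtm, levels, R)
    attr(per_img[[n]], "gtm") <- gtm
  }
  npos_tot <- sum(vapply(per_img, NROW, 0L))
  norm_pos <- max(npos_tot, 1L)

  for (n in seq_len(N)) {
    asn <- per_img[[n]]
    gtm <- attr(asn, "gtm")
    for (li in seq_len(nlv)) {
      lv <- levels[[li]]
      hw <- lv$h * lv$w
      zbox <- preds[[li]]$box[, , , n]
      dim(zbox) <- c(hw, 4L * R)
      zcls <- preds[[li]]$cls[, , , n]
      dim(zcls) <- c(hw, nc)
      pcls <- sigmoid(zcls)
      tgt <- matrix(0, hw, nc)
      rows <- if (NROW(asn)) which(asn[, "level"] == li) else integer(0)
      dcls <- pcls # gradient of summed BCE wrt logits is p - t
      if (length(rows)) {
        cells <- asn[rows, "cell"]
        gids <- asn[rows, "gt"]
        tgt[cbind(cells, gtm[gids, 1] + 1L)] <- 1
        dcls <- pcls - tgt
        dec <- decode_dists(zbox[cells, , drop = FALSE], R)
        pb <- dist_to_boxes(dec$dist, lv$anchors[cells, , drop = FALSE],
                            lv$stride)
        gb <- gtm[gids, 2:5, drop = FALSE]
        bl <- if (cfg$box_loss_kind == "mpdiou")
          mpdiou_loss_grad(pb, gb, input_size, input_size)
        else ciou_loss_grad(pb, gb)
        box_sum <- box_sum + sum(bl$loss)
        # chain: corners -> distances (x1 = ax - l*s etc.)
        ddist <- cbind(-bl$grad[, 1], -bl$grad[, 2],
                       bl$grad[, 3], bl$grad[, 4]) * lv$stride
        # distribution-focal term on the same cells
        tdist <- cbind((lv$anchors[cells, 1] - gb[, 1]) / lv$stride,
                       (lv$anchors[cells, 2] - gb[, 2]) / lv$stride,
                       (gb[, 3] - lv$anchors[cells, 1]) / lv$stride,
                       (gb[, 4] - lv$anchors[cells, 2]) / lv$stride)
        tdist <- pmin(pmax(tdist, 0), R - 1 - 1e-3)
        dzb <- matrix(0, length(cells), 4L * R)
        for (s in 1:4) {
          idx <- ((s - 1L) * R + 1L):(s * R)
          p <- dec$prob[, idx, drop = FALSE]
          # box-loss gradient through the softmax expectation
          dzb[, idx] <- p * (matrix(0:(R - 1), length(cells), R,
                                    byrow = TRUE) - dec$dist[, s]) *
            ddist[, s] * (wts["box"] / norm_pos)
          # two-hot distribution-focal cross-entropy
          lo <- floor(tdist[, s]); hi <- lo + 1
          wl <- hi - tdist[, s]; wh <- tdist[, s] - lo
          tl <- matrix(0, length(cells), R)
          tl[cbind(seq_along(cells), lo + 1L)] <- wl
          tl[cbind(seq_along(cells), pmin(hi, R - 1) + 1L)] <-
            tl[cbind(seq_along(cells), pmin(hi, R - 1) + 1L)] + wh
          dfl_sum <- dfl_sum - sum(tl * log(pmax(p, 1e-12)))
          dzb[, idx] <- dzb[, idx] + (p - tl) * (wts["dfl"] / (4 * norm_pos))
        }
        db <- dy[[li]]$box[, , , n]
        dim(db) <- c(hw, 4L * R)
        db[cells, ] <- dzb
        dy[[li]]$box[, , , n] <- array(db, c(lv$h, lv$w, 4L * R))
      }
      cls_sum <- cls_sum -
        sum(tgt * log(pmax(pcls, 1e-12)) +
            (1 - tgt) * log(pmax(1 - pcls, 1e-12)))
      dy[[li]]$cls[, , , n] <- array(dcls * (wts["cls"] / norm_pos),
                                     c(lv$h, lv$w, nc))
    }
  }
  breakdown <- list(box_loss = box_sum / norm_pos,
                    cls_loss = cls_sum / norm_pos,
                    dfl_loss = dfl_sum / (4 * norm_pos),
                    npos = npos_tot)
  breakdown$total <- unname(wts["box"] * breakdown$box_loss +
                            wts["cls"] * breakdown$cls_loss +
                            wts["dfl"] * breakdown$dfl_loss)
  list(breakdown = breakdown, dy = dy)
}
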