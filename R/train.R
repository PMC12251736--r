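# CPU-scale training: SGD with momentum and weight decay over the layer
# graph, with per-epoch validation mAP@0.5.

sgd_step <- function(params, lr, momentum = 0.937, weight_decay = 5e-4) {
  for (p in params) {
    g <- p$grad
    if (p$decay) g <- g + weight_decay * p$value
    p$mom <- momentum * p$mom + g
    p$value <- p$value - lr * p$mom
    p$grad[] <- 0
  }
}

#' Toy training preset
#'
#' A reduced configuration sized for a single CPU: width multiplier 0.125,
#' 160-pixel inputs, otherwise the standard topology. Pass
#' `variant = "yolo-ssm"` for the SSPDConv/ESPPFCSPC/MPDIoU variant.
#'
#' @param num_classes number of classes.
#' @param variant `"yolov8n"` or `"yolo-ssm"`.
#' @param input_size toy input size (default 160).
#' @return A [model_config()].
#' @export
toy_config <- function(num_classes = 3L, variant = c("yolov8n", "yolo-ssm"),
                       input_size = 160L) {
  variant <- match.arg(variant)
  f <- if (variant == "yolo-ssm") yolo_ssm_config else yolov8n_config
  f(num_classes = num_classes, input_size = input_size,
    width_multiple = 0.125)
}

#' Train a detector on a YOLO-layout dataset
#'
#' Stochastic gradient descent with momentum 0.937 and weight decay 5e-4
#' (the standard single-stage detector schedule), initial learning rate
#' `lr0` with a short linear warmup and cosine decay to `lr0/100`. The run
#' is fully seeded: identical `(dataset, cfg, epochs, seed)` give identical
#' loss trajectories. Validation mAP@0.5 is computed each `eval_every`
#' epochs on the `val` split.
#'
#' @param dataset_dir dataset root containing `dataset.yaml`, `images/`,
#'   `labels/` (see [generate_dataset()]).
#' @param cfg a [model_config()]; its `num_classes` must match the data.
#' @param epochs training epochs.
#' @param seed RNG seed controlling init and batch shuffling.
#' @param batch_size images per SGD step.
#' @param lr0 initial learning rate.
#' @param eval_every validate every this many epochs (0 = only at the end).
#' @param conf_thr,iou_thr inference thresholds for validation.
#' @param verbose print per-epoch progress.
#' @return A `train_report` list: `model`, per-epoch `epoch_loss` (and the
#'   box/cls/dfl components), `map50` (final validation), `map50_history`,
#'   and the resolved schedule.
#' @export
toy_train <- function(dataset_dir, cfg, epochs = 10L, seed = 0L,
                      batch_size = 8L, lr0 = 0.01, eval_every = 0L,
                      conf_thr = 0.25, iou_thr = 0.45, verbose = FALSE) {
  tr <- split_files(dataset_dir, "train")
  if (!length(tr$images)) stop("toy_train: empty training split")
  if (tr$nc != cfg$num_classes)
    stop(sprintf("dataset has %d classes but the config %d", tr$nc,
                 cfg$num_classes))
  set.seed(seed)
  model <- build_model(cfg, seed = seed)
  params <- model_parameters(model)
  sz <- cfg$input_size
  n_img <- length(tr$images)
  labels <- lapply(tr$labels, read_yolo_labels)
  steps_per_epoch <- ceiling(n_img / batch_size)
  total_steps <- epochs * steps_per_epoch
  warmup <- min(3L * steps_per_epoch, max(total_steps %/% 10L, 1L))
  epoch_loss <- numeric(epochs)
  comp <- matrix(0, epochs, 3, dimnames = list(NULL, c("box", "cls", "dfl")))
  map_hist <- data.frame(epoch = integer(0), map50 = numeric(0))
  step <- 0L
  for (ep in seq_len(epochs)) {
    ord <- sample.int(n_img)
    losses <- NULL
    for (bi in seq_len(steps_per_epoch)) {
      ids <- ord[((bi - 1L) * batch_size + 1L):min(bi * batch_size, n_img)]
      xb <- array(0, c(sz, sz, 3, length(ids)))
      for (k in seq_along(ids))
        xb[, , , k] <- resize_image(read_image(tr$images[ids[k]]), sz, sz)
      step <- step + 1L
      lr <- if (step <= warmup) lr0 * step / warmup
            else lr0 * (0.01 + 0.99 * 0.5 *
                        (1 + cos(pi * (step - warmup) /
                                 max(total_steps - warmup, 1))))
      preds <- model_forward(model, xb, training = TRUE)
      lf <- detection_loss_full(preds, labels[ids], cfg, sz)
      model_backward(model, lf$dy)
      sgd_step(params, lr)
      losses <- rbind(losses, c(lf$breakdown$total, lf$breakdown$box_loss,
                                lf$breakdown$cls_loss, lf$breakdown$dfl_loss))
    }
    epoch_loss[ep] <- mean(losses[, 1])
    comp[ep, ] <- colMeans(losses[, 2:4, drop = FALSE])
    if (verbose)
      message(sprintf("epoch %d/%d  loss %.3f (box %.3f cls %.3f dfl %.3f)",
                      ep, epochs, epoch_loss[ep], comp[ep, 1], comp[ep, 2],
                      comp[ep, 3]))
    if (eval_every > 0L && ep %% eval_every == 0L) {
      m <- validate_map(model, dataset_dir, "val", conf_thr, iou_thr)
      map_hist <- rbind(map_hist, data.frame(epoch = ep, map50 = m))
      if (verbose) message(sprintf("  val mAP@0.5 = %.3f", m))
    }
  }
  map50 <- validate_map(model, dataset_dir, "val", conf_thr, iou_thr)
  structure(list(model = model, epoch_loss = epoch_loss, components = comp,
                 map50 = map50, map50_history = map_hist, epochs = epochs,
                 seed = seed, lr0 = lr0, batch_size = batch_size),
            class = "train_report")
}

#' @export
print.train_report <- function(x, ...) {
  cat(sprintf("<train_report: %d epochs, loss %.3f -> %.3f, val mAP@0.5 %.3f>\n",
              x$epochs, x$epoch_loss[1], x$epoch_loss[x$epochs], x$map50))
  invisible(x)
}

#' Validation mAP@0.5 of a model on a dataset split
#'
#' Runs [detect()] over the split and scores against the labels with
#' [evaluate_detections()].
#'
#' @param model a `leaf_model`; @param dataset_dir dataset root;
#' @param split split name; @param conf_thr,iou_thr inference thresholds.
#' @return The mAP@0.5 as a fraction in `[0, 1]`.
#' @export
validate_map <- function(model, dataset_dir, split = "val",
                         conf_thr = 0.25, iou_thr = 0.45) {
  fl <- split_files(dataset_dir, split)
  if (!length(fl$images)) return(NA_real_)
  preds <- NULL; gts <- NULL
  for (i in seq_along(fl$images)) {
    img <- read_image(fl$images[i])
    h0 <- dim(img)[1]; w0 <- dim(img)[2]
    det <- detect(model, img, conf_thr, iou_thr)
    if (nrow(det))
      preds <- rbind(preds, data.frame(image_id = i, class = det$class_id,
                                       confidence = det$confidence,
                                       x1 = det$x1, y1 = det$y1,
                                       x2 = det$x2, y2 = det$y2))
    lb <- read_yolo_labels(fl$labels[i])
    if (nrow(lb)) {
      cc <- yolo_to_corners(lb[, 2:5, drop = FALSE], w0, h0)
      gts <- rbind(gts, data.frame(image_id = i, class = lb[, 1],
                                   x1 = cc[, 1], y1 = cc[, 2],
                                   x2 = cc[, 3], y2 = cc[, 4]))
    }
  }
  evaluate_detections(preds, gts, iou_thr = 0.5,
                      num_classes = fl$nc)$map50 / 100
}
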