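# Detection evaluation: precision, recall, per-class AP and mAP@0.5,
# confusion matrix, and a TIDE-style decomposition of the errors.

# Canonicalize predictions / ground truth to data.frames.
as_pred_df <- function(preds) {
  empty <- data.frame(image_id = integer(0), class = integer(0),
                      confidence = numeric(0), x1 = numeric(0),
                      y1 = numeric(0), x2 = numeric(0), y2 = numeric(0))
  if (is.null(preds) || NROW(preds) == 0) return(empty)
  df <- as.data.frame(preds)
  df[, c("image_id", "class", "confidence", "x1", "y1", "x2", "y2")]
}

as_gt_df <- function(gts) {
  empty <- data.frame(image_id = integer(0), class = integer(0),
                      x1 = numeric(0), y1 = numeric(0), x2 = numeric(0),
                      y2 = numeric(0))
  if (is.null(gts) || NROW(gts) == 0) return(empty)
  df <- as.data.frame(gts)
  df[, c("image_id", "class", "x1", "y1", "x2", "y2")]
}

# Greedy confidence-ordered matching. Returns per-prediction match info
# (gt row index or NA) and per-GT matched flag. Same-class matching when
# class_aware, else class-agnostic.
match_detections <- function(pred, gt, iou_thr, class_aware = TRUE) {
  np <- nrow(pred); ng <- nrow(gt)
  pmatch <- rep(NA_integer_, np)
  gmatched <- rep(FALSE, ng)
  if (np == 0L || ng == 0L)
    return(list(pmatch = pmatch, gmatched = gmatched))
  ord <- order(pred$confidence, decreasing = TRUE)
  pb <- as.matrix(pred[, c("x1", "y1", "x2", "y2")])
  gb <- as.matrix(gt[, c("x1", "y1", "x2", "y2")])
  for (i in ord) {
    cand <- which(gt$image_id == pred$image_id[i] & !gmatched)
    if (class_aware) cand <- cand[gt$class[cand] == pred$class[i]]
    if (!length(cand)) next
    ious <- iou_matrix(pb[i, , drop = FALSE], gb[cand, , drop = FALSE])[1, ]
    j <- which.max(ious)
    if (ious[j] >= iou_thr) {
      pmatch[i] <- cand[j]
      gmatched[cand[j]] <- TRUE
    }
  }
  list(pmatch = pmatch, gmatched = gmatched)
}

# All-point (precision-envelope) AP from TP flags sorted by confidence.
ap_from_flags <- function(tp, conf, n_gt) {
  if (n_gt == 0L) return(NA_real_)
  if (!length(tp)) return(0)
  ord <- order(conf, decreasing = TRUE)
  tp <- tp[ord]
  cum_tp <- cumsum(tp)
  cum_fp <- cumsum(!tp)
  recall <- cum_tp / n_gt
  precision <- cum_tp / (cum_tp + cum_fp)
  # envelope: precision at recall r is the max precision at recall >= r
  for (i in rev(seq_along(precision))[-1])
    precision[i] <- max(precision[i], precision[i + 1])
  dr <- diff(c(0, recall))
  sum(dr * precision)
}

#' Evaluate detections against ground truth
#'
#' Greedy confidence-ordered matching (each ground-truth box matched at
#' most once; a true positive requires the same class and IoU at or above
#' `iou_thr`). Per-class AP uses all-point precision-envelope integration
#' of the PR curve; mAP@0.5 is the mean of per-class AP over classes with
#' ground truth (`mAP = sum AP(c) / C`). The reported precision and recall
#' are taken at the confidence cut maximizing F1. A confusion matrix
#' (predicted class x true class, plus a background row/column) is built
#' at the fixed confidence `conf_thr` with class-agnostic matching.
#'
#' With no ground truth and no predictions the task is vacuously solved
#' and all percentages are 100.
#'
#' @param preds data.frame with `image_id, class, confidence, x1, y1, x2,
#'   y2` (pixel corner form).
#' @param gts data.frame with `image_id, class, x1, y1, x2, y2`.
#' @param iou_thr match threshold (default 0.5).
#' @param num_classes class count for the confusion matrix (inferred from
#'   the data when omitted).
#' @param conf_thr confusion-matrix operating confidence (default 0.25).
#' @return An `eval_result` list: `precision`, `recall` (percent, at the
#'   max-F1 cut), `precision_all`, `recall_all`, `tp_all`, `fp_all`,
#'   `fn_all` (the same quantities over every supplied detection, i.e.
#'   `TP/(TP+FP)` and `TP/(TP+FN)` with no confidence cut),
#'   `f1_confidence`, `ap_per_class` (percent, NA for classes without GT),
#'   `map50` (percent), `tp`, `fp`, `fn` (at the max-F1 cut), and
#'   `confusion_matrix`.
#' @export
evaluate_detections <- function(preds, gts, iou_thr = 0.5,
                                num_classes = NULL, conf_thr = 0.25) {
  pred <- as_pred_df(preds)
  gt <- as_gt_df(gts)
  if (is.null(num_classes))
    num_classes <- max(c(pred$class, gt$class, 0L)) + 1L
  classes <- 0:(num_classes - 1L)

  mt <- match_detections(pred, gt, iou_thr, class_aware = TRUE)
  tp_flag <- !is.na(mt$pmatch)
  # Eq-style counts over all supplied detections
  tp_all <- sum(tp_flag); fp_all <- nrow(pred) - tp_all
  fn_all <- nrow(gt) - tp_all
  precision_all <- if (nrow(pred)) 100 * tp_all / nrow(pred)
                   else if (nrow(gt)) 0 else 100
  recall_all <- if (nrow(gt)) 100 * tp_all / nrow(gt)
                else if (nrow(pred)) 0 else 100

  ap <- vapply(classes, function(cl) {
    sel <- pred$class == cl
    ap_from_flags(tp_flag[sel], pred$confidence[sel],
                  sum(gt$class == cl))
  }, 0)
  map50 <- if (all(is.na(ap))) {
    if (nrow(pred) == 0L) 100 else 0
  } else mean(ap[!is.na(ap)]) * 100

  # operating point: confidence maximizing F1 over the pooled detections
  if (nrow(pred)) {
    ord <- order(pred$confidence, decreasing = TRUE)
    cum_tp <- cumsum(tp_flag[ord])
    cum_fp <- cumsum(!tp_flag[ord])
    rec <- if (nrow(gt)) cum_tp / nrow(gt) else rep(1, nrow(pred))
    prc <- cum_tp / (cum_tp + cum_fp)
    f1 <- ifelse(prc + rec > 0, 2 * prc * rec / (prc + rec), 0)
    i <- which.max(f1)
    precision <- prc[i] * 100
    recall <- rec[i] * 100
    f1_conf <- pred$confidence[ord][i]
    tp <- cum_tp[i]; fp <- cum_fp[i]; fn <- nrow(gt) - cum_tp[i]
  } else {
    precision <- if (nrow(gt)) 0 else 100
    recall <- if (nrow(gt)) 0 else 100
    f1_conf <- NA_real_
    tp <- 0L; fp <- 0L; fn <- nrow(gt)
  }

  # confusion matrix at fixed confidence, class-agnostic matching
  sel <- pred$confidence >= conf_thr
  mt2 <- match_detections(pred[sel, , drop = FALSE], gt, iou_thr,
                          class_aware = FALSE)
  cm <- matrix(0L, num_classes + 1L, num_classes + 1L,
               dimnames = list(predicted = c(classes, "background"),
                               truth = c(classes, "background")))
  psel <- pred[sel, , drop = FALSE]
  for (i in seq_len(nrow(psel))) {
    pc <- psel$class[i] + 1L
    if (!is.na(mt2$pmatch[i])) cm[pc, gt$class[mt2$pmatch[i]] + 1L] <-
        cm[pc, gt$class[mt2$pmatch[i]] + 1L] + 1L
    else cm[pc, num_classes + 1L] <- cm[pc, num_classes + 1L] + 1L
  }
  for (j in which(!mt2$gmatched))
    cm[num_classes + 1L, gt$class[j] + 1L] <-
      cm[num_classes + 1L, gt$class[j] + 1L] + 1L

  structure(list(precision = precision, recall = recall,
                 precision_all = precision_all, recall_all = recall_all,
                 tp_all = tp_all, fp_all = fp_all, fn_all = fn_all,
                 f1_confidence = f1_conf,
                 ap_per_class = stats::setNames(ap * 100, classes),
                 map50 = map50, tp = tp, fp = fp, fn = fn,
                 confusion_matrix = cm),
            class = "eval_result")
}

#' @export
print.eval_result <- function(x, ...) {
  cat(sprintf("<eval_result: P %.1f%%  R %.1f%%  mAP@0.5 %.1f%%>\n",
              x$precision, x$recall, x$map50))
  invisible(x)
}

#' TIDE-style decomposition of detection errors
#'
#' After class-aware greedy matching at the foreground threshold `tf`,
#' every unmatched prediction is attributed to exactly one error type
#' according to its best-overlapping ground-truth box: background error
#' (`Ebkg`) when the best IoU falls below `tb`; duplicate when the best GT
#' has the same class at IoU >= `tf` but is already matched to a
#' higher-confidence detection; localization error (`Eloc`) when the best
#' GT has the same class at `tb <= IoU < tf`; classification error
#' (`Ecls`) when the best GT has a different class at IoU >= `tb`.
#' `Emiss` counts ground-truth boxes no prediction overlaps above `tb`;
#' `EFP` counts all false positives and `EFN` all unmatched ground truth,
#' so the identities `EFP = Ecls + Eloc + Ebkg + duplicate` and
#' `EFN >= Emiss` hold exactly.
#'
#' Besides raw counts, rates (counts over total predictions or total GT)
#' and a delta-mAP-style estimate (the mAP@`tf` gain from oracle-fixing
#' each error type, in percentage points) are reported; the two scales are
#' labelled distinctly.
#'
#' @inheritParams evaluate_detections
#' @param tf foreground IoU threshold (default 0.5).
#' @param tb background IoU threshold (default 0.1).
#' @return An `error_decomposition` list with `counts` (Ecls, Eloc, Ebkg,
#'   duplicate, Emiss, EFP, EFN), `rates`, and `delta_map`.
#' @export
decompose_errors <- function(preds, gts, tf = 0.5, tb = 0.1,
                             num_classes = NULL) {
  pred <- as_pred_df(preds)
  gt <- as_gt_df(gts)
  mt <- match_detections(pred, gt, tf, class_aware = TRUE)
  unmatched <- which(is.na(mt$pmatch))
  type <- rep(NA_character_, nrow(pred))
  pb <- as.matrix(pred[, c("x1", "y1", "x2", "y2")])
  gb <- as.matrix(gt[, c("x1", "y1", "x2", "y2")])
  gt_best_iou <- rep(0, nrow(gt))
  if (nrow(pred) && nrow(gt)) {
    for (i in seq_len(nrow(pred))) {
      cand <- which(gt$image_id == pred$image_id[i])
      if (!length(cand)) next
      ious <- iou_matrix(pb[i, , drop = FALSE], gb[cand, , drop = FALSE])[1, ]
      gt_best_iou[cand] <- pmax(gt_best_iou[cand], ious)
      if (!(i %in% unmatched)) next
      j <- cand[which.max(ious)]
      best <- max(ious)
      type[i] <- if (best < tb) "Ebkg"
      else if (gt$class[j] == pred$class[i]) {
        if (best >= tf) "duplicate" else "Eloc"
      } else "Ecls"
    }
    type[unmatched][is.na(type[unmatched])] <- "Ebkg"
  } else if (nrow(pred)) {
    type[unmatched] <- "Ebkg"
  }
  counts <- c(Ecls = sum(type == "Ecls", na.rm = TRUE),
              Eloc = sum(type == "Eloc", na.rm = TRUE),
              Ebkg = sum(type == "Ebkg", na.rm = TRUE),
              duplicate = sum(type == "duplicate", na.rm = TRUE),
              Emiss = sum(!mt$gmatched & gt_best_iou < tb),
              EFP = length(unmatched),
              EFN = sum(!mt$gmatched))
  np <- max(nrow(pred), 1L); ng <- max(nrow(gt), 1L)
  rates <- c(counts[c("Ecls", "Eloc", "Ebkg", "duplicate", "EFP")] / np,
             counts[c("Emiss", "EFN")] / ng)

  # oracle-fix delta-mAP estimates (percentage points at IoU tf)
  base <- evaluate_detections(pred, gt, iou_thr = tf,
                              num_classes = num_classes)$map50
  fix <- function(drop_types = NULL, fix_miss = FALSE) {
    p2 <- pred
    if (!is.null(drop_types)) p2 <- pred[!(type %in% drop_types), ,
                                         drop = FALSE]
    g2 <- gt
    if (fix_miss) g2 <- gt[!(!mt$gmatched & gt_best_iou < tb), ,
                           drop = FALSE]
    evaluate_detections(p2, g2, iou_thr = tf,
                        num_classes = num_classes)$map50 - base
  }
  delta_map <- c(Ecls = fix("Ecls"), Eloc = fix("Eloc"), Ebkg = fix("Ebkg"),
                 duplicate = fix("duplicate"), Emiss = fix(fix_miss = TRUE))
  structure(list(counts = counts, rates = rates, delta_map = delta_map,
                 tf = tf, tb = tb),
            class = "error_decomposition")
}

#' @export
print.error_decomposition <- function(x, ...) {
  cat("<error_decomposition (counts)>\n")
  print(x$counts)
  invisible(x)
}
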