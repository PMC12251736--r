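test_that("perfect detections score 100% precision, recall and mAP", {
  gts <- data.frame(image_id = c(1, 1, 2), class = c(0, 1, 0),
                    x1 = c(0, 20, 5), y1 = c(0, 20, 5),
                    x2 = c(10, 30, 15), y2 = c(10, 30, 15))
  preds <- cbind(gts[, 1, drop = FALSE], class = gts$class,
                 confidence = 1, gts[, 3:6])
  ev <- evaluate_detections(preds, gts)
  expect_equal(ev$precision, 100)
  expect_equal(ev$recall, 100)
  expect_equal(ev$map50, 100)
  expect_equal(unname(diag(ev$confusion_matrix)[1:2]), c(2L, 1L))
})

test_that("one correct + one off-target detection gives P = R = 50%", {
  gts <- data.frame(image_id = 1, class = c(0, 0),
                    x1 = c(0, 50), y1 = c(0, 50),
                    x2 = c(10, 60), y2 = c(10, 60))
  preds <- data.frame(image_id = 1, class = 0, confidence = c(0.9, 0.8),
                      x1 = c(0, 80), y1 = c(0, 80), x2 = c(10, 90),
                      y2 = c(10, 90))
  ev <- evaluate_detections(preds, gts)
  # TP = 1, FP = 1, FN = 1: Precision = TP/(TP+FP), Recall = TP/(TP+FN)
  expect_equal(ev$tp_all, 1)
  expect_equal(ev$fp_all, 1)
  expect_equal(ev$fn_all, 1)
  expect_equal(ev$precision_all, 50)
  expect_equal(ev$recall_all, 50)
  # the max-F1 operating point instead stops above the off-target box
  expect_equal(ev$precision, 100)
  expect_equal(ev$recall, 50)
})

test_that("empty cases are defined without division faults", {
  e <- evaluate_detections(NULL, NULL)
  expect_equal(e$map50, 100)        # vacuously complete
  e2 <- evaluate_detections(NULL, data.frame(image_id = 1, class = 0,
                                             x1 = 0, y1 = 0, x2 = 5, y2 = 5))
  expect_equal(e2$recall, 0)
  expect_equal(e2$map50, 0)
  e3 <- evaluate_detections(data.frame(image_id = 1, class = 0,
                                       confidence = 0.5, x1 = 0, y1 = 0,
                                       x2 = 5, y2 = 5), NULL)
  expect_equal(e3$precision, 0)
})

test_that("mAP is the class mean of AP and matches the rank-walk oracle", {
  for (case_seed in 1:20) {
    cs <- random_eval_case(n_img = 3, n_classes = 3, seed = case_seed)
    if (is.null(cs$gts)) next
    ev <- evaluate_detections(cs$preds, cs$gts, num_classes = 3)
    mt <- leafyolo:::match_detections(leafyolo:::as_pred_df(cs$preds),
                                      leafyolo:::as_gt_df(cs$gts), 0.5)
    aps <- vapply(0:2, function(cl) {
      sel <- which(cs$preds$class == cl)
      ap_bruteforce(cs$preds$confidence[sel], !is.na(mt$pmatch)[sel],
                    sum(cs$gts$class == cl))
    }, 0)
    expect_equal(unname(ev$ap_per_class) / 100, aps, tolerance = 1e-10)
    expect_equal(ev$map50, mean(aps[!is.na(aps)]) * 100, tolerance = 1e-10)
  }
})

test_that("mAP is invariant to monotone confidence rescaling", {
  cs <- random_eval_case(n_img = 4, n_classes = 3, seed = 77)
  ev1 <- evaluate_detections(cs$preds, cs$gts, num_classes = 3)
  p2 <- cs$preds
  p2$confidence <- plogis(5 * p2$confidence - 1)  # strictly monotone map
  ev2 <- evaluate_detections(p2, cs$gts, num_classes = 3)
  expect_equal(ev1$map50, ev2$map50, tolerance = 1e-12)
  expect_equal(ev1$ap_per_class, ev2$ap_per_class, tolerance = 1e-12)
})

test_that("duplicating a true positive never raises any per-class AP", {
  for (case_seed in 1:10) {
    cs <- random_eval_case(n_img = 3, n_classes = 2, seed = 100 + case_seed)
    if (is.null(cs$gts) || is.null(cs$preds)) next
    ev1 <- evaluate_detections(cs$preds, cs$gts, num_classes = 2)
    dup <- cs$preds[1, , drop = FALSE]
    dup$confidence <- dup$confidence * 0.99
    ev2 <- evaluate_detections(rbind(cs$preds, dup), cs$gts,
                               num_classes = 2)
    ok <- !is.na(ev1$ap_per_class)
    expect_true(all(ev2$ap_per_class[ok] <= ev1$ap_per_class[ok] + 1e-9))
  }
})

test_that("confusion-matrix prediction rows sum to TP+FP per class", {
  cs <- random_eval_case(n_img = 4, n_classes = 3, seed = 55)
  conf_thr <- 0.25
  ev <- evaluate_detections(cs$preds, cs$gts, num_classes = 3,
                            conf_thr = conf_thr)
  kept <- cs$preds[cs$preds$confidence >= conf_thr, ]
  per_class <- vapply(0:2, function(cl) sum(kept$class == cl), 0L)
  expect_equal(unname(rowSums(ev$confusion_matrix)[1:3]), per_class)
})

test_that("error taxonomy labels hand-built cases correctly", {
  gts <- data.frame(image_id = 1, class = 0, x1 = 0, y1 = 0, x2 = 10,
                    y2 = 10)
  # perfect detection: all six counters zero
  p <- data.frame(image_id = 1, class = 0, confidence = 0.9, x1 = 0,
                  y1 = 0, x2 = 10, y2 = 10)
  d <- decompose_errors(p, gts)
  expect_true(all(d$counts == 0))

  # high-IoU wrong-class prediction: Ecls = 1, EFP = 1, EFN = 1
  p$class <- 1
  d <- decompose_errors(p, gts, tf = 0.5, tb = 0.1)
  expect_equal(unname(d$counts[c("Ecls", "EFP", "EFN")]), c(1L, 1L, 1L))
  expect_equal(unname(d$counts["Eloc"]), 0L)

  # extra copy on a matched GT (IoU 0.67): duplicate; same class at mid
  # IoU (0.14): Eloc; far away: Ebkg
  p2 <- data.frame(image_id = 1, class = 0,
                   confidence = c(0.9, 0.8, 0.7, 0.6),
                   x1 = c(0, 2, 5, 50), y1 = c(0, 0, 5, 50),
                   x2 = c(10, 12, 15, 60), y2 = c(10, 10, 15, 60))
  d2 <- decompose_errors(p2, gts)
  expect_equal(unname(d2$counts["duplicate"]), 1L)
  expect_equal(unname(d2$counts["Eloc"]), 1L)
  expect_equal(unname(d2$counts["Ebkg"]), 1L)
  # the GT is matched by the first prediction, so Emiss = EFN = 0
  expect_equal(unname(d2$counts["EFN"]), 0L)
})

test_that("accounting identities hold across a randomized suite", {
  for (case_seed in 1:50) {
    cs <- random_eval_case(n_img = 3, n_classes = 3,
                           seed = 500 + case_seed)
    d <- decompose_errors(cs$preds, cs$gts, num_classes = 3)
    expect_identical(unname(d$counts["EFP"]),
                     unname(d$counts["Ecls"] + d$counts["Eloc"] +
                            d$counts["Ebkg"] + d$counts["duplicate"]))
    expect_true(d$counts["EFN"] >= d$counts["Emiss"])
  }
})

test_that("error rates shrink as predictions interpolate toward the truth", {
  set.seed(91)
  gts <- do.call(rbind, lapply(1:3, function(im) {
    data.frame(image_id = im, class = sample(0:1, 2, replace = TRUE),
               x1 = c(10, 60), y1 = c(10, 60), x2 = c(30, 80),
               y2 = c(30, 80))
  }))
  noisy <- gts
  noisy$confidence <- 0.8
  shift <- 25
  efp <- vapply(c(1, 0.6, 0.3, 0), function(a) {
    p <- noisy
    p[, c("x1", "x2")] <- p[, c("x1", "x2")] + a * shift
    sum(decompose_errors(p, gts, num_classes = 2)$counts["EFP"])
  }, 0)
  expect_true(all(diff(efp) <= 0))
  expect_equal(efp[4], 0)
})

test_that("oracle-fixing an error type never lowers the mAP estimate", {
  cs <- random_eval_case(n_img = 4, n_classes = 2, seed = 42)
  d <- decompose_errors(cs$preds, cs$gts, num_classes = 2)
  expect_true(all(d$delta_map >= -1e-9))
})
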