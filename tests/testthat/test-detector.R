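toy <- model_config(num_classes = 3, input_size = 160,
                    width_multiple = 0.125)

test_that("baseline builds and a forward pass emits three feature levels", {
  m <- build_model(toy, seed = 1)
  x <- array(runif(160 * 160 * 3), c(160, 160, 3, 1))
  out <- model_forward(m, x)
  expect_length(out, 3L)
  sizes <- t(vapply(out, function(o) dim(o$box)[1:2], c(1L, 1L)))
  expect_equal(sizes, rbind(c(20, 20), c(10, 10), c(5, 5)))  # strides 8/16/32
  for (o in out) {
    expect_equal(dim(o$box)[3], 64L)  # 4 sides x 16 bins
    expect_equal(dim(o$cls)[3], 3L)
  }
})

test_that("variant construction differs from the baseline only where configured", {
  b <- build_model(toy, seed = 1)
  v <- build_model(model_config(num_classes = 3, input_size = 160,
                                width_multiple = 0.125,
                                sspdconv_placement = c(1, 5),
                                use_esppfcspc = TRUE,
                                sspdconv_kernel = 3), seed = 1)
  bb <- vapply(b$layers, `[[`, "", "block")
  vb <- vapply(v$layers, `[[`, "", "block")
  expect_equal(which(bb != vb), c(1L, 8L, 10L))
  expect_equal(vb[c(1, 8)], rep("SSPDConv", 2))
  expect_equal(vb[10], "ESPPFCSPC")
  expect_error(model_config(sspdconv_placement = 6), "1..5")
})

test_that("parameter count equals a layer-by-layer counting oracle", {
  m <- build_model(toy, seed = 2)
  # independent hand count at width 0.125: channels 8/16/32/64/128
  conv_p <- function(c1, c2, k) k * k * c1 * c2 + 2 * c2
  c2f_p <- function(c1, c2, n) {
    ch <- c2 %/% 2
    conv_p(c1, 2 * ch, 1) + conv_p((2 + n) * ch, c2, 1) +
      n * (conv_p(ch, ch, 3) + conv_p(ch, ch, 3))
  }
  sppf_p <- function(c) conv_p(c, c %/% 2, 1) + conv_p(2 * c, c, 1)
  head_p <- function(nc, ch) {
    c2h <- max(16, ch[1] %/% 4, 64); c3 <- max(ch[1], min(nc, 100))
    sum(vapply(ch, function(x)
      conv_p(x, c2h, 3) + conv_p(c2h, c2h, 3) + (c2h * 64 + 64) +
      conv_p(x, c3, 3) + conv_p(c3, c3, 3) + (c3 * nc + nc), 0))
  }
  expected <- conv_p(3, 8, 3) + conv_p(8, 16, 3) + c2f_p(16, 16, 1) +
    conv_p(16, 32, 3) + c2f_p(32, 32, 2) + conv_p(32, 64, 3) +
    c2f_p(64, 64, 2) + conv_p(64, 128, 3) + c2f_p(128, 128, 1) +
    sppf_p(128) + c2f_p(192, 64, 1) + c2f_p(96, 32, 1) +
    conv_p(32, 32, 3) + c2f_p(96, 64, 1) + conv_p(64, 64, 3) +
    c2f_p(192, 128, 1) + head_p(3, c(32, 64, 128))
  expect_identical(model_stats(m)$params, expected)
})

test_that("model statistics are convention-stable and reproducible", {
  m1 <- build_model(toy, seed = 3)
  m2 <- build_model(toy, seed = 99)
  # params independent of seed and of input size; exact integers
  expect_identical(model_stats(m1)$params, model_stats(m2)$params)
  expect_identical(model_stats(m1, 320)$params, model_stats(m1, 160)$params)
  # gflops scales with spatial area
  s1 <- model_stats(m1, 160)$gflops_raw
  s2 <- model_stats(m1, 320)$gflops_raw
  expect_equal(s2 / s1, 4, tolerance = 1e-9)
})

test_that("swapping the box-loss kind changes no params and no FLOPs", {
  c1 <- model_config(num_classes = 3, input_size = 160,
                     width_multiple = 0.125, box_loss_kind = "ciou")
  c2 <- model_config(num_classes = 3, input_size = 160,
                     width_multiple = 0.125, box_loss_kind = "mpdiou")
  s1 <- model_stats(build_model(c1, seed = 1))
  s2 <- model_stats(build_model(c2, seed = 1))
  expect_identical(s1$params, s2$params)
  expect_identical(s1$gflops_raw, s2$gflops_raw)
})

test_that("identical-seed builds give identical weights and outputs", {
  m1 <- build_model(toy, seed = 5)
  m2 <- build_model(toy, seed = 5)
  p1 <- leafyolo:::model_parameters(m1)
  p2 <- leafyolo:::model_parameters(m2)
  for (i in seq_along(p1)) expect_identical(p1[[i]]$value, p2[[i]]$value)
})

test_that("detection loss contracts: perfect predictions, empty targets, toggling", {
  cfg <- model_config(num_classes = 2, input_size = 64,
                      width_multiple = 0.125, box_loss_kind = "mpdiou")
  # synthetic head output: an 8px GT centred on the (4,4) stride-8 anchor
  # (centre 28,28) is claimed by exactly that one cell; equal logit peaks
  # on bins 0 and 1 decode each side distance to exactly 0.5 cells, i.e.
  # the predicted box equals the GT box
  mk_preds <- function(logit_peak = 20) {
    lv <- list(box = array(0, c(8, 8, 64, 1)), cls = array(-20, c(8, 8, 2, 1)))
    for (s in 1:4) lv$box[, , (s - 1) * 16 + 1:2, ] <- logit_peak
    lv$cls[4, 4, 2, 1] <- 20
    list(lv,
         list(box = array(0, c(4, 4, 64, 1)), cls = array(-20, c(4, 4, 2, 1))),
         list(box = array(0, c(2, 2, 64, 1)), cls = array(-20, c(2, 2, 2, 1))))
  }
  gt <- matrix(c(1, 28 / 64, 28 / 64, 8 / 64, 8 / 64), 1)
  lb <- compute_detection_loss(mk_preds(), list(gt), cfg)
  expect_equal(lb$box_loss, 0, tolerance = 1e-6)
  expect_gt(lb$npos, 0)

  # no objects, confident prediction: box term 0, cls term positive
  lb0 <- compute_detection_loss(mk_preds(), list(NULL), cfg)
  expect_equal(lb0$box_loss, 0)
  expect_gt(lb0$cls_loss, 0)

  # toggling the box-loss kind changes only the box term
  cfg_c <- cfg; cfg_c$box_loss_kind <- "ciou"
  off_gt <- matrix(c(1, 30 / 64, 26 / 64, 20 / 64, 12 / 64), 1)
  l_m <- compute_detection_loss(mk_preds(), list(off_gt), cfg)
  l_c <- compute_detection_loss(mk_preds(), list(off_gt), cfg_c)
  expect_equal(l_m$cls_loss, l_c$cls_loss)
  expect_equal(l_m$dfl_loss, l_c$dfl_loss)
  expect_false(isTRUE(all.equal(l_m$box_loss, l_c$box_loss)))
})

test_that("single-pair loss reproduces the box_losses worked example", {
  # the batched pair used inside the training loss must reproduce the
  # worked example: (0,0,10,10) vs (5,5,15,15) in a 20x20 image
  pb <- matrix(c(0, 0, 10, 10), 1)
  gb <- matrix(c(5, 5, 15, 15), 1)
  r <- leafyolo:::mpdiou_loss_grad(pb, gb, 20, 20)
  expect_equal(as.numeric(r$loss),
               mpdiou_loss(pb[1, ], gb[1, ], 20, 20)$loss)
  expect_equal(as.numeric(r$loss), 0.982143, tolerance = 1e-5)
})

test_that("NMS keeps the confident box among heavy overlaps", {
  boxes <- rbind(c(0, 0, 10, 10), c(0.5, 0, 10.5, 10), c(30, 30, 40, 40))
  keep <- nms(boxes, c(0.9, 0.8, 0.7), classes = c(0, 0, 0), iou_thr = 0.45)
  expect_equal(sort(keep), c(1, 3))
  # different classes are never suppressed against each other
  keep2 <- nms(boxes[1:2, ], c(0.9, 0.8), classes = c(0, 1), iou_thr = 0.45)
  expect_equal(sort(keep2), c(1, 2))
  expect_equal(nms(boxes[0, , drop = FALSE], numeric(0)), integer(0))
})

test_that("detect returns an empty frame when all scores are below threshold", {
  m <- build_model(toy, seed = 1)  # untrained: confidences near the prior
  img <- array(runif(96 * 96 * 3), c(96, 96, 3))
  det <- detect(m, img, conf_thr = 0.99)
  expect_s3_class(det, "data.frame")
  expect_equal(nrow(det), 0L)
})

test_that("checkpoints round-trip through save_model / load_model", {
  m <- build_model(toy, seed = 8)
  f <- tempfile(fileext = ".rds")
  save_model(m, f)
  m2 <- load_model(f)
  x <- array(runif(64 * 64 * 3), c(64, 64, 3, 1))
  o1 <- model_forward(build_model(toy, seed = 8), x)
  o2 <- model_forward(m2, x)
  expect_equal(o1[[1]]$cls, o2[[1]]$cls, tolerance = 1e-12)
  unlink(f)
})
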