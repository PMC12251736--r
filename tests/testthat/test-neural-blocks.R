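test_that("SPD rearrangement matches the index-arithmetic oracle", {
  # 4x4 single-channel map, values 0..15 laid out column-major: channel 1
  # of the output must be the (even-row, even-col) sub-map
  x <- array(0:15, c(4, 4, 1))
  y <- spd_transform(x)
  expect_equal(dim(y), c(2L, 2L, 4L))
  expect_equal(y[, , 1], x[c(1, 3), c(1, 3), 1])
  expect_equal(y[, , 2], x[c(2, 4), c(1, 3), 1])  # row offset first
  expect_equal(y[, , 3], x[c(1, 3), c(2, 4), 1])
  expect_equal(y[, , 4], x[c(2, 4), c(2, 4), 1])
  # generic oracle: output[h, w, (k-1)*C + c] == input[2h-1+dr, 2w-1+dc, c]
  set.seed(1)
  x <- array(rnorm(6 * 8 * 3), c(6, 8, 3))
  y <- spd_transform(x)
  for (dr in 0:1) for (dc in 0:1) {
    k <- dc * 2 + dr
    for (ch in 1:3)
      expect_equal(y[, , k * 3 + ch],
                   x[seq(1 + dr, 6, 2), seq(1 + dc, 8, 2), ch])
  }
})

test_that("SPD halves the spatial dims and quadruples the channels", {
  x <- array(0, c(640, 640, 3))
  y <- spd_transform(x)
  expect_equal(dim(y), c(320L, 320L, 12L))
  expect_error(spd_transform(array(0, c(5, 4, 2))), "divisible")
})

test_that("SPD is a lossless bijection", {
  set.seed(2)
  for (i in 1:10) {
    d <- c(2 * sample(1:8, 1), 2 * sample(1:8, 1), sample(1:5, 1),
           sample(1:3, 1))
    x <- array(rnorm(prod(d)), d)
    y <- spd_transform(x)
    expect_equal(prod(dim(y)), prod(d))  # element count conserved
    expect_identical(spd_inverse(y), x)  # exact round trip
  }
})

test_that("SimAM constant-channel closed form and shape contract hold", {
  x <- array(3.5, c(6, 6, 4, 2))
  y <- simam_attention(x)
  # zero variance, every neuron at the mean: 1/e = 0.5 everywhere
  expect_equal(y, x * (1 / (1 + exp(-0.5))), tolerance = 1e-12)
  set.seed(4)
  x <- array(rnorm(7 * 5 * 3), c(7, 5, 3))
  expect_equal(dim(simam_attention(x)), dim(x))
  expect_error(simam_attention(x, lambda = 0))
})

test_that("SimAM weights favour neurons far from the channel mean", {
  x <- array(0, c(5, 5, 1))
  x[3, 3, 1] <- 10                      # one outlier neuron
  y <- simam_attention(x)
  w <- y / ifelse(x == 0, 1, x)         # x=0 cells have weight y/0*... skip
  wout <- y[3, 3, 1] / 10
  # near-mean weight from a probe with a tiny value
  x2 <- x; x2[1, 1, 1] <- 1e-6
  y2 <- simam_attention(x2)
  wnear <- y2[1, 1, 1] / 1e-6
  expect_gt(wout, wnear)
  # all weights lie in (0, 1)
  expect_true(wout < 1 && wnear > 0)
})

test_that("SimAM introduces no learnable parameters", {
  m_plain <- leafyolo:::nn_conv(8, 4, 1)
  set.seed(9)
  m_att <- leafyolo:::nn_sspdconv(2, 4, kernel = 1)
  # the SSPDConv block's parameters are exactly those of its convolution
  expect_equal(leafyolo:::param_count(m_att),
               leafyolo:::param_count(m_att$children$cv))
  expect_equal(length(leafyolo:::module_params(m_att$children$att)), 0L)
})

test_that("SSPDConv composes SPD, 1x1 conv and SimAM with the Fig-style shapes", {
  set.seed(11)
  x <- array(rnorm(8 * 8 * 3 * 2), c(8, 8, 3, 2))
  y <- sspdconv_forward(x, out_channels = 5, seed = 3)
  expect_equal(dim(y), c(4L, 4L, 5L, 2L))
  expect_error(sspdconv_forward(array(0, c(7, 8, 3)), 4), "even")

  # closed-form composition on a constant input with an identity-sum kernel:
  # conv output = sum of the 4C1 SPD channels, SimAM then scales by
  # sigmoid(0.5)
  m <- leafyolo:::nn_sspdconv(2, 3, kernel = 1)
  m$children$cv$params$w$value[] <- 1          # summing 1x1 kernel
  m$children$cv$params$gamma$value[] <- 1
  m$children$cv$params$beta$value[] <- 0
  xc <- array(2, c(4, 4, 2, 1))
  # bypass batch-norm statistics by evaluating with frozen running stats
  m$children$cv$run_mean[] <- 2 * 8             # conv out = 4C1 * 2 = 16
  m$children$cv$run_var[] <- 1
  y <- module_forward(m, xc)
  # conv -> BN((16-16)/1)=0 -> SiLU(0)=0 -> SimAM on constant 0 map = 0
  expect_equal(max(abs(y)), 0, tolerance = 1e-9)
  # and with identity BN, the value is silu(16) * sigmoid(0.5)
  m$children$cv$run_mean[] <- 0
  y <- module_forward(m, xc)
  z <- 16 / sqrt(1 + 1e-5)   # identity BN still divides by sqrt(var + eps)
  expect_equal(unique(as.vector(y)),
               z / (1 + exp(-z)) * (1 / (1 + exp(-0.5))), tolerance = 1e-9)
})

test_that("gradient flows through SSPDConv to its kernel", {
  set.seed(12)
  m <- leafyolo:::nn_sspdconv(2, 3, kernel = 3)
  x <- array(rnorm(6 * 6 * 2 * 2), c(6, 6, 2, 2))
  y <- m$fwd(x, training = TRUE)
  m$bwd(array(1, dim(y)))
  expect_gt(max(abs(m$children$cv$params$w$grad)), 0)
})

test_that("serial max-pool cascade equals parallel pools 5/9/13", {
  set.seed(13)
  naive_pool <- function(x, k) {
    # brute-force parallel max-pool, stride 1, same padding
    d <- dim(x); r <- (k - 1) %/% 2
    out <- array(-Inf, d)
    for (n in seq_len(d[4])) for (c in seq_len(d[3]))
      for (i in seq_len(d[1])) for (j in seq_len(d[2]))
        out[i, j, c, n] <- max(x[max(1, i - r):min(d[1], i + r),
                                 max(1, j - r):min(d[2], j + r), c, n])
    out
  }
  x <- array(rnorm(10 * 9 * 2 * 2), c(10, 9, 2, 2))
  p <- leafyolo:::nn_maxpool(5L)
  y1 <- p$fwd(x); y2 <- p$fwd(y1); y3 <- p$fwd(y2)
  expect_equal(y1, naive_pool(x, 5))
  expect_equal(y2, naive_pool(x, 9))
  expect_equal(y3, naive_pool(x, 13))
})

test_that("ESPPFCSPC preserves spatial dims and rejects channel mismatch", {
  set.seed(14)
  x <- array(rnorm(20 * 20 * 16), c(20, 20, 16, 1))
  y <- esppfcspc_forward(x, out_channels = 16, seed = 1)
  expect_equal(dim(y), c(20L, 20L, 16L, 1L))
  # non-square and larger-than-receptive-field inputs keep their dims
  x2 <- array(rnorm(15 * 27 * 16), c(15, 27, 16, 1))
  expect_equal(dim(esppfcspc_forward(x2, 8, seed = 1))[1:2], c(15L, 27L))
  m <- leafyolo:::nn_esppfcspc(16, 16)
  expect_error(m$fwd(array(0, c(8, 8, 4, 1))), "channel mismatch")
})

test_that("dilation rate 1 reduces ESPPFCSPC to plain SPPFCSPC accounting", {
  set.seed(15)
  m1 <- leafyolo:::nn_esppfcspc(32, 32, dilation = 1L)
  set.seed(15)
  m2 <- leafyolo:::nn_esppfcspc(32, 32, dilation = 2L)
  # dilation changes no parameter shapes or counts
  expect_equal(leafyolo:::param_count(m1), leafyolo:::param_count(m2))
  x <- array(rnorm(12 * 12 * 32), c(12, 12, 32, 1))
  expect_equal(dim(module_forward(m1, x)), dim(module_forward(m2, x)))
})

test_that("blocks are batch-consistent in inference mode", {
  # per-sample outputs must not depend on batch composition (SimAM and
  # batch-norm statistics are per sample / frozen at inference)
  set.seed(16)
  for (make in list(function() leafyolo:::nn_sspdconv(3, 4, kernel = 1),
                    function() leafyolo:::nn_esppfcspc(3, 4, hidden = 4))) {
    m <- make()
    x1 <- array(rnorm(8 * 8 * 3), c(8, 8, 3, 1))
    x2 <- array(rnorm(8 * 8 * 3), c(8, 8, 3, 1))
    xb <- array(c(x1, x2), c(8, 8, 3, 2))
    yb <- m$fwd(xb, training = FALSE)
    y1 <- m$fwd(x1, training = FALSE)
    expect_equal(yb[, , , 1, drop = FALSE], y1, tolerance = 1e-12)
  }
})

test_that("block registry exposes the named architecture blocks", {
  expect_identical(get_block("SSPDConv"), leafyolo:::block_registry$SSPDConv)
  m <- get_block("ESPPFCSPC")(8, 8, hidden = 4)
  expect_s3_class(m, "nn_module")
  expect_error(get_block("nope"), "unknown block")
})
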