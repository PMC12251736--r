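# Minimal neural-network engine: modules are environments exposing
# fwd(x, training) and bwd(dy), with parameters held in mutable cells so a
# plain SGD loop can update them in place.  Layout is [H, W, C, N].

param_new <- function(value, decay = TRUE) {
  p <- new.env(parent = emptyenv())
  p$value <- value
  p$grad <- array(0, dim(value))
  p$mom <- array(0, dim(value))
  p$decay <- decay
  p
}

param_count <- function(m) sum(vapply(module_params(m), function(p)
  length(p$value), 0))

#' Collect the trainable parameters of a module
#' @param m a module created by one of the `nn_*` constructors.
#' @return A flat list of parameter cells (each with `$value` and `$grad`).
#' @keywords internal
module_params <- function(m) {
  out <- list()
  if (!is.null(m$params)) out <- c(out, m$params)
  for (ch in m$children) out <- c(out, module_params(ch))
  out
}

#' Run a module forward
#'
#' Convenience wrapper accepting a rank-3 `[H, W, C]` or rank-4
#' `[H, W, C, N]` array and returning the same rank.
#'
#' @param m module; @param x input array; @param training logical, use batch
#'   statistics in normalization layers and cache for the backward pass.
#' @return Output array.
#' @export
module_forward <- function(m, x, training = FALSE) {
  had <- length(dim(x)) == 4L
  y <- m$fwd(as_featuremap(x), training)
  drop_batch(y, had)
}

new_module <- function(type, ..., children = list(), params = list()) {
  m <- new.env(parent = emptyenv())
  m$type <- type
  m$children <- children
  m$params <- params
  extra <- list(...)
  for (nm in names(extra)) assign(nm, extra[[nm]], envir = m)
  class(m) <- c(paste0("nn_", type), "nn_module")
  m
}

#' @export
print.nn_module <- function(x, ...) {
  cat(sprintf("<%s module, %d trainable parameters>\n", x$type,
              param_count(x)))
  invisible(x)
}

kaiming_init <- function(k, c1, c2) {
  array(stats::rnorm(k * k * c1 * c2, sd = sqrt(2 / (k * k * c1))),
        c(k, k, c1, c2))
}

## ---- Conv: conv2d (no bias) + BatchNorm + SiLU --------------------------

nn_conv <- function(c1, c2, k = 1L, stride = 1L, dilation = 1L,
                    act = TRUE) {
  pad <- (dilation * (k - 1L)) %/% 2L
  m <- new_module("conv", c1 = c1, c2 = c2, k = k, stride = stride,
                  pad = pad, dilation = dilation, act = act,
                  bn_eps = 1e-5, bn_momentum = 0.1)
  m$params <- list(w = param_new(kaiming_init(k, c1, c2)),
                   gamma = param_new(array(1, c2), decay = FALSE),
                   beta = param_new(array(0, c2), decay = FALSE))
  m$run_mean <- rep(0, c2)
  m$run_var <- rep(1, c2)
  m$fwd <- function(x, training = FALSE) {
    z <- conv2d_fwd_cpp(x, m$params$w$value, m$stride, m$pad, m$dilation)
    d <- dim(z); nhw <- d[1] * d[2] * d[4]
    if (training) {
      mu <- channel_sum(z) / nhw
      zc <- z - channel_expand(mu, d)
      va <- channel_sum(zc * zc) / nhw
      m$run_mean <- (1 - m$bn_momentum) * m$run_mean + m$bn_momentum * mu
      m$run_var <- (1 - m$bn_momentum) * m$run_var +
        m$bn_momentum * va * nhw / max(nhw - 1, 1)
    } else {
      mu <- m$run_mean; va <- m$run_var
      zc <- z - channel_expand(mu, d)
    }
    invstd <- 1 / sqrt(va + m$bn_eps)
    xhat <- zc * channel_expand(invstd, d)
    y <- xhat * channel_expand(m$params$gamma$value, d) +
      channel_expand(m$params$beta$value, d)
    if (m$act) { a <- silu_fwd(y); out <- a$y } else out <- y
    if (training) {
      m$cache <- list(x = x, xhat = xhat, invstd = invstd, pre = y,
                      s = if (m$act) a$s else NULL, d = d, nhw = nhw)
    }
    out
  }
  m$bwd <- function(dy) {
    cc <- m$cache; d <- cc$d; nhw <- cc$nhw
    if (m$act) dy <- silu_bwd(dy, cc$pre, cc$s)
    dgamma <- channel_sum(dy * cc$xhat)
    dbeta <- channel_sum(dy)
    m$params$gamma$grad <- m$params$gamma$grad + dgamma
    m$params$beta$grad <- m$params$beta$grad + dbeta
    gi <- channel_expand(m$params$gamma$value * cc$invstd, d)
    dz <- gi * (dy - channel_expand(dbeta / nhw, d) -
                cc$xhat * channel_expand(dgamma / nhw, d))
    r <- conv2d_bwd_cpp(cc$x, m$params$w$value, dz, m$stride, m$pad,
                        m$dilation, TRUE)
    m$params$w$grad <- m$params$w$grad + r$dw
    m$cache <- NULL
    r$dx
  }
  m$shape <- function(h, w) c(
    (h + 2 * m$pad - (m$dilation * (m$k - 1) + 1)) %/% m$stride + 1,
    (w + 2 * m$pad - (m$dilation * (m$k - 1) + 1)) %/% m$stride + 1, m$c2)
  m$flops <- function(h, w) {
    s <- m$shape(h, w)
    m$k^2 * m$c1 * m$c2 * s[1] * s[2]
  }
  m
}

## ---- plain conv2d with bias (detection-head finals) ---------------------

nn_conv2d <- function(c1, c2, k = 1L, bias_init = 0) {
  m <- new_module("conv2d", c1 = c1, c2 = c2, k = k, pad = (k - 1L) %/% 2L)
  m$params <- list(w = param_new(kaiming_init(k, c1, c2)),
                   b = param_new(array(bias_init, c2), decay = FALSE))
  m$fwd <- function(x, training = FALSE) {
    y <- conv2d_fwd_cpp(x, m$params$w$value, 1L, m$pad, 1L)
    y <- y + channel_expand(m$params$b$value, dim(y))
    if (training) m$cache <- list(x = x)
    y
  }
  m$bwd <- function(dy) {
    m$params$b$grad <- m$params$b$grad + channel_sum(dy)
    r <- conv2d_bwd_cpp(m$cache$x, m$params$w$value, dy, 1L, m$pad, 1L, TRUE)
    m$params$w$grad <- m$params$w$grad + r$dw
    m$cache <- NULL
    r$dx
  }
  m$shape <- function(h, w) c(h, w, m$c2)
  m$flops <- function(h, w) m$k^2 * m$c1 * m$c2 * h * w
  m
}

## ---- SPD space-to-depth -------------------------------------------------

#' Space-to-depth transform
#'
#' Losslessly rearranges each `scale x scale` spatial block into the channel
#' axis: an `S x S x C` map becomes `(S/scale) x (S/scale) x (scale^2 C)`.
#' Sub-map concatenation order is row-major over offsets
#' `(0,0), (1,0), (0,1), (1,1)` (row offset fastest), i.e. output channel
#' block `k` (0-based, of size C) holds the sub-map at row offset
#' `k %% scale`, column offset `k %/% scale`. [spd_inverse()] reconstructs
#' the input exactly.
#'
#' @param x feature map `[H, W, C]` or `[H, W, C, N]`; H and W must be
#'   divisible by `scale`.
#' @param scale integer downscale factor (default 2).
#' @return The rearranged map, same total element count.
#' @examples
#' x <- array(0:15, c(4, 4, 1))
#' y <- spd_transform(x)
#' dim(y)                       # 2 2 4
#' all(spd_inverse(y) == x)     # TRUE
#' @export
spd_transform <- function(x, scale = 2L) {
  had <- length(dim(x)) == 4L
  x <- as_featuremap(x)
  d <- dim(x)
  if (d[1] %% scale != 0L || d[2] %% scale != 0L)
    stop("spd_transform: spatial dims must be divisible by the scale factor")
  subs <- vector("list", scale * scale)
  i <- 1L
  for (dc in seq_len(scale) - 1L) {   # column offset slow
    for (dr in seq_len(scale) - 1L) { # row offset fast
      subs[[i]] <- x[seq(dr + 1L, d[1], by = scale),
                     seq(dc + 1L, d[2], by = scale), , , drop = FALSE]
      i <- i + 1L
    }
  }
  drop_batch(cat_channels(subs), had)
}

#' @rdname spd_transform
#' @export
spd_inverse <- function(x, scale = 2L) {
  had <- length(dim(x)) == 4L
  x <- as_featuremap(x)
  d <- dim(x)
  if (d[3] %% (scale * scale) != 0L)
    stop("spd_inverse: channel count not divisible by scale^2")
  C <- d[3] %/% (scale * scale)
  out <- array(0, c(d[1] * scale, d[2] * scale, C, d[4]))
  subs <- split_channels(x, rep(C, scale * scale))
  i <- 1L
  for (dc in seq_len(scale) - 1L) {
    for (dr in seq_len(scale) - 1L) {
      out[seq(dr + 1L, d[1] * scale, by = scale),
          seq(dc + 1L, d[2] * scale, by = scale), , ] <- subs[[i]]
      i <- i + 1L
    }
  }
  drop_batch(out, had)
}

nn_spd <- function(scale = 2L) {
  m <- new_module("spd", scale = scale, c_mult = scale * scale)
  m$fwd <- function(x, training = FALSE) {
    if (training) m$cache <- dim(x)
    spd_transform(x, m$scale)
  }
  m$bwd <- function(dy) spd_inverse(dy, m$scale)
  m$shape <- function(h, w, c) c(h %/% m$scale, w %/% m$scale, c * m$c_mult)
  m$flops <- function(h, w) 0
  m
}

## ---- SimAM parameter-free attention -------------------------------------

#' SimAM attention (functional form)
#'
#' Parameter-free attention: each neuron `t` in a channel receives energy
#' `e_t = 4 (sigma^2 + lambda) / ((t - mu)^2 + 2 sigma^2 + 2 lambda)` where
#' `mu`, `sigma^2` are that channel's spatial mean and variance (per
#' sample), and the output is `x * sigmoid(1 / e_t)`. A constant channel
#' has `1/e = 0.5` everywhere, so the whole map is scaled by
#' `sigmoid(0.5) ~ 0.6225`. No learnable parameters are introduced.
#'
#' @param x feature map `[H, W, C]` or `[H, W, C, N]`.
#' @param lambda energy regularizer (> 0), default `1e-4`.
#' @return Recalibrated map, same shape as the input.
#' @export
simam_attention <- function(x, lambda = 1e-4) {
  stopifnot(lambda > 0)
  had <- length(dim(x)) == 4L
  y <- simam_fwd(as_featuremap(x), lambda)$y
  drop_batch(y, had)
}

# Channel statistics are per sample, per channel over the spatial plane;
# variance uses the n-1 denominator of the original energy derivation.
simam_fwd <- function(x, lambda) {
  d <- dim(x)
  n <- d[1] * d[2]
  mu <- .colSums(x, n, d[3] * d[4]) / n              # C*N channel means
  mu_full <- rep(mu, each = n)
  xc <- x - mu_full
  v <- .colSums(xc * xc, n, d[3] * d[4]) / max(n - 1, 1)
  denom <- 4 * (v + lambda)
  einv <- xc * xc / rep(denom, each = n) + 0.5
  s <- sigmoid(einv)
  list(y = x * s, xc = xc, v = v, s = s, d = d, lambda = lambda)
}

nn_simam <- function(lambda = 1e-4) {
  m <- new_module("simam", lambda = lambda)
  m$fwd <- function(x, training = FALSE) {
    r <- simam_fwd(x, m$lambda)
    if (training) { r$x <- x; m$cache <- r }
    r$y
  }
  m$bwd <- function(dy) {
    cc <- m$cache; d <- cc$d; n <- d[1] * d[2]
    x <- cc$x; xc <- cc$xc; s <- cc$s
    denom <- 4 * (cc$v + m$lambda)           # per channel-sample
    # dE_i/dx_j = 2 xc_i (delta_ij - 1/n) / denom - (xc_i^2 / denom) *
    #             (2 xc_j / ((n-1)(v+lambda)))
    a <- dy * x * s * (1 - s)                # upstream through sigmoid arg
    a_over <- a / rep(denom, each = n)
    sum_a <- .colSums(a_over * xc, n, d[3] * d[4])
    sum_ad <- .colSums(a_over * xc * xc, n, d[3] * d[4])
    dx <- dy * s +
      2 * a_over * xc -
      rep(2 * sum_a / n, each = n) -
      xc * rep(2 * sum_ad / (max(n - 1, 1) * (cc$v + m$lambda)), each = n)
    m$cache <- NULL
    dx
  }
  m$shape <- function(h, w, c) c(h, w, c)
  m$flops <- function(h, w) 0
  m
}

## ---- SSPDConv: SPD -> 1x1 conv -> SimAM ---------------------------------

#' Build an SSPDConv block
#'
#' Drop-in replacement for a stride-2 convolution: a space-to-depth
#' rearrangement halves the spatial resolution and quadruples the channels,
#' a convolution (1x1 by default, 3x3 optional) maps `4*C1` to `C2`, and a
#' SimAM attention recalibrates the result. Output is `(S/2) x (S/2) x C2`.
#'
#' @param c1,c2 input and output channel counts.
#' @param kernel convolution kernel size after the SPD step (1 or 3).
#' @param lambda SimAM energy regularizer.
#' @return A module usable with [module_forward()].
#' @export
nn_sspdconv <- function(c1, c2, kernel = 1L, lambda = 1e-4) {
  stopifnot(kernel %in% c(1L, 3L))
  spd <- nn_spd(2L)
  cv <- nn_conv(4L * c1, c2, k = as.integer(kernel))
  att <- nn_simam(lambda)
  m <- new_module("sspdconv", c1 = c1, c2 = c2, kernel = kernel,
                  children = list(spd = spd, cv = cv, att = att))
  m$fwd <- function(x, training = FALSE) {
    d <- dim(x)
    if (d[1] %% 2L != 0L || d[2] %% 2L != 0L)
      stop("sspdconv: spatial dims must be even")
    att$fwd(cv$fwd(spd$fwd(x, training), training), training)
  }
  m$bwd <- function(dy) spd$bwd(cv$bwd(att$bwd(dy)))
  m$shape <- function(h, w) c(h %/% 2L, w %/% 2L, m$c2)
  m$flops <- function(h, w) cv$flops(h %/% 2L, w %/% 2L)
  m
}

#' @rdname nn_sspdconv
#' @param x input feature map with even spatial dims.
#' @param out_channels output channels `C2`.
#' @param kernel,lambda as above.
#' @param seed RNG seed for the convolution weights.
#' @export
sspdconv_forward <- function(x, out_channels, kernel = 1L, lambda = 1e-4,
                             seed = 0L) {
  d <- dim(as_featuremap(x))
  set.seed(seed)
  m <- nn_sspdconv(d[3], out_channels, kernel, lambda)
  module_forward(m, x)
}

## ---- Bottleneck and C2f -------------------------------------------------

nn_bottleneck <- function(c, shortcut = TRUE) {
  cv1 <- nn_conv(c, c, 3L)
  cv2 <- nn_conv(c, c, 3L)
  m <- new_module("bottleneck", c = c, shortcut = shortcut,
                  children = list(cv1 = cv1, cv2 = cv2))
  m$fwd <- function(x, training = FALSE) {
    y <- cv2$fwd(cv1$fwd(x, training), training)
    if (m$shortcut) x + y else y
  }
  m$bwd <- function(dy) {
    dx <- cv1$bwd(cv2$bwd(dy))
    if (m$shortcut) dy + dx else dx
  }
  m$flops <- function(h, w) cv1$flops(h, w) + cv2$flops(h, w)
  m
}

nn_c2f <- function(c1, c2, n = 1L, shortcut = FALSE) {
  ch <- c2 %/% 2L
  cv1 <- nn_conv(c1, 2L * ch, 1L)
  cv2 <- nn_conv((2L + n) * ch, c2, 1L)
  blocks <- lapply(seq_len(n), function(i) nn_bottleneck(ch, shortcut))
  m <- new_module("c2f", c1 = c1, c2 = c2, n = n, ch = ch,
                  children = c(list(cv1 = cv1, cv2 = cv2), blocks))
  m$fwd <- function(x, training = FALSE) {
    y <- cv1$fwd(x, training)
    ys <- split_channels(y, c(ch, ch))
    for (b in blocks) ys[[length(ys) + 1L]] <- b$fwd(ys[[length(ys)]], training)
    cv2$fwd(cat_channels(ys), training)
  }
  m$bwd <- function(dy) {
    dcat <- cv2$bwd(dy)
    parts <- split_channels(dcat, rep(ch, 2L + n))
    # walk the bottleneck chain backwards, accumulating into earlier parts
    for (i in rev(seq_len(n))) {
      parts[[i + 1L]] <- parts[[i + 1L]] + blocks[[i]]$bwd(parts[[i + 2L]])
    }
    cv1$bwd(cat_channels(parts[1:2]))
  }
  m$shape <- function(h, w) c(h, w, m$c2)
  m$flops <- function(h, w) cv1$flops(h, w) + cv2$flops(h, w) +
    sum(vapply(blocks, function(b) b$flops(h, w), 0))
  m
}

## ---- SPPF and ESPPFCSPC -------------------------------------------------

nn_maxpool <- function(k = 5L, stride = 1L) {
  pad <- (k - 1L) %/% 2L
  m <- new_module("maxpool", k = k, stride = stride, pad = pad)
  m$fwd <- function(x, training = FALSE) {
    r <- maxpool_fwd_cpp(x, m$k, m$stride, m$pad)
    if (training) m$cache <- list(argmax = r$argmax, xdim = dim(x))
    r$y
  }
  m$bwd <- function(dy) {
    r <- maxpool_bwd_cpp(dy, m$cache$argmax, m$cache$xdim)
    m$cache <- NULL
    r
  }
  m$flops <- function(h, w) 0
  m
}

nn_sppf <- function(c1, c2, k = 5L) {
  ch <- c1 %/% 2L
  cv1 <- nn_conv(c1, ch, 1L)
  cv2 <- nn_conv(4L * ch, c2, 1L)
  pools <- lapply(1:3, function(i) nn_maxpool(k))
  m <- new_module("sppf", c1 = c1, c2 = c2, ch = ch,
                  children = list(cv1 = cv1, cv2 = cv2))
  m$fwd <- function(x, training = FALSE) {
    y0 <- cv1$fwd(x, training)
    y1 <- pools[[1]]$fwd(y0, training)
    y2 <- pools[[2]]$fwd(y1, training)
    y3 <- pools[[3]]$fwd(y2, training)
    cv2$fwd(cat_channels(list(y0, y1, y2, y3)), training)
  }
  m$bwd <- function(dy) {
    d <- split_channels(cv2$bwd(dy), rep(ch, 4L))
    d3 <- pools[[3]]$bwd(d[[4]])
    d2 <- pools[[2]]$bwd(d[[3]] + d3)
    d1 <- pools[[1]]$bwd(d[[2]] + d2)
    cv1$bwd(d[[1]] + d1)
  }
  m$shape <- function(h, w) c(h, w, m$c2)
  m$flops <- function(h, w) cv1$flops(h, w) + cv2$flops(h, w)
  m
}

#' Build an ESPPFCSPC block
#'
#' Cross-stage-partial spatial pyramid pooling with serial max-pools and
#' dilated 3x3 convolutions. The main branch applies a conv stack
#' (1x1, dilated 3x3, 1x1), three serial max-pools (kernel `pool_kernel`,
#' stride 1, same padding), concatenates the pre-pool map with all three
#' pooled maps, and fuses them through another conv stack (1x1, dilated
#' 3x3); the shortcut branch is a single 1x1 conv. Branch outputs are
#' concatenated and fused to `out_channels` by a final 1x1 conv. Spatial
#' dims are preserved. Three serial k-pools give effective receptive fields
#' k, 2k-1, 3k-2 (5/9/13 for the default kernel 5).
#'
#' @param c1,c2 input / output channels.
#' @param hidden hidden branch width (default `c2 %/% 2`).
#' @param pool_kernel odd max-pool kernel, default 5.
#' @param dilation dilation rate of the two 3x3 convolutions, default 2;
#'   `dilation = 1` recovers the plain SPPFCSPC topology.
#' @return A module usable with [module_forward()].
#' @export
nn_esppfcspc <- function(c1, c2, hidden = NULL, pool_kernel = 5L,
                         dilation = 2L) {
  if (is.null(hidden)) hidden <- c2 %/% 2L
  stopifnot(pool_kernel %% 2L == 1L, dilation >= 1L, hidden >= 1L)
  h <- as.integer(hidden)
  cv1 <- nn_conv(c1, h, 1L)                     # main branch entry
  cv3 <- nn_conv(h, h, 3L, dilation = as.integer(dilation))
  cv4 <- nn_conv(h, h, 1L)
  cv5 <- nn_conv(4L * h, h, 1L)                 # pool fusion
  cv6 <- nn_conv(h, h, 3L, dilation = as.integer(dilation))
  cv2 <- nn_conv(c1, h, 1L)                     # shortcut branch
  cv7 <- nn_conv(2L * h, c2, 1L)                # final fuse
  pools <- lapply(1:3, function(i) nn_maxpool(as.integer(pool_kernel)))
  m <- new_module("esppfcspc", c1 = c1, c2 = c2, hidden = h,
                  pool_kernel = pool_kernel, dilation = dilation,
                  children = list(cv1 = cv1, cv2 = cv2, cv3 = cv3,
                                  cv4 = cv4, cv5 = cv5, cv6 = cv6,
                                  cv7 = cv7))
  m$fwd <- function(x, training = FALSE) {
    if (dim(x)[3] != m$c1) stop("esppfcspc: channel mismatch")
    y0 <- cv4$fwd(cv3$fwd(cv1$fwd(x, training), training), training)
    p1 <- pools[[1]]$fwd(y0, training)
    p2 <- pools[[2]]$fwd(p1, training)
    p3 <- pools[[3]]$fwd(p2, training)
    main <- cv6$fwd(cv5$fwd(cat_channels(list(y0, p1, p2, p3)), training),
                    training)
    short <- cv2$fwd(x, training)
    cv7$fwd(cat_channels(list(main, short)), training)
  }
  m$bwd <- function(dy) {
    d <- split_channels(cv7$bwd(dy), c(h, h))
    dx <- cv2$bwd(d[[2]])
    dcat <- split_channels(cv5$bwd(cv6$bwd(d[[1]])), rep(h, 4L))
    d3 <- pools[[3]]$bwd(dcat[[4]])
    d2 <- pools[[2]]$bwd(dcat[[3]] + d3)
    d1 <- pools[[1]]$bwd(dcat[[2]] + d2)
    dx + cv1$bwd(cv3$bwd(cv4$bwd(dcat[[1]] + d1)))
  }
  m$shape <- function(h2, w2) c(h2, w2, m$c2)
  m$flops <- function(h2, w2) sum(vapply(
    list(cv1, cv2, cv3, cv4, cv5, cv6, cv7),
    function(cv) cv$flops(h2, w2), 0))
  m
}

#' @rdname nn_esppfcspc
#' @param x input feature map.
#' @param out_channels output channels.
#' @param seed RNG seed for the convolution weights.
#' @export
esppfcspc_forward <- function(x, out_channels, hidden = NULL,
                              pool_kernel = 5L, dilation = 2L, seed = 0L) {
  d <- dim(as_featuremap(x))
  set.seed(seed)
  m <- nn_esppfcspc(d[3], out_channels, hidden, pool_kernel, dilation)
  module_forward(m, x)
}

## ---- plumbing modules ---------------------------------------------------

nn_upsample <- function(f = 2L) {
  m <- new_module("upsample", f = f)
  m$fwd <- function(x, training = FALSE) upsample_fwd_cpp(x, m$f)
  m$bwd <- function(dy) upsample_bwd_cpp(dy, m$f)
  m$flops <- function(h, w) 0
  m
}

# Block registry: architectures are declaratively editable by block name.
block_registry <- list(
  Conv = function(c1, c2, ...) nn_conv(c1, c2, ...),
  C2f = function(c1, c2, ...) nn_c2f(c1, c2, ...),
  SPPF = function(c1, c2, ...) nn_sppf(c1, c2, ...),
  SSPDConv = function(c1, c2, ...) nn_sspdconv(c1, c2, ...),
  ESPPFCSPC = function(c1, c2, ...) nn_esppfcspc(c1, c2, ...)
)

#' Look up a network block constructor by name
#' @param name one of `"Conv"`, `"C2f"`, `"SPPF"`, `"SSPDConv"`,
#'   `"ESPPFCSPC"`.
#' @return The constructor function.
#' @export
get_block <- function(name) {
  f <- block_registry[[name]]
  if (is.null(f)) stop("unknown block: ", name)
  f
}
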