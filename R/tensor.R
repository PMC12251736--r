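# Array helpers for [H, W, C, N] feature maps.

# Coerce a rank-3 [H, W, C] map to rank-4 with a singleton batch axis.
as_featuremap <- function(x) {
  if (!is.numeric(x) || is.null(dim(x)))
    stop("feature map must be a numeric array")
  d <- dim(x)
  if (length(d) == 3L) dim(x) <- c(d, 1L)
  else if (length(d) != 4L)
    stop("feature map must be rank 3 [H,W,C] or rank 4 [H,W,C,N]")
  if (any(dim(x) <= 0L)) stop("feature map dims must be positive")
  x
}

drop_batch <- function(x, had_batch) {
  if (!had_batch && dim(x)[4] == 1L) { d <- dim(x); dim(x) <- d[1:3] }
  x
}

# Concatenate along the channel axis.
cat_channels <- function(xs) {
  d1 <- dim(xs[[1]])
  ctot <- sum(vapply(xs, function(x) dim(x)[3], 0L))
  out <- array(0, c(d1[1], d1[2], ctot, d1[4]))
  off <- 0L
  for (x in xs) {
    c <- dim(x)[3]
    out[, , (off + 1L):(off + c), ] <- x
    off <- off + c
  }
  out
}

# Split along the channel axis into chunks of the given sizes.
split_channels <- function(x, sizes) {
  off <- 0L
  lapply(sizes, function(c) {
    y <- x[, , (off + 1L):(off + c), , drop = FALSE]
    off <<- off + c
    y
  })
}

silu_fwd <- function(z) {
  s <- 1 / (1 + exp(-z))
  list(y = z * s, s = s)
}

silu_bwd <- function(dy, z, s) dy * (s * (1 + z * (1 - s)))

sigmoid <- function(z) 1 / (1 + exp(-z))

# Per-channel sums over (H, W, N); x is [H, W, C, N].  Returns length-C.
channel_sum <- function(x) {
  d <- dim(x)
  m <- .colSums(x, d[1] * d[2], d[3] * d[4])
  .rowSums(matrix(m, d[3], d[4]), d[3], d[4])
}

# Expand a per-channel vector to the full [H, W, C, N] layout.
channel_expand <- function(v, d) {
  rep(rep(v, each = d[1] * d[2]), times = d[4])
}
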