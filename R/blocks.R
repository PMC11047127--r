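# Encoder and skip-path building blocks.
#
# SAEB (single adaptive encoder block): 3x3x3 conv -> batch norm -> global
# average pooling -> squeeze/excite bottleneck (two 1x1x1 convs, ReLU between)
# -> softmax over channels -> channel-wise rescaling of the normalized map ->
# ReLU. The softmax (rather than the canonical SE sigmoid) makes the channel
# weights a probability distribution: they are non-negative and sum to 1.
#
# DAEB (dual adaptive encoder block): 3x3x3 conv -> two parallel attention
# branches. The channel branch pools a global descriptor, passes it through a
# squeeze/excite bottleneck and a sigmoid; the spatial branch concatenates the
# channel-wise max and average maps, convolves them (default 7x7x7) and
# applies a sigmoid. Each attention map rescales the conv output and the two
# rescaled tensors are fused by elementwise addition.
#
# SegPath: n parallel iterations, each summing ReLU(BN(conv1x1x1(x))) and
# ReLU(BN(conv3x3x3(x))); the n iteration outputs are accumulated by addition.
# n = 0 degenerates to a plain identity skip.

block_saeb <- function(tape, x, P, state, key, training, collect = NULL) {
  y <- tp_conv3d(tape, x, P("conv.W"), P("conv.b"))
  ybn <- tp_bn(tape, y, P("bn.gamma"), P("bn.beta"), state, paste0(key, ".bn"), training)
  s <- tp_gap(tape, ybn)
  z <- tp_conv3d(tape, s, P("fc1.W"), P("fc1.b"))
  z <- tp_relu(tape, z)
  z <- tp_conv3d(tape, z, P("fc2.W"), P("fc2.b"))
  a <- tp_softmax_c(tape, z)
  if (!is.null(collect)) collect$attention <- tval(tape, a)
  tp_relu(tape, tp_mul_bcast(tape, ybn, a))
}

block_daeb <- function(tape, x, P, collect = NULL) {
  t <- tp_conv3d(tape, x, P("conv.W"), P("conv.b"))
  ca <- tp_gap(tape, t)
  ca <- tp_conv3d(tape, ca, P("fc1.W"), P("fc1.b"))
  ca <- tp_relu(tape, ca)
  ca <- tp_conv3d(tape, ca, P("fc2.W"), P("fc2.b"))
  ca <- tp_sigmoid(tape, ca)
  t_ca <- tp_mul_bcast(tape, t, ca)
  sa <- tp_concat_c(tape, tp_chan_max(tape, t), tp_chan_avg(tape, t))
  sa <- tp_conv3d(tape, sa, P("sconv.W"), P("sconv.b"))
  sa <- tp_sigmoid(tape, sa)
  t_sa <- tp_mul_bcast(tape, t, sa)
  if (!is.null(collect)) {
    collect$channel_attention <- tval(tape, ca)
    collect$spatial_attention <- tval(tape, sa)
  }
  tp_add(tape, t_ca, t_sa)
}

block_segpath <- function(tape, x, P, n, state, key, training) {
  if (n == 0L) return(x)
  z <- NULL
  for (i in seq_len(n)) {
    pre <- sprintf("it%d.", i)
    y1 <- tp_conv3d(tape, x, P(paste0(pre, "c1.W")), P(paste0(pre, "c1.b")))
    y1 <- tp_bn(tape, y1, P(paste0(pre, "bn1.gamma")), P(paste0(pre, "bn1.beta")),
                state, sprintf("%s.it%d.bn1", key, i), training)
    y1 <- tp_relu(tape, y1)
    y2 <- tp_conv3d(tape, x, P(paste0(pre, "c3.W")), P(paste0(pre, "c3.b")))
    y2 <- tp_bn(tape, y2, P(paste0(pre, "bn3.gamma")), P(paste0(pre, "bn3.beta")),
                state, sprintf("%s.it%d.bn3", key, i), training)
    y2 <- tp_relu(tape, y2)
    yi <- tp_add(tape, y1, y2)
    z <- if (is.null(z)) yi else tp_add(tape, z, yi)
  }
  z
}

# ---- parameter initializers ------------------------------------------------

#' Initialize parameters for one SAEB block
#'
#' Draws He-uniform convolution kernels, zero biases, and unit/zero batch-norm
#' scale/shift from the current R random number generator state.
#'
#' @param in_channels,out_channels Channel counts entering/leaving the block.
#' @param reduction Squeeze-and-excitation bottleneck reduction ratio `r`; the
#'   descriptor is reduced to `max(1, out_channels / r)` channels.
#' @return Nested list of arrays: `conv`, `bn`, `fc1`, `fc2`.
#' @export
init_saeb_params <- function(in_channels, out_channels, reduction = 4) {
  cred <- max(1L, out_channels %/% reduction)
  list(conv = conv_init(3L, in_channels, out_channels),
       bn = bn_init(out_channels),
       fc1 = conv_init(1L, out_channels, cred),
       fc2 = conv_init(1L, cred, out_channels))
}

#' Initialize parameters for one DAEB block
#'
#' @inheritParams init_saeb_params
#' @param spatial_kernel Odd kernel size of the spatial-attention convolution
#'   acting on the 2-channel pooled map (default 7).
#' @return Nested list of arrays: `conv`, `fc1`, `fc2`, `sconv`.
#' @export
init_daeb_params <- function(in_channels, out_channels, reduction = 4,
                             spatial_kernel = 7) {
  cred <- max(1L, out_channels %/% reduction)
  list(conv = conv_init(3L, in_channels, out_channels),
       fc1 = conv_init(1L, out_channels, cred),
       fc2 = conv_init(1L, cred, out_channels),
       sconv = conv_init(as.integer(spatial_kernel), 2L, 1L))
}

#' Initialize parameters for a SegPath skip-refinement module
#'
#' Each of the `n` iterations has its own 1x1x1 and 3x3x3 convolution branch
#' with batch normalization; channel count is preserved.
#'
#' @param channels Channel count of the skip tensor.
#' @param n Number of iterations (0 returns an empty list: identity skip).
#' @return Nested list `it1`, ..., `itn`.
#' @export
init_segpath_params <- function(channels, n) {
  out <- list()
  for (i in seq_len(n)) {
    out[[sprintf("it%d", i)]] <- list(
      c1 = conv_init(1L, channels, channels), bn1 = bn_init(channels),
      c3 = conv_init(3L, channels, channels), bn3 = bn_init(channels))
  }
  out
}

# ---- standalone forward passes --------------------------------------------

#' SAEB forward pass
#'
#' Applies one single-adaptive-encoder block to a feature map. The softmax
#' channel-attention weights are attached as attribute `"attention"` (shape
#' `(batch, 1, 1, 1, C)`; they sum to 1 over channels).
#'
#' @param x 5-axis array `(batch, H, W, D, channel)` of finite values.
#' @param params Parameter list as produced by [init_saeb_params()].
#' @param training Logical; `TRUE` (default) normalizes with batch statistics,
#'   `FALSE` requires running statistics in `state`.
#' @param state Optional environment holding batch-norm running statistics.
#' @return Feature map with the same spatial shape as `x` and the block's
#'   output channel count.
#' @export
saeb_forward <- function(x, params, training = TRUE, state = NULL) {
  check_feature_map(x)
  check_block_channels(x, params$conv$W)
  if (is.null(state)) state <- new.env(parent = emptyenv())
  col <- new.env(parent = emptyenv())
  out <- block_saeb(NULL, x, nested_getter(params), state, "saeb", training, collect = col)
  attr(out, "attention") <- col$attention
  out
}

#' DAEB forward pass
#'
#' Applies one dual-adaptive-encoder block. The sigmoid channel and spatial
#' attention maps (entries in `[0, 1]`) are attached as attributes
#' `"channel_attention"` and `"spatial_attention"`.
#'
#' @inheritParams saeb_forward
#' @param params Parameter list as produced by [init_daeb_params()].
#' @export
daeb_forward <- function(x, params, training = TRUE, state = NULL) {
  check_feature_map(x)
  check_block_channels(x, params$conv$W)
  col <- new.env(parent = emptyenv())
  out <- block_daeb(NULL, x, nested_getter(params), collect = col)
  attr(out, "channel_attention") <- col$channel_attention
  attr(out, "spatial_attention") <- col$spatial_attention
  out
}

#' SegPath forward pass
#'
#' @inheritParams saeb_forward
#' @param n Number of refinement iterations; `0` returns `x` unchanged.
#' @param params Parameter list as produced by [init_segpath_params()].
#' @export
segpath_forward <- function(x, n, params, training = TRUE, state = NULL) {
  check_feature_map(x)
  if (length(n) != 1L || n < 0 || n != round(n))
    abort_validation("n must be a single non-negative integer")
  if (n > 0) check_block_channels(x, params$it1$c1$W)
  if (is.null(state)) state <- new.env(parent = emptyenv())
  block_segpath(NULL, x, nested_getter(params), as.integer(n), state, "segpath", training)
}

check_block_channels <- function(x, W) {
  if (is.null(W)) abort_config("parameter list is missing its first convolution kernel")
  if (dim(x)[5] != dim(W)[4])
    abort_config(sprintf("input has %d channels but the filter expects %d",
                         dim(x)[5], dim(W)[4]))
  invisible(x)
}
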