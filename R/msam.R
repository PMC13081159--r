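# Multi-scale attention module (MSAM) for skip connections.
#
# Two branches refine a skip tensor. The spatial branch compresses channels
# with a pointwise convolution, extracts multi-scale context with three
# parallel depthwise convolutions (summed, then BN + ReLU), and emits a
# sigmoid spatial attention map. The channel branch squeezes the map with
# global average pooling and two pointwise convolutions (SE-style) into
# per-channel sigmoid weights. A fusion pointwise convolution lifts the
# multi-scale features back to the input width; the output is
#   out = x + channel_att * (spatial_att * fused_features),
# so zeroing the fusion weights leaves the input untouched (residual).

#' MSAM configuration
#'
#' @param channels number of input (= output) channels.
#' @param compression_ratio pointwise compression for the spatial branch;
#'   must divide `channels`.
#' @param dw_kernel_sizes three odd kernel sizes for the parallel depthwise
#'   convolutions (default 3, 5, 7).
#' @param channel_bottleneck_ratio squeeze ratio of the channel branch; must
#'   divide `channels`.
#' @param spatial_per_channel emit the spatial map with `channels` channels
#'   instead of a single broadcast channel.
#' @return an `msam_config` list.
#' @export
msam_config <- function(channels, compression_ratio = 4L,
                        dw_kernel_sizes = c(3L, 5L, 7L),
                        channel_bottleneck_ratio = 4L,
                        spatial_per_channel = FALSE) {
  stopifnot(channels >= 1L, compression_ratio >= 1L,
            channel_bottleneck_ratio >= 1L,
            length(dw_kernel_sizes) == 3L)
  if (any(dw_kernel_sizes %% 2L == 0L)) {
    stop("depthwise kernel sizes must be odd to preserve shape")
  }
  if (channels %% compression_ratio != 0L) {
    stop("channels (", channels, ") not divisible by compression_ratio (",
         compression_ratio, ")")
  }
  if (channels %% channel_bottleneck_ratio != 0L) {
    stop("channels (", channels, ") not divisible by ",
         "channel_bottleneck_ratio (", channel_bottleneck_ratio, ")")
  }
  structure(list(channels = as.integer(channels),
                 compression_ratio = as.integer(compression_ratio),
                 dw_kernel_sizes = as.integer(dw_kernel_sizes),
                 channel_bottleneck_ratio = as.integer(channel_bottleneck_ratio),
                 spatial_per_channel = isTRUE(spatial_per_channel)),
            class = "msam_config")
}

#' Construct an MSAM block
#'
#' @param config an [msam_config()], or a channel count (defaults applied).
#' @return an `msam_block` parameter container.
#' @export
msam_block <- function(config) {
  if (is.numeric(config)) config <- msam_config(config)
  stopifnot(inherits(config, "msam_config"))
  C <- config$channels
  cc <- C %/% config$compression_ratio
  cb <- C %/% config$channel_bottleneck_ratio
  ks <- config$dw_kernel_sizes
  sp_out <- if (config$spatial_per_channel) C else 1L
  structure(list(
    compress = conv_layer(1L, 1L, C, cc, bias = FALSE),
    dw1 = conv_layer(ks[1], ks[1], cc, cc, groups = cc, bias = FALSE),
    dw2 = conv_layer(ks[2], ks[2], cc, cc, groups = cc, bias = FALSE),
    dw3 = conv_layer(ks[3], ks[3], cc, cc, groups = cc, bias = FALSE),
    bn = bn_layer(cc),
    pw_spatial = conv_layer(1L, 1L, cc, sp_out),
    pw_fuse = conv_layer(1L, 1L, cc, C),
    ch_fc1 = conv_layer(1L, 1L, C, cb),
    ch_fc2 = conv_layer(1L, 1L, cb, C),
    config = config
  ), class = "msam_block")
}

.msam_check <- function(x, params) {
  d <- .dims4(x$value)
  if (d[3] != params$config$channels) {
    stop("MSAM configured for ", params$config$channels,
         " channels, input has ", d[3])
  }
}

# shared trunk of the spatial branch: compressed multi-scale features
.msam_multiscale <- function(x, params, training) {
  u <- fwd_conv(params$compress, x)
  s <- op_add(op_add(fwd_conv(params$dw1, u), fwd_conv(params$dw2, u)),
              fwd_conv(params$dw3, u))
  op_relu(fwd_bn(params$bn, s, training = training))
}

#' Spatial attention map of an MSAM block
#'
#' Pointwise compression, three parallel depthwise convolutions (summed),
#' BN + ReLU, pointwise projection, sigmoid. Values are strictly in (0, 1).
#'
#' @inheritParams msam_forward
#' @return array/tensor `(H, W, 1, N)` (or `(H, W, C, N)` when the block was
#'   configured with `spatial_per_channel = TRUE`).
#' @export
spatial_attention <- function(features, params, training = FALSE) {
  plain <- !is_tensor(features)
  x <- as_tensor(features)
  .msam_check(x, params)
  m <- .msam_multiscale(x, params, training)
  y <- op_sigmoid(fwd_conv(params$pw_spatial, m))
  if (plain) y$value else y
}

#' Channel attention weights of an MSAM block
#'
#' Global average pooling followed by a two-layer pointwise bottleneck
#' (leaky rectifier between, sigmoid at the end), giving one weight per
#' channel per sample. The bottleneck activation leaks (slope 0.01) so that
#' squeeze units cannot be silenced permanently by an unlucky
#' initialization — every parameter keeps a gradient path.
#'
#' @inheritParams msam_forward
#' @return array/tensor of shape `(1, 1, C, N)`.
#' @export
channel_attention <- function(features, params, training = FALSE) {
  plain <- !is_tensor(features)
  x <- as_tensor(features)
  .msam_check(x, params)
  y <- op_sigmoid(fwd_conv(params$ch_fc2,
                           op_leaky_relu(fwd_conv(params$ch_fc1, op_gap(x)))))
  if (plain) y$value else y
}

#' Apply an MSAM block (residual output)
#'
#' @param features array `(H, W, C, N)` or `hf_tensor`.
#' @param params an [msam_block()].
#' @param training use batch statistics in BN stages?
#' @return refined features with the same shape as the input.
#' @export
msam_forward <- function(features, params, training = FALSE) {
  plain <- !is_tensor(features)
  x <- as_tensor(features)
  .msam_check(x, params)
  m <- .msam_multiscale(x, params, training)
  a_sp <- op_sigmoid(fwd_conv(params$pw_spatial, m))
  v <- fwd_conv(params$pw_fuse, m)
  weighted <- if (params$config$spatial_per_channel) {
    tensor(v$value * a_sp$value, parents = list(v, a_sp),
           backward = function(g) list(g * a_sp$value, g * v$value))
  } else {
    op_scale_spatial(v, a_sp)
  }
  a_ch <- op_sigmoid(fwd_conv(params$ch_fc2,
                              op_leaky_relu(fwd_conv(params$ch_fc1, op_gap(x)))))
  y <- op_add(x, op_scale_channel(weighted, a_ch))
  if (plain) y$value else y
}
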