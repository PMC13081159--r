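# HFSUNet assembly: encoder with HWD downsampling, MSAM-refined skip
# connections, upsampling decoder, 1-channel sigmoid head.

#' Model configuration
#'
#' @param levels number of resolution levels (default 4, i.e. 3 HWD
#'   downsampling stages between them).
#' @param base_channels channels at the finest level; doubled at each level.
#' @param in_channels,out_channels input/output channels (grayscale in,
#'   binary-probability out).
#' @param hwd_kernel_size kernel of the HWD fusion convolution (default 1).
#' @param msam_compression_ratio,msam_dw_kernel_sizes,msam_bottleneck_ratio
#'   MSAM settings applied per skip level (see [msam_config()]).
#' @param upsample_mode `"bilinear"` (upsample + 3x3 conv, default) or
#'   `"transposed"` (learned 2x2 stride-2 transposed convolution).
#' @return a `model_config` list.
#' @export
model_config <- function(levels = 4L, base_channels = 32L, in_channels = 1L,
                         out_channels = 1L, hwd_kernel_size = 1L,
                         msam_compression_ratio = 4L,
                         msam_dw_kernel_sizes = c(3L, 5L, 7L),
                         msam_bottleneck_ratio = 4L,
                         upsample_mode = c("bilinear", "transposed")) {
  upsample_mode <- match.arg(upsample_mode)
  stopifnot(levels >= 2L, base_channels >= 1L)
  channels <- base_channels * 2L^(seq_len(levels) - 1L)
  if (base_channels %% msam_compression_ratio != 0L ||
      base_channels %% msam_bottleneck_ratio != 0L) {
    stop("base_channels must be divisible by the MSAM ratios")
  }
  structure(list(levels = as.integer(levels),
                 base_channels = as.integer(base_channels),
                 channels = as.integer(channels),
                 in_channels = as.integer(in_channels),
                 out_channels = as.integer(out_channels),
                 hwd_kernel_size = as.integer(hwd_kernel_size),
                 msam_compression_ratio = as.integer(msam_compression_ratio),
                 msam_dw_kernel_sizes = as.integer(msam_dw_kernel_sizes),
                 msam_bottleneck_ratio = as.integer(msam_bottleneck_ratio),
                 upsample_mode = upsample_mode),
            class = "model_config")
}

.double_conv <- function(cin, cout) {
  list(conv1 = conv_layer(3L, 3L, cin, cout, bias = FALSE),
       bn1 = bn_layer(cout),
       conv2 = conv_layer(3L, 3L, cout, cout, bias = FALSE),
       bn2 = bn_layer(cout))
}

.fwd_double_conv <- function(block, x, training) {
  h <- op_relu(fwd_bn(block$bn1, fwd_conv(block$conv1, x), training))
  op_relu(fwd_bn(block$bn2, fwd_conv(block$conv2, h), training))
}

# learned 2x2 stride-2 transposed convolution (for upsample_mode "transposed")
.convT_layer <- function(cin, cout) {
  layer <- new.env(parent = emptyenv())
  layer$kind <- "convT"
  layer$cin <- cin; layer$cout <- cout
  layer$w <- tensor(.he_init(2L, 2L, cin, cout), requires_grad = TRUE)
  layer$b <- tensor(array(0, dim = cout), requires_grad = TRUE)
  class(layer) <- "hf_layer"
  layer
}

.fwd_convT <- function(layer, x) {
  d <- .dims4(x$value)
  cin <- layer$cin; cout <- layer$cout
  wv <- layer$w$value
  fwd_val <- function(xv, w) {
    out <- array(0, dim = c(2L * d[1], 2L * d[2], cout, d[4]))
    xm <- xv; dim(xm) <- c(d[1] * d[2], cin, d[4])
    for (di in 1:2) for (dj in 1:2) {
      wm <- matrix(w[di, dj, , ], cin, cout)
      for (n in seq_len(d[4])) {
        blk <- xm[, , n] %*% wm
        dim(blk) <- c(d[1], d[2], cout)
        out[seq(di, 2L * d[1], 2L), seq(dj, 2L * d[2], 2L), , n] <- blk
      }
    }
    out
  }
  y <- fwd_val(x$value, wv)
  y <- y + .expand_channel(as.vector(layer$b$value),
                           c(2L * d[1], 2L * d[2], cout, d[4]))
  tensor(y, parents = list(x, layer$w, layer$b), backward = function(g) {
    dx <- array(0, dim = d)
    dw <- array(0, dim = dim(wv))
    xm <- x$value; dim(xm) <- c(d[1] * d[2], cin, d[4])
    dxm <- array(0, dim = c(d[1] * d[2], cin, d[4]))
    for (di in 1:2) for (dj in 1:2) {
      gs <- g[seq(di, 2L * d[1], 2L), seq(dj, 2L * d[2], 2L), , , drop = FALSE]
      dim(gs) <- c(d[1] * d[2], cout, d[4])
      wm <- matrix(wv[di, dj, , ], cin, cout)
      for (n in seq_len(d[4])) {
        dxm[, , n] <- dxm[, , n] + gs[, , n] %*% t(wm)
        dw[di, dj, , ] <- dw[di, dj, , ] + t(xm[, , n]) %*% gs[, , n]
      }
    }
    dim(dxm) <- d
    gd <- g; dim(gd) <- c(4L * d[1] * d[2], cout * d[4])
    db <- rowSums(matrix(colSums(gd), cout, d[4]))
    list(dxm, dw, array(db))
  })
}

#' Build an HFSUNet model
#'
#' Encoder levels are double-conv blocks; resolution is halved between
#' levels by HWD blocks (wavelet subband stack + fusion convolution) rather
#' than pooling. Each skip tensor passes through an MSAM block before being
#' concatenated in the decoder, which mirrors the encoder with upsampling +
#' double-conv, ending in a 1x1 convolution and a sigmoid.
#'
#' Parameter initialization draws from R's RNG: call `set.seed()` first for
#' reproducible builds.
#'
#' @param config a [model_config()].
#' @return an object of class `hfsunet_model`.
#' @export
build_model <- function(config = model_config()) {
  stopifnot(inherits(config, "model_config"))
  ch <- config$channels
  L <- config$levels
  enc <- list(.double_conv(config$in_channels, ch[1]))
  hwd <- list()
  for (l in 2:L) {
    hwd[[l - 1]] <- hwd_block(ch[l - 1], ch[l - 1], config$hwd_kernel_size)
    enc[[l]] <- .double_conv(ch[l - 1], ch[l])
  }
  msam <- lapply(seq_len(L - 1), function(l) {
    msam_block(msam_config(ch[l],
                           compression_ratio = config$msam_compression_ratio,
                           dw_kernel_sizes = config$msam_dw_kernel_sizes,
                           channel_bottleneck_ratio = config$msam_bottleneck_ratio))
  })
  dec <- lapply(seq_len(L - 1), function(l) {
    # decoder stage producing level-l features from level-(l+1)
    up <- if (config$upsample_mode == "transposed") {
      list(convT = .convT_layer(ch[l + 1], ch[l]))
    } else {
      list(conv = conv_layer(3L, 3L, ch[l + 1], ch[l], bias = FALSE),
           bn = bn_layer(ch[l]))
    }
    list(up = up, block = .double_conv(2L * ch[l], ch[l]))
  })
  head <- conv_layer(1L, 1L, ch[1], config$out_channels, bias = TRUE)
  structure(list(config = config, enc = enc, hwd = hwd, msam = msam,
                 dec = dec, head = head),
            class = "hfsunet_model")
}

#' @export
print.hfsunet_model <- function(x, ...) {
  cat("<hfsunet_model levels=", x$config$levels,
      " channels=", paste(x$config$channels, collapse = "/"),
      " params=", count_parameters(x), ">\n", sep = "")
  invisible(x)
}

.check_input_hw <- function(hw, levels) {
  div <- 2L^(levels - 1L)
  if (any(hw %% div != 0L)) {
    pad_to <- div * ceiling(hw / div)
    stop("input ", hw[1], "x", hw[2], " not divisible by ", div,
         "; pad to ", pad_to[1], "x", pad_to[2],
         " (see pad_to_multiple())")
  }
}

#' Forward pass
#'
#' @param model an `hfsunet_model`.
#' @param images numeric array `(H, W, N)` or `(H, W, 1, N)` with values in
#'   `[0, 1]`, or an `hf_tensor`; `H` and `W` must be divisible by
#'   `2^(levels-1)`.
#' @param training use batch statistics in BN layers (training mode)?
#' @return per-pixel foreground probabilities, same spatial shape; a plain
#'   array when the input was one, else an `hf_tensor`.
#' @export
model_forward <- function(model, images, training = FALSE) {
  plain <- !is_tensor(images)
  if (plain) {
    if (length(dim(images)) == 2L) dim(images) <- c(dim(images), 1L, 1L)
    if (length(dim(images)) == 3L) {
      dim(images) <- c(dim(images)[1:2], 1L, dim(images)[3])
    }
    images <- tensor(images)
  }
  d <- .dims4(images$value)
  .check_input_hw(d[1:2], model$config$levels)
  L <- model$config$levels
  feats <- vector("list", L)
  x <- .fwd_double_conv(model$enc[[1]], images, training)
  feats[[1]] <- x
  for (l in 2:L) {
    x <- hwd_forward(x, model$hwd[[l - 1]], training = training)
    x <- .fwd_double_conv(model$enc[[l]], x, training)
    feats[[l]] <- x
  }
  for (l in rev(seq_len(L - 1))) {
    up <- model$dec[[l]]$up
    x <- if (!is.null(up$convT)) {
      .fwd_convT(up$convT, x)
    } else {
      op_relu(fwd_bn(up$bn, fwd_conv(up$conv, op_upsample2(x)), training))
    }
    skip <- msam_forward(feats[[l]], model$msam[[l]], training = training)
    x <- .fwd_double_conv(model$dec[[l]]$block, op_concat_c(skip, x), training)
  }
  y <- op_sigmoid(fwd_conv(model$head, x))
  if (plain) y$value else y
}

#' Count trainable parameters
#'
#' @param model an `hfsunet_model` (or any nested structure of layers).
#' @return integer count of trainable scalar parameters.
#' @export
count_parameters <- function(model) {
  sum(vapply(collect_params(model), function(p) length(p$value), numeric(1)))
}

#' Analytic FLOPs of a single convolution
#'
#' Multiply-accumulate count times two, plus one FLOP per output element
#' when a bias is added.
#'
#' @param kh,kw kernel size; @param cin,cout channel counts;
#' @param h,w output spatial size; @param groups,bias as in the layer.
#' @export
conv_flops <- function(kh, kw, cin, cout, h, w, groups = 1L, bias = FALSE) {
  2 * kh * kw * (cin / groups) * cout * h * w + if (bias) h * w * cout else 0
}

#' Analytic FLOPs estimate for a model
#'
#' Per-layer analytic cost for one sample at the given input size:
#' convolutions (2 FLOPs per MAC), batch norm as a fused per-element affine
#' (2 FLOPs), ReLU (1), sigmoid (4), Haar subband stage (4 per input
#' element), bilinear upsampling (8 per output element). Convolutions
#' dominate; the rest is bookkeeping.
#'
#' @param model an `hfsunet_model`.
#' @param input_hw input height/width (length-2 integer).
#' @return total FLOPs (numeric) with a `breakdown` data.frame attribute;
#'   divide by `1e9` for GFLOPs.
#' @export
estimate_flops <- function(model, input_hw = c(256L, 256L)) {
  cfg <- model$config
  .check_input_hw(input_hw, cfg$levels)
  rows <- list()
  add <- function(name, flops) rows[[length(rows) + 1L]] <<- data.frame(
    layer = name, flops = flops)
  dc <- function(name, cin, cout, h, w) {
    add(paste0(name, ".conv1"), conv_flops(3, 3, cin, cout, h, w))
    add(paste0(name, ".bn1+relu"), 3 * h * w * cout)
    add(paste0(name, ".conv2"), conv_flops(3, 3, cout, cout, h, w))
    add(paste0(name, ".bn2+relu"), 3 * h * w * cout)
  }
  msam_fl <- function(name, C, h, w) {
    cc <- C / cfg$msam_compression_ratio
    cb <- C / cfg$msam_bottleneck_ratio
    f <- conv_flops(1, 1, C, cc, h, w)
    for (k in cfg$msam_dw_kernel_sizes) {
      f <- f + conv_flops(k, k, cc, cc, h, w, groups = cc)
    }
    f <- f + 3 * h * w * cc                                    # BN + ReLU
    f <- f + conv_flops(1, 1, cc, 1, h, w, bias = TRUE) + 4 * h * w
    f <- f + conv_flops(1, 1, cc, C, h, w, bias = TRUE)        # fuse
    f <- f + h * w * C                                         # GAP
    f <- f + conv_flops(1, 1, C, cb, 1, 1, bias = TRUE) + cb
    f <- f + conv_flops(1, 1, cb, C, 1, 1, bias = TRUE) + 4 * C
    f <- f + 2 * h * w * C + h * w * C                         # scaling + residual
    add(name, f)
  }
  ch <- cfg$channels
  h <- input_hw[1]; w <- input_hw[2]
  dc("enc1", cfg$in_channels, ch[1], h, w)
  for (l in 2:cfg$levels) {
    add(paste0("hwd", l - 1, ".haar"), 4 * h * w * ch[l - 1])
    h <- h / 2; w <- w / 2
    k <- cfg$hwd_kernel_size
    add(paste0("hwd", l - 1, ".conv"),
        conv_flops(k, k, 4 * ch[l - 1], ch[l - 1], h, w) + 3 * h * w * ch[l - 1])
    dc(paste0("enc", l), ch[l - 1], ch[l], h, w)
  }
  for (l in rev(seq_len(cfg$levels - 1))) {
    h <- h * 2; w <- w * 2
    if (cfg$upsample_mode == "transposed") {
      # 2x2 stride-2 transposed conv: h*w*cin*cout MACs + bias
      add(paste0("up", l), 2 * h * w * ch[l + 1] * ch[l] + h * w * ch[l])
    } else {
      add(paste0("up", l), 8 * h * w * ch[l + 1] +
            conv_flops(3, 3, ch[l + 1], ch[l], h, w) + 3 * h * w * ch[l])
    }
    msam_fl(paste0("msam", l), ch[l], h, w)
    dc(paste0("dec", l), 2 * ch[l], ch[l], h, w)
  }
  add("head", conv_flops(1, 1, ch[1], cfg$out_channels, h, w, bias = TRUE) +
        4 * h * w * cfg$out_channels)
  breakdown <- do.call(rbind, rows)
  total <- sum(breakdown$flops)
  attr(total, "breakdown") <- breakdown
  total
}

#' Reflect-pad an image to a size multiple
#'
#' @param image numeric matrix.
#' @param multiple required divisor of both dimensions.
#' @return list with the padded `image` and the original `shape`.
#' @export
pad_to_multiple <- function(image, multiple) {
  d <- dim(image)
  target <- as.integer(multiple * ceiling(d / multiple))
  if (all(target == d)) return(list(image = image, shape = d))
  ri <- c(seq_len(d[1]), rev(seq_len(d[1])))[seq_len(target[1])]
  rj <- c(seq_len(d[2]), rev(seq_len(d[2])))[seq_len(target[2])]
  list(image = image[ri, rj, drop = FALSE], shape = d)
}
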