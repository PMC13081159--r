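# 2-D Haar wavelet analysis/synthesis and the HWD downsampling block.
#
# The transform uses the averaging convention: each pair stage computes
# L = (x0 + x1)/2 and H = (x0 - x1)/2, first along rows (width), then along
# columns of both results. Under this convention the LL subband equals 2x2
# average pooling exactly, and the energy identity reads
# 4 * (sum(ll^2) + sum(lh^2) + sum(hl^2) + sum(hh^2)) = sum(x^2).

.check_even <- function(d) {
  if (d[1] %% 2L != 0L) stop("image height must be even, got ", d[1])
  if (d[2] %% 2L != 0L) stop("image width must be even, got ", d[2])
}

#' Single-level 2-D Haar wavelet transform
#'
#' Decomposes an even-sized matrix into four half-resolution subbands:
#' `ll` (approximation; identical to 2x2 block averaging), `lh` (vertical
#' detail: differences between row pairs of the row-lowpass), `hl`
#' (horizontal detail), and `hh` (diagonal detail).
#'
#' @param image numeric matrix with even numbers of rows and columns.
#' @return an object of class `subband_set`: a list with matrices
#'   `ll`, `lh`, `hl`, `hh` (each `nrow/2 x ncol/2`) and `source_shape`.
#' @examples
#' s <- haar_dwt_2d(matrix(1:16, 4, 4))
#' all.equal(haar_idwt_2d(s), matrix(1:16, 4, 4))
#' @export
haar_dwt_2d <- function(image) {
  stopifnot(is.matrix(image), is.numeric(image))
  d <- dim(image)
  .check_even(d)
  x <- array(image, dim = c(d[1], d[2], 1, 1))
  s <- .haar_split4(x)
  as_band <- function(b) {
    dim(b) <- d %/% 2L
    b
  }
  structure(list(ll = as_band(s$ll), lh = as_band(s$lh),
                 hl = as_band(s$hl), hh = as_band(s$hh),
                 source_shape = d),
            class = "subband_set")
}

#' @export
print.subband_set <- function(x, ...) {
  cat("<subband_set ", paste(dim(x$ll), collapse = "x"),
      " per band, source ", paste(x$source_shape, collapse = "x"), ">\n",
      sep = "")
  invisible(x)
}

#' Inverse single-level 2-D Haar wavelet transform
#'
#' Exact inverse of [haar_dwt_2d()] under the averaging convention: each
#' pair stage reconstructs `x0 = L + H`, `x1 = L - H`, columns first, then
#' rows.
#'
#' @param subbands a `subband_set` (or a list with `ll`, `lh`, `hl`, `hh`).
#' @return the reconstructed matrix.
#' @export
haar_idwt_2d <- function(subbands) {
  b <- subbands[c("ll", "lh", "hl", "hh")]
  dims <- lapply(b, dim)
  if (length(unique(dims)) != 1L) {
    stop("subband shape mismatch: ",
         paste(vapply(dims, paste, "", collapse = "x"), collapse = ", "))
  }
  h2 <- nrow(b$ll); w2 <- ncol(b$ll)
  L <- matrix(0, 2 * h2, w2); Hh <- L
  oi <- seq(1L, 2L * h2, 2L); ei <- oi + 1L
  L[oi, ] <- b$ll + b$lh
  L[ei, ] <- b$ll - b$lh
  Hh[oi, ] <- b$hl + b$hh
  Hh[ei, ] <- b$hl - b$hh
  x <- matrix(0, 2 * h2, 2 * w2)
  oj <- seq(1L, 2L * w2, 2L); ej <- oj + 1L
  x[, oj] <- L + Hh
  x[, ej] <- L - Hh
  x
}

#' Construct a Haar wavelet downsampling (HWD) block
#'
#' The HWD block replaces pooling: each input channel is decomposed into its
#' four Haar subbands, the subbands are stacked along the channel dimension
#' (channel-major order `ll, lh, hl, hh` per input channel, yielding `4 * C`
#' channels at half resolution), and a convolution + batch normalization +
#' ReLU maps the stack to `c_out` channels.
#'
#' @param c_in,c_out input/output channel counts.
#' @param kernel_size convolution kernel over the subband stack (default 1).
#' @return an `hwd_block` parameter container.
#' @export
hwd_block <- function(c_in, c_out, kernel_size = 1L) {
  stopifnot(c_in >= 1L, c_out >= 1L, kernel_size %% 2L == 1L)
  structure(list(conv = conv_layer(kernel_size, kernel_size, 4L * c_in, c_out,
                                   bias = FALSE),
                 bn = bn_layer(c_out),
                 c_in = c_in, c_out = c_out, kernel_size = kernel_size),
            class = "hwd_block")
}

#' Apply an HWD block to a feature map
#'
#' @param features numeric array `(H, W, C, N)` with even `H`, `W`, or an
#'   `hf_tensor` wrapping one.
#' @param params an [hwd_block()].
#' @param training use batch statistics in the BN stage?
#' @return array (or tensor, matching the input type) of shape
#'   `(H/2, W/2, c_out, N)`.
#' @export
hwd_forward <- function(features, params, training = FALSE) {
  plain <- !is_tensor(features)
  x <- as_tensor(features)
  stopifnot(.dims4(x$value)[3] == params$c_in)
  y <- op_relu(fwd_bn(params$bn, fwd_conv(params$conv, op_haar_subbands(x)),
                      training = training))
  if (plain) y$value else y
}
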