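# Morphology-weighted boundary loss (MWL) and baseline losses.
#
# MWL is pixel-weighted binary cross-entropy. The weight mask partitions the
# image into three regions derived from the ground truth by binary
# morphology with a square structuring element (zero-padded borders):
#   interior   W_e = erosion(gt)            -> weight w_0
#   margin     W_d - W_e (boundary band)    -> weight w_m
#   background 1 - W_d, W_d = dilation(gt)  -> weight w_b
# Because W_e <= gt <= W_d, the three indicator regions always sum to one.

.check_binary <- function(mask, what = "mask") {
  if (!all(mask %in% c(0, 1))) stop(what, " must be binary (0/1)")
}

.shift_pad0 <- function(mask, di, dj) {
  d <- dim(mask)
  out <- matrix(0, d[1], d[2])
  si <- seq_len(d[1]) + di
  sj <- seq_len(d[2]) + dj
  ok_i <- si >= 1L & si <= d[1]
  ok_j <- sj >= 1L & sj <= d[2]
  out[ok_i, ok_j] <- mask[si[ok_i], sj[ok_j]]
  out
}

.morph_once <- function(mask, kernel_size, op) {
  r <- (kernel_size - 1L) %/% 2L
  acc <- NULL
  for (di in -r:r) {
    for (dj in -r:r) {
      s <- .shift_pad0(mask, di, dj)
      acc <- if (is.null(acc)) s else if (op == "min") pmin(acc, s) else pmax(acc, s)
    }
  }
  acc
}

#' Binary erosion with a square structuring element
#'
#' Zero-padded borders: pixels whose neighborhood extends outside the image
#' are eroded away, so an all-ones mask loses its border ring.
#'
#' @param mask binary matrix (0/1).
#' @param kernel_size odd side length of the square structuring element.
#' @param iterations number of times the operation is applied.
#' @return binary matrix, a subset of `mask`.
#' @export
binary_erosion <- function(mask, kernel_size = 3L, iterations = 1L) {
  stopifnot(is.matrix(mask), kernel_size %% 2L == 1L, iterations >= 0L)
  .check_binary(mask)
  out <- mask
  for (i in seq_len(iterations)) out <- .morph_once(out, kernel_size, "min")
  out
}

#' Binary dilation with a square structuring element
#'
#' @inheritParams binary_erosion
#' @return binary matrix, a superset of `mask`.
#' @export
binary_dilation <- function(mask, kernel_size = 3L, iterations = 1L) {
  stopifnot(is.matrix(mask), kernel_size %% 2L == 1L, iterations >= 0L)
  .check_binary(mask)
  out <- mask
  for (i in seq_len(iterations)) out <- .morph_once(out, kernel_size, "max")
  out
}

#' Three-region boundary weight mask
#'
#' Computes `w_b * (1 - W_d) + w_m * (W_d - W_e) + w_0 * W_e` where
#' `W_e`/`W_d` are the erosion/dilation of the ground truth. Every pixel's
#' weight is one of `w_b`, `w_m`, `w_0`; with all three equal to 1 the mask
#' is identically 1.
#'
#' @param gt binary ground-truth matrix.
#' @param w_b,w_m,w_0 nonnegative weights for background, margin band, and
#'   lesion interior. Defaults up-weight the margin (w_m = 2).
#' @param kernel_size,iterations structuring element settings passed to the
#'   morphology operations.
#' @return object of class `weight_mask`: list with the `weights` matrix and
#'   the parameters used.
#' @export
weight_mask <- function(gt, w_b = 1, w_m = 2, w_0 = 1, kernel_size = 3L,
                        iterations = 1L) {
  if (any(c(w_b, w_m, w_0) < 0)) stop("region weights must be nonnegative")
  .check_binary(gt, "gt")
  we <- binary_erosion(gt, kernel_size, iterations)
  wd <- binary_dilation(gt, kernel_size, iterations)
  structure(list(weights = w_b * (1 - wd) + w_m * (wd - we) + w_0 * we,
                 interior = we, dilated = wd,
                 params = c(w_b = w_b, w_m = w_m, w_0 = w_0),
                 kernel_size = kernel_size, iterations = iterations),
            class = "weight_mask")
}

.loss_prep <- function(pred, gt, eps = 1e-7) {
  pred <- as.array(pred); gt <- as.array(gt)
  if (!identical(dim(pred), dim(gt))) {
    stop("pred and gt shapes differ: ", paste(dim(pred), collapse = "x"),
         " vs ", paste(dim(gt), collapse = "x"))
  }
  if (any(pred < 0 | pred > 1)) stop("pred must lie in [0, 1]")
  .check_binary(gt, "gt")
  list(p = pmin(pmax(pred, eps), 1 - eps), y = gt)
}

# per-sample weight array matching pred layout; weights may be a
# weight_mask, a matrix/array of weights, or NULL (unit weights)
.expand_weights <- function(weights, dims) {
  if (is.null(weights)) return(array(1, dim = dims))
  if (inherits(weights, "weight_mask")) weights <- weights$weights
  w <- as.array(weights)
  if (identical(dim(w), dims)) return(w)
  if (length(dims) == 4L && identical(dim(w), dims[1:2])) {
    return(array(rep(as.vector(w), times = prod(dims[3:4])), dim = dims))
  }
  stop("weights shape incompatible with predictions")
}

#' Marginal weight loss (boundary-weighted binary cross-entropy)
#'
#' `-sum_i weight(i) * (y_i log p_i + (1 - y_i) log(1 - p_i))`, optionally
#' divided by the pixel count (`reduction = "mean"`, the training default;
#' `"sum"` is the exact summed form).
#'
#' @param pred predicted probabilities, any array shape (matrix or
#'   `(H, W, 1, N)`), values in `[0, 1]` (clamped at `eps` internally).
#' @param gt binary ground truth, same shape.
#' @param weights a [weight_mask()], a plain weight array, or `NULL` for
#'   unit weights. If `NULL` and `mwl_params` is given, per-sample weight
#'   masks are derived from `gt`.
#' @param mwl_params optional list with `w_b`, `w_m`, `w_0`, `kernel_size`,
#'   `iterations` used to derive weights from `gt`.
#' @param reduction `"mean"` or `"sum"`.
#' @param eps probability clamp to avoid `log(0)`.
#' @return nonnegative scalar loss.
#' @export
mwl_loss <- function(pred, gt, weights = NULL, mwl_params = NULL,
                     reduction = c("mean", "sum"), eps = 1e-7) {
  reduction <- match.arg(reduction)
  z <- .loss_prep(pred, gt, eps)
  if (is.null(weights) && !is.null(mwl_params)) {
    weights <- mwl_weights_for(gt, mwl_params)
  }
  w <- .expand_weights(weights, dim(z$y) %||% length(z$y))
  ll <- -(z$y * log(z$p) + (1 - z$y) * log(1 - z$p))
  s <- sum(w * ll)
  if (reduction == "mean") s / length(z$p) else s
}

#' Gradient of [mwl_loss()] with respect to the predictions
#'
#' @inheritParams mwl_loss
#' @return array of `d loss / d pred`, same shape as `pred`.
#' @export
mwl_loss_grad <- function(pred, gt, weights = NULL, mwl_params = NULL,
                          reduction = c("mean", "sum"), eps = 1e-7) {
  reduction <- match.arg(reduction)
  z <- .loss_prep(pred, gt, eps)
  if (is.null(weights) && !is.null(mwl_params)) {
    weights <- mwl_weights_for(gt, mwl_params)
  }
  w <- .expand_weights(weights, dim(z$y) %||% length(z$y))
  g <- w * (z$p - z$y) / (z$p * (1 - z$p))
  # the loss is computed from the clamped probabilities, so it is flat in
  # pred wherever the clamp is active
  g[pred < eps | pred > 1 - eps] <- 0
  if (reduction == "mean") g / length(z$p) else g
}

# derive an (H,W,1,N)-shaped weight array from a batch of ground truths
mwl_weights_for <- function(gt, params = list()) {
  p <- utils::modifyList(list(w_b = 1, w_m = 2, w_0 = 1, kernel_size = 3L,
                              iterations = 1L), as.list(params))
  g <- as.array(gt)
  d <- dim(g)
  if (length(d) == 2L) {
    return(weight_mask(g, p$w_b, p$w_m, p$w_0, p$kernel_size,
                       p$iterations)$weights)
  }
  stopifnot(length(d) == 4L)
  out <- array(0, dim = d)
  for (n in seq_len(d[4])) {
    for (ci in seq_len(d[3])) {
      out[, , ci, n] <- weight_mask(g[, , ci, n], p$w_b, p$w_m, p$w_0,
                                    p$kernel_size, p$iterations)$weights
    }
  }
  out
}

#' Binary cross-entropy loss
#'
#' @inheritParams mwl_loss
#' @return nonnegative scalar.
#' @export
ce_loss <- function(pred, gt, reduction = c("mean", "sum"), eps = 1e-7) {
  mwl_loss(pred, gt, weights = NULL, reduction = match.arg(reduction),
           eps = eps)
}

ce_loss_grad <- function(pred, gt, reduction = c("mean", "sum"), eps = 1e-7) {
  mwl_loss_grad(pred, gt, weights = NULL, reduction = match.arg(reduction),
                eps = eps)
}

#' Soft Dice loss
#'
#' `1 - (2 * sum(p*y) + s) / (sum(p) + sum(y) + s)` with smoothing `s`.
#'
#' @inheritParams mwl_loss
#' @param smooth additive smoothing constant.
#' @return scalar in `[0, 1]`.
#' @export
dice_loss <- function(pred, gt, smooth = 1) {
  z <- .loss_prep(pred, gt)
  1 - (2 * sum(z$p * z$y) + smooth) / (sum(z$p) + sum(z$y) + smooth)
}

dice_loss_grad <- function(pred, gt, smooth = 1) {
  z <- .loss_prep(pred, gt)
  num <- 2 * sum(z$p * z$y) + smooth
  den <- sum(z$p) + sum(z$y) + smooth
  -(2 * z$y * den - num) / den^2
}
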