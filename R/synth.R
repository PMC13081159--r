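# Synthetic CT-like phantom generator.
#
# Emulates the appearance that makes pneumonia lesions hard to segment:
# a smooth low-frequency background texture with Gaussian noise, and
# lesions formed as unions of random ellipses whose intensity offset is
# small and whose boundaries are Gaussian-blurred (ground-glass-like,
# low-contrast, blurred edges). Masks are the crisp (unblurred) ellipse
# supports. A configurable fraction of images additionally carries a small
# lesion (single component under 100 pixels), the regime where standard
# encoders lose targets during downsampling.

#' Synthetic dataset configuration
#'
#' @param n_images number of images.
#' @param image_size side length in pixels (square images).
#' @param n_lesions integer range `c(min, max)` of lesions per image.
#' @param lesion_radius range of ellipse semi-axes in pixels.
#' @param intensity_offset lesion-background intensity contrast in `[0, 1]`
#'   units (low values emulate ground-glass opacity).
#' @param boundary_blur Gaussian sigma (pixels) applied to the lesion
#'   intensity profile — the mask stays crisp, only the image is blurred.
#' @param small_lesion_fraction fraction of images that must contain at
#'   least one component with area below 100 pixels.
#' @param noise_sd additive Gaussian pixel noise SD.
#' @param seed RNG seed; the same seed reproduces the dataset exactly.
#' @return a `synth_config` list.
#' @export
synth_config <- function(n_images = 50L, image_size = 64L,
                         n_lesions = c(1L, 3L), lesion_radius = c(3, 10),
                         intensity_offset = 0.25, boundary_blur = 1.5,
                         small_lesion_fraction = 0.3, noise_sd = 0.05,
                         seed = 1L) {
  stopifnot(n_images >= 1L, image_size >= 8L,
            length(n_lesions) == 2L, length(lesion_radius) == 2L)
  if (max(lesion_radius) * 2 >= image_size) {
    stop("lesion radius too large for the image size")
  }
  structure(list(n_images = as.integer(n_images),
                 image_size = as.integer(image_size),
                 n_lesions = as.integer(n_lesions),
                 lesion_radius = as.numeric(lesion_radius),
                 intensity_offset = intensity_offset,
                 boundary_blur = boundary_blur,
                 small_lesion_fraction = small_lesion_fraction,
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "synth_config")
}

# separable Gaussian blur with border renormalization
gaussian_blur <- function(mat, sigma) {
  if (sigma <= 0) return(mat)
  r <- ceiling(3 * sigma)
  k <- stats::dnorm(-r:r, sd = sigma)
  band <- function(n) {
    K <- matrix(0, n, n)
    for (o in -r:r) {
      idx <- seq_len(n)
      tgt <- idx + o
      ok <- tgt >= 1 & tgt <= n
      K[cbind(idx[ok], tgt[ok])] <- K[cbind(idx[ok], tgt[ok])] + k[o + r + 1]
    }
    K / rowSums(K)
  }
  band(nrow(mat)) %*% mat %*% t(band(ncol(mat)))
}

# ellipse support on the pixel grid
.ellipse_mask <- function(size, ci, cj, a, b, theta) {
  di <- outer(seq_len(size) - ci, rep(1, size))
  dj <- outer(rep(1, size), seq_len(size) - cj)
  u <- (di * cos(theta) + dj * sin(theta)) / a
  v <- (-di * sin(theta) + dj * cos(theta)) / b
  (u^2 + v^2 <= 1) + 0
}

.draw_lesion <- function(size, radius_range, small = FALSE) {
  if (small) {
    # pi * a * b < 100 guaranteed: semi-axes at most 4.5
    a <- stats::runif(1, 1.5, 4.5)
    b <- stats::runif(1, 1.5, min(4.5, 95 / (pi * a)))
  } else {
    a <- stats::runif(1, radius_range[1], radius_range[2])
    b <- stats::runif(1, radius_range[1], radius_range[2])
  }
  m <- ceiling(max(a, b)) + 1
  ci <- stats::runif(1, m + 1, size - m)
  cj <- stats::runif(1, m + 1, size - m)
  .ellipse_mask(size, ci, cj, a, b, stats::runif(1, 0, pi))
}

#' Generate a synthetic CT-like dataset
#'
#' @param config a [synth_config()].
#' @param out_dir optional directory; if given, the dataset is written as
#'   paired 8-bit PNGs under `images/` and `masks/`.
#' @return list of samples (ids `synth_001`, ...).
#' @export
generate_synthetic <- function(config = synth_config(), out_dir = NULL) {
  stopifnot(inherits(config, "synth_config"))
  set.seed(config$seed)
  size <- config$image_size
  n_small <- round(config$small_lesion_fraction * config$n_images)
  small_in <- seq_len(config$n_images) <= n_small
  samples <- lapply(seq_len(config$n_images), function(i) {
    coarse <- matrix(stats::runif(64, 0.15, 0.45), 8, 8)
    bg <- resize_bilinear(coarse, c(size, size)) +
      matrix(stats::rnorm(size^2, sd = config$noise_sd), size, size)
    rng <- config$n_lesions[1]:config$n_lesions[2]
    k <- if (length(rng) == 1L) rng else sample(rng, 1)
    mask <- matrix(0, size, size)
    profile <- matrix(0, size, size)
    add <- function(les) {
      mask <<- pmax(mask, les)
      profile <<- pmax(profile, gaussian_blur(les, config$boundary_blur))
    }
    n_big <- if (small_in[i] && k > 0) k - 1 else k
    for (j in seq_len(n_big)) {
      add(.draw_lesion(size, config$lesion_radius, small = FALSE))
    }
    if (small_in[i] && k > 0) {
      # keep the small lesion a separate connected component: reject
      # placements touching (or diagonally adjacent to) existing lesions
      for (try in 1:100) {
        les <- .draw_lesion(size, config$lesion_radius, small = TRUE)
        if (sum(.morph_once(les, 3L, "max") * mask) == 0) break
      }
      add(les)
    }
    img <- pmin(pmax(bg + config$intensity_offset * profile, 0), 1)
    new_sample(img, mask, sprintf("synth_%03d", i))
  })
  if (!is.null(out_dir)) write_dataset(samples, out_dir)
  samples
}
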