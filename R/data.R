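# PNG image/mask I/O, dataset splitting, and paired augmentation.
#
# A sample is a list(image, mask, id): image a grayscale matrix in [0, 1],
# mask a binary matrix of the same shape. On disk, datasets follow the
# images/ masks/ convention with shared file stems, 8-bit grayscale PNGs,
# masks in {0, 255}.

new_sample <- function(image, mask, id) {
  stopifnot(identical(dim(image), dim(mask)))
  .check_binary(mask)
  structure(list(image = image, mask = mask, id = as.character(id)),
            class = "hf_sample")
}

#' @export
print.hf_sample <- function(x, ...) {
  cat("<sample '", x$id, "' ", nrow(x$image), "x", ncol(x$image),
      " fg=", sum(x$mask), "px>\n", sep = "")
  invisible(x)
}

.read_gray_png <- function(path) {
  img <- png::readPNG(path)
  if (length(dim(img)) == 3L) {
    warning("converting non-grayscale image to luminance: ", basename(path))
    img <- 0.299 * img[, , 1] + 0.587 * img[, , 2] + 0.114 * img[, , 3]
  }
  img
}

#' Load a paired image/mask dataset
#'
#' Pairs files by stem between the two directories. Images are scaled to
#' `[0, 1]`; masks are binarized at the 8-bit threshold 128.
#'
#' @param image_dir,mask_dir directories of PNG files with matching stems.
#' @return list of samples.
#' @export
load_dataset <- function(image_dir, mask_dir) {
  imgs <- sort(list.files(image_dir, pattern = "\\.png$"))
  if (length(imgs) == 0) stop("no PNG images found in ", image_dir)
  lapply(imgs, function(f) {
    stem <- sub("\\.png$", "", f)
    mask_path <- file.path(mask_dir, f)
    if (!file.exists(mask_path)) {
      stop("missing mask for image stem '", stem, "'")
    }
    image <- .read_gray_png(file.path(image_dir, f))
    mask <- .read_gray_png(mask_path)
    mask <- (round(mask * 255) >= 128) + 0
    new_sample(image, mask, stem)
  })
}

#' Write a dataset as paired PNGs
#'
#' @param samples list of samples.
#' @param dir output directory; `images/` and `masks/` are created inside.
#' @return the directory, invisibly.
#' @export
write_dataset <- function(samples, dir) {
  image_dir <- file.path(dir, "images")
  mask_dir <- file.path(dir, "masks")
  dir.create(image_dir, recursive = TRUE, showWarnings = FALSE)
  dir.create(mask_dir, recursive = TRUE, showWarnings = FALSE)
  for (s in samples) {
    png::writePNG(pmin(pmax(s$image, 0), 1),
                  file.path(image_dir, paste0(s$id, ".png")))
    png::writePNG(s$mask, file.path(mask_dir, paste0(s$id, ".png")))
  }
  invisible(dir)
}

#' Split a dataset into train/test/validation
#'
#' Seeded shuffle followed by a contiguous partition; the splits are
#' disjoint and exhaustive. Sizes are `floor(ratio * n)` for train and test,
#' the remainder goes to validation.
#'
#' @param samples list of samples.
#' @param ratios length-3 numeric summing to 1 (train, test, val).
#' @param seed shuffle seed.
#' @return list with elements `train`, `test`, `val`.
#' @export
split_dataset <- function(samples, ratios = c(0.7, 0.2, 0.1), seed = 1L) {
  stopifnot(length(ratios) == 3L)
  if (abs(sum(ratios) - 1) > 1e-6) stop("split ratios must sum to 1")
  n <- length(samples)
  set.seed(seed)
  idx <- sample.int(n)
  n_train <- floor(ratios[1] * n)
  n_test <- floor(ratios[2] * n)
  list(train = samples[idx[seq_len(n_train)]],
       test = samples[idx[n_train + seq_len(n_test)]],
       val = samples[idx[setdiff(seq_len(n), seq_len(n_train + n_test))]])
}

# ---- resizing ----

.resize_map <- function(n_in, n_out) {
  f <- (seq_len(n_out) - 0.5) * n_in / n_out + 0.5
  i0 <- floor(f)
  w <- f - i0
  i0 <- pmin(pmax(i0, 1L), n_in)
  list(i0 = as.integer(i0), i1 = as.integer(pmin(i0 + 1L, n_in)), w = w)
}

resize_bilinear <- function(mat, out_hw) {
  mh <- .resize_map(nrow(mat), out_hw[1])
  mw <- .resize_map(ncol(mat), out_hw[2])
  y <- mat[mh$i0, , drop = FALSE] * (1 - mh$w) +
    mat[mh$i1, , drop = FALSE] * mh$w
  t(t(y[, mw$i0, drop = FALSE]) * (1 - mw$w) +
      t(y[, mw$i1, drop = FALSE]) * mw$w)
}

resize_nearest <- function(mat, out_hw) {
  ri <- pmin(pmax(round((seq_len(out_hw[1]) - 0.5) * nrow(mat) / out_hw[1] +
                          0.5), 1L), nrow(mat))
  rj <- pmin(pmax(round((seq_len(out_hw[2]) - 0.5) * ncol(mat) / out_hw[2] +
                          0.5), 1L), ncol(mat))
  mat[ri, rj, drop = FALSE]
}

# crop or reflect/zero-pad a matrix back to a target size at a given offset
.fit_to <- function(mat, target, off_i = 1L, off_j = 1L, fill_reflect = TRUE) {
  d <- dim(mat)
  out <- matrix(0, target[1], target[2])
  ni <- min(d[1], target[1]); nj <- min(d[2], target[2])
  src_i <- if (d[1] > target[1]) off_i + seq_len(ni) - 1L else seq_len(ni)
  src_j <- if (d[2] > target[2]) off_j + seq_len(nj) - 1L else seq_len(nj)
  out[seq_len(ni), seq_len(nj)] <- mat[src_i, src_j]
  if (fill_reflect && (ni < target[1] || nj < target[2])) {
    ri <- c(seq_len(ni), rev(seq_len(ni)))[seq_len(target[1])]
    rj <- c(seq_len(nj), rev(seq_len(nj)))[seq_len(target[2])]
    out <- out[ri, rj, drop = FALSE]
  }
  out
}

#' Training-time augmentation
#'
#' Applies, each with probability 0.5: horizontal flip, vertical flip,
#' scaling (factor U(0.8, 1.2), result cropped or reflect-padded back to the
#' original size at a random offset), random cropping (window of fraction
#' U(0.8, 1), resized back), and contrast adjustment (gamma U(0.8, 1.2),
#' image only). Geometric transforms are applied identically to image and
#' mask; the mask is resized with nearest-neighbor interpolation and remains
#' binary.
#'
#' @param sample a dataset sample.
#' @param seed optional seed for the parameter draw.
#' @param params optional explicit parameter list (fields `hflip`, `vflip`,
#'   `scale`, `crop_frac`, `gamma`; any subset) overriding the random draw —
#'   useful for deterministic transforms.
#' @return augmented sample.
#' @export
augment <- function(sample, seed = NULL, params = NULL) {
  if (!is.null(seed)) set.seed(seed)
  d <- dim(sample$image)
  if (is.null(params)) {
    params <- list(
      hflip = stats::runif(1) < 0.5,
      vflip = stats::runif(1) < 0.5,
      scale = if (stats::runif(1) < 0.5) stats::runif(1, 0.8, 1.2) else 1,
      crop_frac = if (stats::runif(1) < 0.5) stats::runif(1, 0.8, 1) else 1,
      gamma = if (stats::runif(1) < 0.5) stats::runif(1, 0.8, 1.2) else 1)
  } else {
    params <- utils::modifyList(list(hflip = FALSE, vflip = FALSE, scale = 1,
                                     crop_frac = 1, gamma = 1), params)
  }
  img <- sample$image; msk <- sample$mask
  if (isTRUE(params$hflip)) {
    img <- img[, rev(seq_len(d[2])), drop = FALSE]
    msk <- msk[, rev(seq_len(d[2])), drop = FALSE]
  }
  if (isTRUE(params$vflip)) {
    img <- img[rev(seq_len(d[1])), , drop = FALSE]
    msk <- msk[rev(seq_len(d[1])), , drop = FALSE]
  }
  if (params$scale != 1) {
    new_hw <- pmax(round(d * params$scale), 2L)
    img <- resize_bilinear(img, new_hw)
    msk <- resize_nearest(msk, new_hw)
    off_i <- if (new_hw[1] > d[1]) sample.int(new_hw[1] - d[1] + 1L, 1) else 1L
    off_j <- if (new_hw[2] > d[2]) sample.int(new_hw[2] - d[2] + 1L, 1) else 1L
    img <- .fit_to(img, d, off_i, off_j, fill_reflect = TRUE)
    msk <- .fit_to(msk, d, off_i, off_j, fill_reflect = FALSE)
  }
  if (params$crop_frac < 1) {
    win <- pmax(round(d * params$crop_frac), 2L)
    if (any(win > d)) stop("crop window larger than image")
    off_i <- sample.int(d[1] - win[1] + 1L, 1)
    off_j <- sample.int(d[2] - win[2] + 1L, 1)
    img <- resize_bilinear(img[off_i + seq_len(win[1]) - 1L,
                               off_j + seq_len(win[2]) - 1L, drop = FALSE], d)
    msk <- resize_nearest(msk[off_i + seq_len(win[1]) - 1L,
                              off_j + seq_len(win[2]) - 1L, drop = FALSE], d)
  }
  if (params$gamma != 1) img <- pmin(pmax(img, 0), 1)^params$gamma
  new_sample(pmin(pmax(img, 0), 1), msk, sample$id)
}
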