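# Shared fixtures and independent brute-force oracles used across tests.

random_mask <- function(h, w, p = 0.4) {
  matrix(as.numeric(stats::runif(h * w) < p), h, w)
}

# brute-force 2x2 block means of an even-sized matrix
brute_avgpool2 <- function(x) {
  h2 <- nrow(x) / 2; w2 <- ncol(x) / 2
  out <- matrix(0, h2, w2)
  for (i in seq_len(h2)) {
    for (j in seq_len(w2)) {
      out[i, j] <- mean(x[(2 * i - 1):(2 * i), (2 * j - 1):(2 * j)])
    }
  }
  out
}

# brute-force morphology by scanning the k x k neighborhood of every pixel,
# zero padding outside the image
brute_morph <- function(mask, kernel_size = 3L, op = c("erode", "dilate")) {
  op <- match.arg(op)
  r <- (kernel_size - 1L) %/% 2L
  h <- nrow(mask); w <- ncol(mask)
  out <- matrix(0, h, w)
  for (i in seq_len(h)) {
    for (j in seq_len(w)) {
      vals <- c()
      for (di in -r:r) {
        for (dj in -r:r) {
          ii <- i + di; jj <- j + dj
          vals <- c(vals,
                    if (ii < 1 || ii > h || jj < 1 || jj > w) 0
                    else mask[ii, jj])
        }
      }
      out[i, j] <- if (op == "erode") min(vals) else max(vals)
    }
  }
  out
}

# brute-force pixel confusion tally
brute_confusion <- function(pred, gt) {
  tp <- 0L; fp <- 0L; fn <- 0L; tn <- 0L
  for (i in seq_along(pred)) {
    if (pred[i] == 1 && gt[i] == 1) tp <- tp + 1L
    else if (pred[i] == 1 && gt[i] == 0) fp <- fp + 1L
    else if (pred[i] == 0 && gt[i] == 1) fn <- fn + 1L
    else tn <- tn + 1L
  }
  list(tp = tp, fp = fp, fn = fn, tn = tn)
}

# small model/training settings used by the fast engine tests
tiny_model_cfg <- function() model_config(levels = 2L, base_channels = 4L)

tiny_train_cfg <- function(steps = 5L, seed = 1L, ...) {
  train_config(batch_size = 2L, total_steps = steps, augment = FALSE,
               seed = seed, ...)
}

tiny_samples <- function(n = 4L, size = 16L, seed = 3L) {
  generate_synthetic(synth_config(n_images = n, image_size = size,
                                  lesion_radius = c(2, 5),
                                  small_lesion_fraction = 0, seed = seed))
}
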