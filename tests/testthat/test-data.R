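test_that("synthetic generation is seed-reproducible, byte for byte", {
  cfg <- synth_config(n_images = 3, image_size = 32, seed = 9)
  d1 <- file.path(tempdir(), "synth_a")
  d2 <- file.path(tempdir(), "synth_b")
  unlink(c(d1, d2), recursive = TRUE)
  generate_synthetic(cfg, out_dir = d1)
  generate_synthetic(cfg, out_dir = d2)
  for (sub in c("images", "masks")) {
    for (f in list.files(file.path(d1, sub))) {
      expect_identical(readBin(file.path(d1, sub, f), "raw", 1e6),
                       readBin(file.path(d2, sub, f), "raw", 1e6))
    }
  }
})

test_that("synthetic lesions respect the configuration", {
  # every image carries a sub-100-pixel component when the fraction is 1
  s <- generate_synthetic(synth_config(n_images = 8, image_size = 48,
                                       small_lesion_fraction = 1, seed = 10))
  for (smp in s) {
    expect_gte(count_small_lesions(smp$mask), 1)
  }
  # no lesions requested: empty masks
  s0 <- generate_synthetic(synth_config(n_images = 2, image_size = 32,
                                        n_lesions = c(0L, 0L), seed = 11))
  expect_true(all(vapply(s0, function(x) sum(x$mask), 0) == 0))
  # masks binary, images in range
  s1 <- generate_synthetic(synth_config(n_images = 2, image_size = 32,
                                        seed = 12))
  for (smp in s1) {
    expect_true(all(smp$mask %in% c(0, 1)))
    expect_true(all(smp$image >= 0 & smp$image <= 1))
  }
  expect_error(synth_config(image_size = 16, lesion_radius = c(3, 10)),
               "radius")
})

test_that("write/load round-trip is exact for masks, 8-bit for images", {
  s <- generate_synthetic(synth_config(n_images = 3, image_size = 32,
                                       seed = 13))
  d <- file.path(tempdir(), "roundtrip")
  unlink(d, recursive = TRUE)
  write_dataset(s, d)
  loaded <- load_dataset(file.path(d, "images"), file.path(d, "masks"))
  expect_length(loaded, 3)
  for (i in seq_along(s)) {
    expect_identical(loaded[[i]]$id, s[[i]]$id)
    expect_equal(loaded[[i]]$mask, s[[i]]$mask)
    expect_lt(max(abs(loaded[[i]]$image - s[[i]]$image)), 1 / 255)
  }
  # missing mask names the stem
  file.remove(file.path(d, "masks", paste0(s[[2]]$id, ".png")))
  expect_error(load_dataset(file.path(d, "images"), file.path(d, "masks")),
               s[[2]]$id)
})

test_that("mask binarization thresholds 8-bit PNGs at 128", {
  d <- file.path(tempdir(), "binarize")
  dir.create(file.path(d, "images"), recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(d, "masks"), recursive = TRUE, showWarnings = FALSE)
  png::writePNG(matrix(0.5, 2, 2), file.path(d, "images", "a.png"))
  png::writePNG(matrix(c(0, 127, 128, 255) / 255, 2, 2),
                file.path(d, "masks", "a.png"))
  s <- load_dataset(file.path(d, "images"), file.path(d, "masks"))
  expect_equal(as.vector(s[[1]]$mask), c(0, 0, 1, 1))
})

test_that("RGB images are converted to luminance with a warning", {
  d <- file.path(tempdir(), "rgb")
  dir.create(file.path(d, "images"), recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(d, "masks"), recursive = TRUE, showWarnings = FALSE)
  rgb <- array(runif(4 * 4 * 3), dim = c(4, 4, 3))
  png::writePNG(rgb, file.path(d, "images", "a.png"))
  png::writePNG(matrix(1, 4, 4), file.path(d, "masks", "a.png"))
  expect_warning(s <- load_dataset(file.path(d, "images"),
                                   file.path(d, "masks")), "luminance")
  lum <- 0.299 * rgb[, , 1] + 0.587 * rgb[, , 2] + 0.114 * rgb[, , 3]
  expect_equal(s[[1]]$image, lum, tolerance = 1 / 255)
})

test_that("split_dataset partitions deterministically by seed", {
  s <- tiny_samples(n = 10, size = 16)
  sp <- split_dataset(s, c(0.7, 0.2, 0.1), seed = 5)
  expect_length(sp$train, 7)
  expect_length(sp$test, 2)
  expect_length(sp$val, 1)
  sp2 <- split_dataset(s, c(0.7, 0.2, 0.1), seed = 5)
  expect_identical(lapply(sp$train, `[[`, "id"),
                   lapply(sp2$train, `[[`, "id"))
  all_ids <- sort(unlist(lapply(c(sp$train, sp$test, sp$val), `[[`, "id")))
  expect_identical(all_ids, sort(vapply(s, `[[`, "", "id")))
  expect_error(split_dataset(s, c(0.5, 0.2, 0.1)), "sum to 1")
})

test_that("augmentation keeps masks binary and geometry consistent", {
  s <- tiny_samples(n = 1, size = 16)[[1]]
  # flips are involutions and preserve foreground area
  f1 <- augment(s, params = list(hflip = TRUE))
  f2 <- augment(f1, params = list(hflip = TRUE))
  expect_equal(f2$image, s$image)
  expect_equal(f2$mask, s$mask)
  expect_equal(sum(f1$mask), sum(s$mask))
  v1 <- augment(s, params = list(vflip = TRUE))
  expect_equal(sum(v1$mask), sum(s$mask))
  # random parameter draws: shape preserved, mask stays binary
  for (seed in 1:10) {
    a <- augment(s, seed = seed)
    expect_identical(dim(a$image), dim(s$image))
    expect_true(all(a$mask %in% c(0, 1)))
    expect_true(all(a$image >= 0 & a$image <= 1))
  }
  # identical seeds give identical augmentations
  expect_equal(augment(s, seed = 3), augment(s, seed = 3))
})
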