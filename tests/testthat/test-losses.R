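test_that("erosion and dilation match a brute-force neighborhood scan", {
  ones <- matrix(1, 4, 4)
  er <- binary_erosion(ones, 3)
  expect_true(all(er[2:3, 2:3] == 1))
  expect_true(all(er[c(1, 4), ] == 0) && all(er[, c(1, 4)] == 0))

  sq <- matrix(0, 4, 4); sq[2:3, 2:3] <- 1
  expect_true(all(binary_erosion(sq, 3) == 0))

  dot <- matrix(0, 5, 5); dot[3, 3] <- 1
  di <- binary_dilation(dot, 3)
  expect_true(all(di[2:4, 2:4] == 1) && sum(di) == 9)
  expect_true(all(binary_dilation(matrix(0, 4, 4), 3) == 0))

  set.seed(41)
  for (rep in 1:20) {
    m <- random_mask(8, 8)
    expect_equal(binary_erosion(m, 3), brute_morph(m, 3, "erode"))
    expect_equal(binary_dilation(m, 3), brute_morph(m, 3, "dilate"))
    expect_true(all(binary_erosion(m, 3) <= m))          # anti-extensive
    expect_true(all(binary_dilation(m, 3) >= m))         # extensive
    # two iterations equal one pass with the doubled-radius brute force
    expect_equal(binary_erosion(m, 3, iterations = 2),
                 brute_morph(m, 5, "erode"))
  }
  expect_error(binary_erosion(matrix(2, 2, 2)), "binary")
})

test_that("weight_mask partitions the image into the three regions", {
  # empty gt: everything is background
  wm <- weight_mask(matrix(0, 5, 5), w_b = 0.5, w_m = 2, w_0 = 1)
  expect_true(all(wm$weights == 0.5))
  # all-equal weights collapse to unity regardless of the mask
  set.seed(42)
  for (rep in 1:20) {
    g <- random_mask(8, 8)
    expect_true(all(weight_mask(g, 1, 1, 1)$weights == 1))
    # partition of unity of the three indicators
    we <- binary_erosion(g, 3); wd <- binary_dilation(g, 3)
    expect_true(all((1 - wd) + (wd - we) + we == 1))
    expect_true(all(wd - we >= 0))
  }
  # 2x2 square in 4x4: erosion empty, dilation full -> all margin
  sq <- matrix(0, 4, 4); sq[2:3, 2:3] <- 1
  expect_true(all(weight_mask(sq, 1, 2, 1)$weights == 2))
  expect_error(weight_mask(sq, w_b = -1), "nonnegative")
})

test_that("mwl_loss reproduces hand-computed values and reduces to BCE", {
  # 2x2 toy: gt one positive pixel, uniform 0.5 prediction, sum form
  gt <- rbind(c(1, 0), c(0, 0))
  pred <- matrix(0.5, 2, 2)
  expect_equal(mwl_loss(pred, gt, reduction = "sum"), 4 * log(2),
               tolerance = 1e-12)
  expect_equal(ce_loss(pred, gt), log(2), tolerance = 1e-12)

  set.seed(43)
  for (rep in 1:10) {
    g <- random_mask(6, 6)
    p <- matrix(runif(36, 0.05, 0.95), 6, 6)
    expect_equal(mwl_loss(p, g, reduction = "sum"),
                 ce_loss(p, g, reduction = "sum"), tolerance = 1e-9)
  }
  # perfect prediction: bounded by the clamp
  g <- random_mask(6, 6)
  eps <- 1e-7
  l <- mwl_loss(g, g, mwl_params = list(w_m = 3), reduction = "sum")
  expect_lte(l, 36 * (-log(1 - eps)) * 3)
  expect_gte(l, 0)
  # dice loss vanishes at a perfect binary prediction (up to smoothing)
  expect_lt(dice_loss(g, g), 0.05)
  expect_gt(dice_loss(1 - g, g), 0.9)
})

test_that("raising the margin weight raises the loss", {
  set.seed(44)
  g <- matrix(0, 8, 8); g[3:6, 3:6] <- 1
  p <- matrix(runif(64, 0.2, 0.8), 8, 8)
  l2 <- mwl_loss(p, g, mwl_params = list(w_m = 2))
  l4 <- mwl_loss(p, g, mwl_params = list(w_m = 4))
  expect_gt(l4, l2)
})

test_that("analytic loss gradients match central finite differences", {
  set.seed(45)
  gt <- rbind(c(1, 1, 0), c(0, 1, 0), c(0, 0, 0))
  pred <- matrix(runif(9, 0.1, 0.9), 3, 3)
  for (setup in list(
    list(v = function(p) mwl_loss(p, gt, mwl_params = list(w_m = 2.5)),
         g = function(p) mwl_loss_grad(p, gt, mwl_params = list(w_m = 2.5))),
    list(v = function(p) ce_loss(p, gt),
         g = function(p) hfsunet:::ce_loss_grad(p, gt)),
    list(v = function(p) dice_loss(p, gt),
         g = function(p) hfsunet:::dice_loss_grad(p, gt)))) {
    g_an <- setup$g(pred)
    h <- 1e-6
    for (i in seq_along(pred)) {
      pp <- pred; pp[i] <- pred[i] + h
      pm <- pred; pm[i] <- pred[i] - h
      g_fd <- (setup$v(pp) - setup$v(pm)) / (2 * h)
      expect_equal(g_an[i], g_fd, tolerance = 1e-4)
    }
  }
})

test_that("loss input validation catches shape and range errors", {
  expect_error(mwl_loss(matrix(0.5, 2, 2), matrix(0, 2, 3)), "shapes differ")
  expect_error(mwl_loss(matrix(1.5, 2, 2), matrix(0, 2, 2)), "0, 1")
  expect_error(mwl_loss(matrix(0.5, 2, 2), matrix(0.3, 2, 2)), "binary")
})
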