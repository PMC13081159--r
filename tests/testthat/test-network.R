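# closed-form parameter count assembled independently from the config
analytic_param_count <- function(levels, base) {
  ch <- base * 2^(seq_len(levels) - 1)
  dconv <- function(cin, cout) 9 * cin * cout + 9 * cout^2 + 4 * cout
  total <- dconv(1, ch[1])
  for (l in 2:levels) {
    total <- total + 4 * ch[l - 1]^2 + 2 * ch[l - 1]      # HWD conv + BN
    total <- total + dconv(ch[l - 1], ch[l])
  }
  for (l in seq_len(levels - 1)) {                        # MSAM per skip
    C <- ch[l]; cc <- C / 4; cb <- C / 4
    total <- total + C * cc +                             # compress
      (9 + 25 + 49) * cc + 2 * cc +                       # depthwise + BN
      (cc + 1) + (cc * C + C) +                           # pw_spatial, pw_fuse
      (C * cb + cb) + (cb * C + C)                        # channel MLP
  }
  for (l in seq_len(levels - 1)) {                        # decoder stages
    total <- total + 9 * ch[l + 1] * ch[l] + 2 * ch[l] +  # up conv + BN
      dconv(2 * ch[l], ch[l])
  }
  total + ch[1] + 1                                       # 1x1 head
}

test_that("build_model produces a shape-preserving sigmoid segmenter", {
  set.seed(31)
  cfg <- model_config(levels = 3, base_channels = 8)
  model <- build_model(cfg)
  x <- array(runif(32 * 32 * 2), dim = c(32, 32, 1, 2))
  p <- model_forward(model, x)
  expect_identical(dim(p), dim(x))
  expect_true(all(p > 0 & p < 1))
  # degenerate two-level config builds and runs (single HWD stage)
  m2 <- build_model(model_config(levels = 2, base_channels = 4))
  expect_identical(dim(model_forward(m2, array(runif(16 * 16), c(16, 16, 1, 1)))),
                   c(16L, 16L, 1L, 1L))
  # zeroed head -> probability one half everywhere
  model$head$w$value[] <- 0
  model$head$b$value[] <- 0
  expect_true(all(model_forward(model, x) == 0.5))
})

test_that("invalid input sizes raise an error suggesting the pad size", {
  set.seed(32)
  model <- build_model(model_config(levels = 3, base_channels = 4))
  expect_error(model_forward(model, array(0, c(30, 32, 1, 1))), "pad to 32x32")
  padded <- pad_to_multiple(matrix(runif(30 * 31), 30, 31), 4)
  expect_identical(dim(padded$image), c(32L, 32L))
  expect_identical(padded$shape, c(30L, 31L))
})

test_that("seeded builds are identical; transposed-conv decoder runs", {
  cfg <- model_config(levels = 2, base_channels = 4)
  set.seed(33); m1 <- build_model(cfg)
  set.seed(33); m2 <- build_model(cfg)
  p1 <- hfsunet:::collect_params(m1)
  p2 <- hfsunet:::collect_params(m2)
  expect_equal(lapply(p1, function(p) p$value),
               lapply(p2, function(p) p$value))
  set.seed(34)
  mt <- build_model(model_config(levels = 2, base_channels = 4,
                                 upsample_mode = "transposed"))
  x <- array(runif(8 * 8), dim = c(8, 8, 1, 1))
  expect_identical(dim(model_forward(mt, x)), c(8L, 8L, 1L, 1L))
})

test_that("count_parameters matches a layerwise closed form", {
  set.seed(35)
  # single conv layer: 3x3, 1 -> 8 channels with bias = 8*9 + 8 = 80
  layer <- hfsunet:::conv_layer(3L, 3L, 1L, 8L, bias = TRUE)
  expect_identical(count_parameters(list(layer)), 80)
  for (cfgp in list(c(3, 8), c(2, 4), c(4, 8))) {
    m <- build_model(model_config(levels = cfgp[1], base_channels = cfgp[2]))
    expect_identical(count_parameters(m),
                     analytic_param_count(cfgp[1], cfgp[2]))
  }
  # halving base width cuts conv-dominated counts by roughly 4x
  r <- analytic_param_count(3, 16) / analytic_param_count(3, 8)
  expect_gt(r, 3.5); expect_lt(r, 4.1)
})

test_that("estimate_flops is analytic and scales with pixel count", {
  expect_identical(conv_flops(1, 1, 4, 4, 8, 8), 2048)
  set.seed(36)
  m <- build_model(model_config(levels = 3, base_channels = 8))
  f32 <- estimate_flops(m, c(32, 32))
  f64 <- estimate_flops(m, c(64, 64))
  expect_equal(as.numeric(f64) / as.numeric(f32), 4, tolerance = 1e-3)
  bd <- attr(f32, "breakdown")
  expect_equal(sum(bd$flops), as.numeric(f32))
  # hand tally of a two-level toy (levels = 2, base = 4, 8x8 input)
  m2 <- build_model(model_config(levels = 2, base_channels = 4))
  hand <- (4608 + 768 + 18432 + 768) +                 # enc1
    (1024 + 2048 + 192) +                              # hwd: haar + 1x1 + bn
    (9216 + 384 + 18432 + 384) +                       # enc2
    (4096 + 36864 + 768) +                             # upsample + conv + bn
    (512 + 1152 + 3200 + 6272 + 192 +                  # msam spatial trunk
       128 + 64 + 256 +                                # pw_spatial + sigmoid
       512 + 256 +                                     # pw_fuse
       256 + 9 + 1 + 12 + 16 +                         # gap + channel mlp
       512 + 256) +                                    # scaling + residual
    (36864 + 768 + 18432 + 768) +                      # dec1
    (512 + 64 + 256)                                   # head conv + bias + sigmoid
  expect_equal(as.numeric(estimate_flops(m2, c(8, 8))), hand)
})

test_that("every parameter receives gradient on a random batch", {
  set.seed(37)
  model <- build_model(model_config(levels = 3, base_channels = 8))
  x <- tensor(array(runif(32 * 32 * 1 * 4), dim = c(32, 32, 1, 4)))
  gt <- array(as.numeric(runif(32 * 32 * 4) < 0.3), dim = c(32, 32, 1, 4))
  pred <- model_forward(model, x, training = TRUE)
  backward(pred, seed = mwl_loss_grad(pred$value, gt))
  for (p in hfsunet:::collect_params(model)) {
    expect_false(is.null(p$grad))
    expect_gt(sum(abs(p$grad)), 0)
  }
})
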