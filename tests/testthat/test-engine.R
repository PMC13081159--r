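test_that("training is deterministic under a fixed seed", {
  s <- tiny_samples()
  f1 <- train(s, config = tiny_train_cfg(steps = 3, seed = 2),
              model_cfg = tiny_model_cfg())
  f2 <- train(s, config = tiny_train_cfg(steps = 3, seed = 2),
              model_cfg = tiny_model_cfg())
  expect_identical(f1$history$loss, f2$history$loss)
  f3 <- train(s, config = tiny_train_cfg(steps = 3, seed = 4),
              model_cfg = tiny_model_cfg())
  expect_false(identical(f1$history$loss[1], f3$history$loss[1]))
})

test_that("loss decreases over a short MWL run and NaN inputs abort", {
  s <- tiny_samples()
  f <- train(s, config = tiny_train_cfg(steps = 40, seed = 2,
                                        learning_rate = 1e-3),
             model_cfg = tiny_model_cfg())
  expect_lt(mean(tail(f$history$loss, 5)), mean(head(f$history$loss, 5)))
  expect_error(train(list(), config = tiny_train_cfg()), "empty")
})

test_that("early stopping with patience 0 halts at the first flat check", {
  s <- tiny_samples(n = 6)
  # learning rate so small that validation mIoU cannot improve between checks
  f <- train(s[1:4], val_samples = s[5:6],
             config = tiny_train_cfg(steps = 50, seed = 2,
                                     learning_rate = 1e-12,
                                     early_stopping_patience = 0L,
                                     eval_every = 5L),
             model_cfg = tiny_model_cfg())
  expect_true(f$early_stopped)
  # stops well before the 50-step budget (BN running statistics may nudge
  # the validation score across the first couple of checks)
  expect_lt(nrow(f$history), 25)
})

test_that("checkpoint round-trip reproduces metrics bit for bit", {
  s <- tiny_samples()
  f <- train(s, config = tiny_train_cfg(steps = 5, seed = 2),
             model_cfg = tiny_model_cfg())
  ev1 <- evaluate(f, s)
  ck <- file.path(tempdir(), "model.rds")
  save_checkpoint(f, ck)
  m2 <- load_checkpoint(ck)
  ev2 <- evaluate(m2, s)
  expect_identical(ev1$per_image, ev2$per_image)
  expect_identical(ev1$aggregates, ev2$aggregates)
})

test_that("evaluate writes one CSV row per image with the metric columns", {
  s <- tiny_samples(n = 3)
  set.seed(71)
  model <- build_model(tiny_model_cfg())
  csv <- file.path(tempdir(), "eval.csv")
  ev <- evaluate(model, s, out_csv = csv)
  expect_equal(nrow(ev$per_image), 3)
  got <- utils::read.csv(csv)
  expect_equal(nrow(got), 3)
  expect_true(all(c("id", "miou", "dice", "f1", "acc", "n_lesions",
                    "n_small_lesions") %in% names(got)))
  # all-background predictions on lesion images: zero foreground IoU
  model$head$w$value[] <- 0
  model$head$b$value[] <- -10
  ev0 <- evaluate(model, s)
  fg_iou <- 2 * ev0$per_image$dice / (200 - ev0$per_image$dice)
  expect_true(all(ev0$per_image$dice == 0))
  expect_true(all(fg_iou == 0))
})

test_that("predict_dir writes idempotent 0/255 masks with thresholds", {
  s <- tiny_samples(n = 2)
  d <- file.path(tempdir(), "predict_io")
  unlink(d, recursive = TRUE)
  write_dataset(s, d)
  set.seed(72)
  model <- build_model(tiny_model_cfg())
  out1 <- file.path(d, "pred1"); out2 <- file.path(d, "pred2")
  predict_dir(model, file.path(d, "images"), out1)
  predict_dir(model, file.path(d, "images"), out2)
  for (f in list.files(out1)) {
    expect_identical(readBin(file.path(out1, f), "raw", 1e6),
                     readBin(file.path(out2, f), "raw", 1e6))
    px <- png::readPNG(file.path(out1, f))
    expect_true(all(px %in% c(0, 1)))
  }
  # threshold extremes
  expect_true(all(predict_mask(model, s[[1]]$image, threshold = 1.01) == 0))
  expect_true(all(predict_mask(model, s[[1]]$image, threshold = 0) == 1))
  # non-divisible sizes are padded with a warning
  expect_warning(pm <- predict_mask(model, s[[1]]$image[1:15, 1:16]),
                 "padding")
  expect_identical(dim(pm), c(15L, 16L))
})

test_that("compare_runs reproduces the paired test and flags degeneracy", {
  df <- data.frame(id = c("a", "b", "c"), miou = c(90, 92, 91))
  ca <- file.path(tempdir(), "runA.csv")
  cb <- file.path(tempdir(), "runB.csv")
  utils::write.csv(df, ca, row.names = FALSE)
  df$miou <- df$miou + c(0.5, 1.5, 1.0)
  utils::write.csv(df, cb, row.names = FALSE)
  rep <- compare_runs(ca, cb)
  direct <- paired_t_test(paired_scores(c(90, 92, 91),
                                        c(90.5, 93.5, 92)))
  expect_equal(rep$t_test$t, direct$t)
  expect_equal(rep$t_test$p, direct$p)
  # a run against itself: zero SD flagged, no effect size
  rep_same <- compare_runs(ca, ca)
  expect_true(is.nan(rep_same$t_test$t))
  expect_true(isTRUE(rep_same$t_test$degenerate))
  # constant offset: mean difference recovered, t infinite but flagged
  df2 <- utils::read.csv(ca); df2$miou <- df2$miou + 0.1
  cc <- file.path(tempdir(), "runC.csv")
  utils::write.csv(df2, cc, row.names = FALSE)
  rep_c <- compare_runs(ca, cc)
  expect_equal(rep_c$summary["mean", "difference"], 0.1)
  expect_true(isTRUE(rep_c$t_test$degenerate))
  expect_true(is.na(rep_c$cohens_d))
  # id mismatch
  df3 <- df; df3$id <- c("a", "b", "z")
  cd <- file.path(tempdir(), "runD.csv")
  utils::write.csv(df3, cd, row.names = FALSE)
  expect_error(compare_runs(ca, cd), "id mismatch")
})
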