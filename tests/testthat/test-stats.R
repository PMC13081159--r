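test_that("paired_summary uses sample SD and SE = SD/sqrt(n)", {
  ps <- paired_scores(c(0, 0, 0), c(1, 2, 3))
  sm <- paired_summary(ps)
  expect_equal(sm["mean", "difference"], 2)
  expect_equal(sm["sd", "difference"], 1)
  expect_equal(sm["se", "difference"], 1 / sqrt(3))
  expect_equal(sm["median", "b"], 2)
  expect_equal(sm["min", "b"], 1)
  expect_equal(sm["max", "b"], 3)
  expect_error(paired_summary(paired_scores(1, 2)), "n >= 2")
  expect_error(paired_scores(1:3, 1:2))
})

test_that("paired t statistic matches the closed form and stats::t.test", {
  ps <- paired_scores(c(0, 0, 0), c(1, 2, 3))
  tt <- paired_t_test(ps)
  expect_equal(tt$t, 2 * sqrt(3), tolerance = 1e-12)
  expect_equal(tt$df, 2)

  set.seed(61)
  for (rep in 1:10) {
    a <- rnorm(20, 80, 5); b <- a + rnorm(20, 0.5, 1)
    ps <- paired_scores(a, b)
    tt <- paired_t_test(ps)
    ref <- stats::t.test(b, a, paired = TRUE, alternative = "greater")
    expect_equal(tt$t, unname(ref$statistic), tolerance = 1e-10)
    expect_equal(tt$p, ref$p.value, tolerance = 1e-10)
    expect_equal(tt$df, unname(ref$parameter))
    # shift invariance
    ps2 <- paired_scores(a + 7, b + 7)
    expect_equal(paired_t_test(ps2)$t, tt$t, tolerance = 1e-9)
    expect_equal(cohens_d(ps2), cohens_d(ps), tolerance = 1e-9)
    # common rescaling leaves t and d unchanged
    ps3 <- paired_scores(a * 3, b * 3)
    expect_equal(paired_t_test(ps3)$t, tt$t, tolerance = 1e-9)
    expect_equal(cohens_d(ps3), cohens_d(ps), tolerance = 1e-9)
  }
})

test_that("degenerate zero-SD differences are flagged explicitly", {
  ps <- paired_scores(c(1, 2, 3), c(2, 3, 4))   # constant difference 1
  tt <- paired_t_test(ps)
  expect_true(isTRUE(tt$degenerate))
  expect_identical(tt$t, Inf)
  expect_equal(tt$p, 0)
  expect_error(cohens_d(ps), "zero SD")
  tie <- paired_t_test(paired_scores(1:3, 1:3))
  expect_true(is.nan(tie$t))
})

test_that("cohens_d is the mean/SD ratio and flips with arm order", {
  ps <- paired_scores(c(0, 0, 0), c(1, 2, 3))
  expect_equal(cohens_d(ps), 2)
  expect_equal(cohens_d(paired_scores(c(1, 2, 3), c(0, 0, 0))), -2)
  expect_equal(cohens_d_from_summary(0.0497, 0.0766), 0.0497 / 0.0766)
})

test_that("one-tailed p decreases in t and approaches the normal tail", {
  ts <- c(0.5, 1, 2, 3)
  ps <- stats::pt(ts, df = 10, lower.tail = FALSE)
  expect_true(all(diff(ps) < 0))
  # moderate statistics at df >= 200: t tail within 10% of the normal tail
  for (t in c(1, 2)) {
    # mean/SD chosen so the t statistic equals t at df = 200
    res <- paired_t_from_summary(t / sqrt(201), 1, 201)
    expect_equal(res$t, t, tolerance = 1e-12)
    p_n <- stats::pnorm(t, lower.tail = FALSE)
    expect_lt(abs(res$p - p_n) / p_n, 0.1)
  }
  # far tails need larger df for the same accuracy
  res3 <- paired_t_from_summary(3 / sqrt(2001), 1, 2001)
  expect_lt(abs(res3$p - stats::pnorm(3, lower.tail = FALSE)) /
              stats::pnorm(3, lower.tail = FALSE), 0.1)
})

test_that("comparison_report fractions match a brute-force loop", {
  # identical arms: nothing strictly above y = x
  ps <- paired_scores(c(1, 2, 3), c(1, 2, 3))
  rep0 <- comparison_report(ps)
  expect_equal(rep0$frac_above, 0)
  expect_true(is.na(rep0$cohens_d))

  ps2 <- paired_scores(c(1, 2), c(2, 3))
  expect_equal(comparison_report(ps2)$frac_above, 100)

  set.seed(62)
  a <- rnorm(30); b <- a + rnorm(30, 0.2, 0.5)
  ps3 <- paired_scores(a, b)
  rep3 <- comparison_report(ps3, threshold = 0.3)
  above <- 0; large_pos <- 0; large <- 0
  for (i in 1:30) {
    if (b[i] > a[i]) above <- above + 1
    if (abs(b[i] - a[i]) > 0.3) {
      large <- large + 1
      if (b[i] > a[i]) large_pos <- large_pos + 1
    }
  }
  expect_equal(rep3$frac_above, 100 * above / 30)
  expect_equal(rep3$n_large, large)
  expect_equal(rep3$frac_large_positive, 100 * large_pos / large)
  expect_named(rep3$plots, c("differences", "boxplot", "scatter"))

  out <- file.path(tempdir(), "cmp_report")
  comparison_report(ps3, out_dir = out)
  expect_true(all(file.exists(file.path(out, c("summary.csv",
                                               "differences.png",
                                               "boxplot.png",
                                               "scatter.png")))))
})
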