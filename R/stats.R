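# Paired statistical comparison of two models' per-image scores.
#
# Given aligned per-image metric vectors (e.g. mIoU in percent) from two
# models evaluated on the same test images, the module computes descriptive
# summaries, a one-tailed paired t-test (alternative: model B > model A),
# and Cohen's d for paired data (mean difference over the sample SD of the
# differences, n-1 denominator).

#' Construct paired per-image scores
#'
#' @param scores_a,scores_b aligned numeric vectors (model A and model B).
#' @param ids optional image identifiers.
#' @return object of class `paired_scores` with the two arms, the
#'   differences `b - a`, and `n`.
#' @export
paired_scores <- function(scores_a, scores_b, ids = NULL) {
  stopifnot(length(scores_a) == length(scores_b))
  if (!is.null(ids)) stopifnot(length(ids) == length(scores_a))
  structure(list(scores_a = as.numeric(scores_a),
                 scores_b = as.numeric(scores_b),
                 differences = as.numeric(scores_b) - as.numeric(scores_a),
                 ids = ids, n = length(scores_a)),
            class = "paired_scores")
}

.arm_summary <- function(x) {
  n <- length(x)
  s <- stats::sd(x)
  c(mean = mean(x), median = stats::median(x), sd = s, se = s / sqrt(n),
    min = min(x), max = max(x))
}

#' Descriptive summary of paired scores
#'
#' Sample statistics (n-1 SD; SE = SD / sqrt(n)) for each arm and for the
#' paired differences.
#'
#' @param scores a [paired_scores()].
#' @return data.frame with rows mean/median/sd/se/min/max and columns
#'   `a`, `b`, `difference`.
#' @export
paired_summary <- function(scores) {
  stopifnot(inherits(scores, "paired_scores"))
  if (scores$n < 2) stop("need n >= 2 for SD/SE")
  out <- data.frame(a = .arm_summary(scores$scores_a),
                    b = .arm_summary(scores$scores_b),
                    difference = .arm_summary(scores$differences))
  out
}

#' One-tailed paired t-test from summary statistics
#'
#' `t = mean_d / (sd_d / sqrt(n))` with `df = n - 1`; the one-tailed p-value
#' is the upper tail of the t distribution. Usable directly on printed
#' summary tables (mean and SD of the paired differences).
#'
#' @param mean_d mean of the differences.
#' @param sd_d sample SD of the differences.
#' @param n number of pairs.
#' @return list with `t`, `df`, `p`.
#' @export
paired_t_from_summary <- function(mean_d, sd_d, n) {
  stopifnot(n >= 2)
  if (sd_d == 0) {
    return(list(t = if (mean_d == 0) NaN else Inf * sign(mean_d),
                df = n - 1, p = if (mean_d > 0) 0 else 1,
                degenerate = TRUE))
  }
  t <- mean_d / (sd_d / sqrt(n))
  list(t = t, df = n - 1, p = stats::pt(t, df = n - 1, lower.tail = FALSE))
}

#' One-tailed paired t-test (model B > model A)
#'
#' @param scores a [paired_scores()].
#' @param alternative only `"greater"` (the direction B exceeds A).
#' @return list with `t`, `df`, `p`; a zero-SD difference vector is flagged
#'   via `degenerate = TRUE` with an infinite (or NaN) statistic.
#' @export
paired_t_test <- function(scores, alternative = "greater") {
  stopifnot(inherits(scores, "paired_scores"), scores$n >= 2,
            identical(alternative, "greater"))
  d <- scores$differences
  paired_t_from_summary(mean(d), stats::sd(d), scores$n)
}

#' Cohen's d for paired data
#'
#' `d = mean(differences) / sd(differences)` with the sample (n-1) SD.
#'
#' @param scores a [paired_scores()].
#' @return effect size (sign follows the arm order: positive when B > A).
#' @export
cohens_d <- function(scores) {
  stopifnot(inherits(scores, "paired_scores"), scores$n >= 2)
  s <- stats::sd(scores$differences)
  if (s == 0) stop("zero SD of differences; effect size undefined")
  mean(scores$differences) / s
}

#' Cohen's d from summary statistics
#'
#' @param mean_d,sd_d mean and sample SD of the paired differences.
#' @return `mean_d / sd_d`.
#' @export
cohens_d_from_summary <- function(mean_d, sd_d) {
  if (sd_d == 0) stop("zero SD of differences; effect size undefined")
  mean_d / sd_d
}

#' Paired comparison report
#'
#' Builds the full comparison between two arms: descriptive summary table,
#' t-test, effect size, the fraction of points strictly above the `y = x`
#' line, the fraction of large differences (|difference| > `threshold`)
#' that are positive, and three diagnostic plots (difference histogram with
#' a mean line, arm boxplots, paired scatter with the identity line).
#'
#' @param scores a [paired_scores()].
#' @param names_ab labels for the two arms.
#' @param threshold absolute-difference cutoff for the "large difference"
#'   fraction (same units as the scores).
#' @param out_dir if non-NULL, write `summary.csv` and the three plots as
#'   PNGs into this directory.
#' @return list with `summary` (data.frame), `t_test`, `cohens_d` (NA when
#'   degenerate), `frac_above` (percent), `n_large`, `frac_large_positive`
#'   (percent, NA if no large differences), and `plots` (list of ggplot
#'   objects).
#' @export
comparison_report <- function(scores, names_ab = c("A", "B"), threshold = 0.1,
                              out_dir = NULL) {
  stopifnot(inherits(scores, "paired_scores"))
  sm <- paired_summary(scores)
  tt <- paired_t_test(scores)
  d_eff <- if (isTRUE(tt$degenerate)) NA_real_ else cohens_d(scores)
  dd <- scores$differences
  frac_above <- 100 * mean(dd > 0)
  large <- abs(dd) > threshold
  frac_large_pos <- if (any(large)) 100 * mean(dd[large] > 0) else NA_real_

  df <- data.frame(a = scores$scores_a, b = scores$scores_b, diff = dd)
  long <- data.frame(model = rep(names_ab, each = scores$n),
                     score = c(scores$scores_a, scores$scores_b))
  p_hist <- ggplot2::ggplot(df, ggplot2::aes(x = .data$diff)) +
    ggplot2::geom_histogram(bins = 15, fill = "steelblue", color = "white") +
    ggplot2::geom_vline(xintercept = mean(dd), color = "red",
                        linetype = "dashed") +
    ggplot2::geom_vline(xintercept = 0, color = "grey40") +
    ggplot2::labs(x = sprintf("difference (%s - %s)", names_ab[2], names_ab[1]),
                  y = "count", title = "Paired differences")
  p_box <- ggplot2::ggplot(long, ggplot2::aes(x = .data$model,
                                              y = .data$score)) +
    ggplot2::geom_boxplot(fill = "grey85") +
    ggplot2::labs(x = NULL, y = "score", title = "Score distributions")
  p_scatter <- ggplot2::ggplot(df, ggplot2::aes(x = .data$a, y = .data$b)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, color = "grey40") +
    ggplot2::geom_point(alpha = 0.7, color = "steelblue") +
    ggplot2::labs(x = names_ab[1], y = names_ab[2],
                  title = "Paired per-image scores")

  out <- list(summary = sm, t_test = tt, cohens_d = d_eff,
              frac_above = frac_above, n_large = sum(large),
              frac_large_positive = frac_large_pos,
              plots = list(differences = p_hist, boxplot = p_box,
                           scatter = p_scatter))
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(cbind(statistic = rownames(sm), sm),
                     file.path(out_dir, "summary.csv"), row.names = FALSE)
    for (nm in names(out$plots)) {
      grDevices::png(file.path(out_dir, paste0(nm, ".png")),
                     width = 600, height = 500)
      print(out$plots[[nm]])
      grDevices::dev.off()
    }
  }
  out
}
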