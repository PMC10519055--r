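# Cohort statistics: descriptives, Wilcoxon dialects, correlation, slope,
# sample size, cohort summary.

test_that("descriptive statistics use the sample sd and midpoint median", {
  d <- descriptive_stats(c(18, 24))
  expect_equal(d$mean, 21)
  expect_equal(d$median, 21)
  expect_equal(d$sd, sqrt(18), tolerance = 1e-12)  # 4.243 by hand
  expect_warning(d1 <- descriptive_stats(21), "single observation")
  expect_equal(d1$sd, 0)
  expect_error(descriptive_stats(numeric(0)), "n >= 1")
})

test_that("exact Wilcoxon enumerates the sign-assignment distribution", {
  # n = 6, all differences one-signed: p = 2 / 2^6
  x <- c(21, 20, 19, 23, 22, 18)
  y <- x + c(1.8, 1.7, 1.2, 2.5, 0.4, 3.0)
  w <- wilcoxon_signed_rank(x, y, method = "exact")
  expect_equal(w$statistic, 0)
  expect_equal(w$p_two_sided, 0.03125)

  # cross-check the enumeration against the stats package on tie-free data
  set.seed(11)
  for (i in 1:20) {
    n <- sample(4:12, 1)
    a <- rnorm(n); b <- rnorm(n)
    ours <- wilcoxon_signed_rank(a, b, method = "exact")
    ref <- wilcox.test(a, b, paired = TRUE, exact = TRUE)
    expect_equal(ours$p_two_sided, ref$p.value, tolerance = 1e-12)
    expect_equal(ours$statistic, unname(ref$statistic))
  }

  # exact p depends only on the ranks of |differences|: any strictly
  # monotone magnitude transform leaves it unchanged
  a <- c(5, 3, 8, 1, 9, 4); b <- c(4, 5, 2, 3, 1, 7)
  p1 <- wilcoxon_signed_rank(a, b)$p_two_sided
  d <- a - b
  d2 <- sign(d) * exp(abs(d))  # rank-preserving magnitude transform
  p2 <- wilcoxon_signed_rank(d2, rep(0, 6))$p_two_sided
  expect_equal(p1, p2)
})

test_that("normal-dialect Wilcoxon matches the tie-corrected z without
           continuity correction", {
  x <- c(21, 20, 19, 23, 22, 18)
  y <- x + c(1.8, 1.7, 1.2, 2.5, 0.4, 3.0)
  w <- wilcoxon_signed_rank(x, y, method = "normal")
  expect_equal(w$z, -10.5 / sqrt(22.75), tolerance = 1e-9)  # T+=0, n=6
  expect_equal(w$p_two_sided, 0.02771, tolerance = 1e-4)

  set.seed(12)
  for (i in 1:10) {
    n <- sample(6:15, 1)
    a <- sample(1:8, n, replace = TRUE)  # forces ties
    b <- sample(1:8, n, replace = TRUE)
    if (all(a == b)) next
    ours <- wilcoxon_signed_rank(a, b, method = "normal")
    ref <- suppressWarnings(
      wilcox.test(a, b, paired = TRUE, exact = FALSE, correct = FALSE))
    expect_equal(ours$p_two_sided, ref$p.value, tolerance = 1e-9)
  }
})

test_that("degenerate Wilcoxon inputs are surfaced", {
  expect_error(wilcoxon_signed_rank(1:5, 1:5), "all paired differences")
  expect_error(wilcoxon_signed_rank(1:25, 25:1, method = "exact"), "n <= 20")
})

test_that("Pearson correlation reproduces the reference-table value", {
  expect_equal(round(pearson_r(REF_ANGLES, REF_MEANS), 3), -0.991)
  expect_equal(pearson_r(1:5, seq(10, 2, by = -2)), -1)
  # shuffling pairs together leaves r unchanged
  set.seed(4)
  x <- rnorm(10); y <- rnorm(10)
  i <- sample(10)
  expect_equal(pearson_r(x[i], y[i]), pearson_r(x, y), tolerance = 1e-12)
  expect_error(pearson_r(1:5, rep(2, 5)), "zero variance")
  expect_error(pearson_r(1:2, 2:1), "n >= 3")
})

test_that("per-step slope is the mean successive difference", {
  expect_equal(per_step_slope(c(21.0, 19.3)), -1.7)
  expect_equal(per_step_slope(REF_MEANS), -1.7)
  expect_equal(per_step_slope(rep(3, 5)), 0)
  # telescoping identity: slope * (k - 1) = last - first
  expect_equal(per_step_slope(REF_MEANS) * 6, REF_MEANS[7] - REF_MEANS[1])
  expect_error(per_step_slope(21), "at least 2")
})

test_that("Fisher-z sample size reproduces worked values", {
  expect_identical(sample_size_correlation(0.9, 0.05, 0.8, tails = 1), 6L)
  expect_identical(sample_size_correlation(0.9, 0.05, 0.8, tails = 2), 7L)
  # r -> 1: formula floor of 3 approached from above
  expect_identical(sample_size_correlation(1 - 1e-12), 4L)
  expect_error(sample_size_correlation(1), "0 < r < 1")
  expect_error(sample_size_correlation(0), "0 < r < 1")
})

test_that("cohort summary reproduces per-angle structure and tests", {
  # noise-free cohort: identical knees, zero sd, strictly decreasing means
  p <- noise_free_params()
  series <- suppressWarnings(lapply(sample_cohort(p), run_schedule))
  cs <- summarize_cohort(series)
  expect_equal(cs$per_angle$sd, rep(0, 7))
  expect_true(all(diff(cs$per_angle$mean) < 0))
  expect_equal(cs$n, 6L)
  expect_lt(cs$pearson_r, -0.999)  # near-perfect linearity over 0-12 deg

  # stochastic cohort: pendulum monotonicity makes every subject decrease,
  # so every vs-baseline exact p is the uniform-sign 0.03125
  series2 <- lapply(sample_cohort(generator_params(seed = 77L)), run_schedule)
  cs2 <- summarize_cohort(series2)
  expect_equal(cs2$tests_vs_baseline$p_value, rep(0.03125, 6))
  expect_equal(nrow(cs2$tests_vs_previous), 6L)

  # single-subject cohort: descriptives still emitted, tests not applicable
  cs1 <- suppressWarnings(summarize_cohort(series2[1]))
  expect_true(all(is.na(cs1$tests_vs_baseline$p_value)))
  expect_equal(cs1$per_angle$mean, series2[[1]]$tttg_mm)

  expect_error(summarize_cohort(list(series2[[1]],
                                     run_schedule(sample_knee(p, 1),
                                                  angles = c(0, 2, 4)))),
               "same angle schedule")
})
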