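# Cohort statistics: per-angle descriptives, paired Wilcoxon signed-rank
# tests (exact enumeration and large-sample normal dialects), Pearson
# correlation of angle vs mean TT-TG, the per-2-degree slope, and the
# Fisher-z sample-size calculation for an expected correlation.

#' Descriptive statistics
#'
#' @param values numeric vector (n >= 1).
#' @return list with `min`, `max`, `median`, `mean`, `sd` (sample sd,
#'   n-1 denominator; defined as 0 with a warning for n = 1).
#' @export
descriptive_stats <- function(values) {
  stopifnot(is.numeric(values))
  if (length(values) == 0L) stop("descriptive statistics need n >= 1")
  s <- if (length(values) == 1L) {
    warning("sd of a single observation reported as 0")
    0
  } else stats::sd(values)
  list(min = min(values), max = max(values),
       median = stats::median(values), mean = mean(values), sd = s)
}

# exact null distribution of the positive-rank sum: subset-sum DP over the
# (possibly tied, hence averaged) ranks. Ranks are doubled so average ranks
# become integers; counts[k+1] = number of sign assignments with 2*T+ == k.
.signed_rank_counts <- function(ranks2) {
  total <- sum(ranks2)
  counts <- numeric(total + 1)
  counts[1] <- 1
  for (r in ranks2) {
    shifted <- c(numeric(r), counts[seq_len(total + 1 - r)])
    counts <- counts + shifted
  }
  counts
}

#' Paired Wilcoxon signed-rank test
#'
#' Two dialects. `"exact"` (default) enumerates the full permutation
#' distribution of the positive-rank sum over all `2^n` sign assignments of
#' the ranked absolute differences (average ranks under ties; n <= 20), and
#' reports the two-sided p as `2 * min(P(T+ <= t), P(T+ >= t))` capped at 1.
#' `"normal"` uses the large-sample z with tie-corrected variance and no
#' continuity correction — the dialect common in commercial statistics
#' packages (for n = 6 uniform-sign differences it yields p = 0.0277 where
#' the exact test yields 0.03125). Zero differences are dropped before
#' ranking in both dialects.
#'
#' @param x,y paired numeric vectors of equal length.
#' @param method `"exact"` or `"normal"`.
#' @return list with `statistic` (positive-rank sum T+), `n` (pairs after
#'   dropping zeros), `p_two_sided`, `method`, and `z` for the normal
#'   dialect.
#' @export
wilcoxon_signed_rank <- function(x, y, method = c("exact", "normal")) {
  method <- match.arg(method)
  stopifnot(is.numeric(x), is.numeric(y), length(x) == length(y),
            length(x) >= 1L)
  d <- x - y
  d <- d[d != 0]
  n <- length(d)
  if (n == 0L)
    stop("undefined test: all paired differences are zero")
  r <- rank(abs(d))
  t_plus <- sum(r[d > 0])
  if (method == "exact") {
    if (n > 20L)
      stop("exact enumeration supported for n <= 20; use method = 'normal'")
    counts <- .signed_rank_counts(as.integer(round(2 * r)))
    total <- 2^n
    k <- as.integer(round(2 * t_plus))
    p_le <- sum(counts[seq_len(k + 1)]) / total
    p_ge <- sum(counts[seq.int(k + 1, length(counts))]) / total
    p <- min(1, 2 * min(p_le, p_ge))
    list(statistic = t_plus, n = n, p_two_sided = p, method = "exact")
  } else {
    mu <- n * (n + 1) / 4
    ties <- table(r)
    sigma2 <- n * (n + 1) * (2 * n + 1) / 24 -
      sum(ties^3 - ties) / 48
    if (sigma2 <= 0) stop("undefined test: zero variance (all ranks tied out)")
    z <- (t_plus - mu) / sqrt(sigma2)
    list(statistic = t_plus, n = n, z = z,
         p_two_sided = 2 * stats::pnorm(-abs(z)), method = "normal")
  }
}

#' Pearson product-moment correlation
#'
#' Thin validated wrapper over [stats::cor()].
#'
#' @param xs,ys numeric vectors, n >= 3, each with nonzero variance.
#' @return correlation coefficient in `[-1, 1]`.
#' @export
pearson_r <- function(xs, ys) {
  stopifnot(is.numeric(xs), is.numeric(ys), length(xs) == length(ys))
  if (length(xs) < 3L) stop("correlation needs n >= 3")
  if (stats::sd(xs) == 0 || stats::sd(ys) == 0)
    stop("undefined correlation: zero variance")
  stats::cor(xs, ys)
}

#' Mean per-step slope of an equally spaced series
#'
#' Mean of successive differences; algebraically `(last - first) / (k - 1)`
#' (telescoping), sign preserved.
#'
#' @param series_means numeric vector of per-step means (>= 2 values,
#'   equally spaced in the predictor).
#' @param step step width in the predictor (degrees); informational.
#' @return slope in mm per step.
#' @export
per_step_slope <- function(series_means, step = 2) {
  if (length(series_means) < 2L) stop("slope needs at least 2 values")
  mean(diff(series_means))
}

#' Fisher-z sample size for detecting a correlation
#'
#' `n = ceiling(((z_alpha + z_beta) / C)^2 + 3)` with
#' `C = 0.5 * log((1 + r) / (1 - r))`; `z_alpha` is the upper
#' `alpha / tails` normal quantile. With r = 0.9, alpha = 0.05 and power
#' 0.80 the one-tailed formula gives n = 6 and the two-tailed gives n = 7 —
#' worth knowing when reconciling published calculations that quote
#' "two-tailed" alongside n = 6.
#'
#' @param r expected correlation, 0 < r < 1.
#' @param alpha type-I error rate.
#' @param power target power (1 - beta).
#' @param tails 1 or 2.
#' @return minimum number of cases (integer).
#' @export
sample_size_correlation <- function(r, alpha = 0.05, power = 0.80,
                                    tails = 1) {
  if (!is.finite(r) || r <= 0 || r >= 1)
    stop("expected correlation must satisfy 0 < r < 1")
  stopifnot(alpha > 0, alpha < 1, power > 0, power < 1, tails %in% c(1, 2))
  C <- 0.5 * log((1 + r) / (1 - r))
  z_a <- stats::qnorm(1 - alpha / tails)
  z_b <- stats::qnorm(power)
  as.integer(ceiling(((z_a + z_b) / C)^2 + 3))
}

#' Summarise a cohort of per-angle TT-TG series
#'
#' Reproduces the standard per-angle comparison table: descriptive
#' statistics at every angle, paired Wilcoxon tests of each angle against
#' baseline and against the previous angle, the mean per-step slope of the
#' per-angle means, and the Pearson correlation of angle vs per-angle mean.
#' No multiple-testing correction is applied; the number of comparisons is
#' reported alongside.
#'
#' @param series_list list of [tttg_series()] sharing one angle schedule.
#' @param wilcoxon `"exact"` or `"normal"` dialect for all tests.
#' @return an object of class `cohort_summary`.
#' @export
summarize_cohort <- function(series_list, wilcoxon = c("exact", "normal")) {
  wilcoxon <- match.arg(wilcoxon)
  stopifnot(length(series_list) >= 1L,
            all(vapply(series_list, inherits, TRUE, "tttg_series")))
  angles <- series_list[[1]]$angle_deg
  for (s in series_list)
    if (!isTRUE(all.equal(s$angle_deg, angles)))
      stop("all series must share the same angle schedule")
  n <- length(series_list)
  mat <- vapply(series_list, function(s) s$tttg_mm,
                numeric(length(angles)))  # angles x subjects
  mat <- matrix(mat, nrow = length(angles))
  per_angle <- do.call(rbind, lapply(seq_along(angles), function(i) {
    d <- descriptive_stats(mat[i, ])
    data.frame(angle_deg = angles[i], min = d$min, max = d$max,
               median = d$median, mean = d$mean, sd = d$sd)
  }))
  run_test <- function(i, j, label) {
    if (n < 2L)
      return(data.frame(comparison = label, statistic = NA_real_,
                        p_value = NA_real_, method = "not applicable"))
    w <- wilcoxon_signed_rank(mat[j, ], mat[i, ], method = wilcoxon)
    data.frame(comparison = label, statistic = w$statistic,
               p_value = w$p_two_sided, method = w$method)
  }
  vs_base <- do.call(rbind, lapply(seq_along(angles)[-1], function(i)
    run_test(1L, i, sprintf("%gdeg vs baseline", angles[i]))))
  vs_prev <- do.call(rbind, lapply(seq_along(angles)[-1], function(i)
    run_test(i - 1L, i, sprintf("%gdeg vs %gdeg", angles[i],
                                angles[i - 1L]))))
  structure(list(per_angle = per_angle,
                 tests_vs_baseline = vs_base,
                 tests_vs_previous = vs_prev,
                 slope_per_step = per_step_slope(per_angle$mean),
                 pearson_r = pearson_r(angles, per_angle$mean),
                 n = n, wilcoxon = wilcoxon,
                 n_comparisons = 2L * (length(angles) - 1L)),
            class = "cohort_summary")
}

#' @export
print.cohort_summary <- function(x, digits = 3, ...) {
  cat(sprintf("Cohort of %d knee(s), %d angles, Wilcoxon dialect: %s\n\n",
              x$n, nrow(x$per_angle), x$wilcoxon))
  pa <- x$per_angle
  pb <- c(NA, x$tests_vs_baseline$p_value)
  pp <- c(NA, x$tests_vs_previous$p_value)
  tab <- data.frame(
    angle = sprintf("%g deg", pa$angle_deg),
    `min-max` = sprintf("%.1f-%.1f", pa$min, pa$max),
    median = sprintf("%.1f", pa$median),
    `mean+/-sd` = sprintf("%.1f +/- %.1f", pa$mean, pa$sd),
    `p vs baseline` = ifelse(is.na(pb), "", sprintf("%.3f", pb)),
    `p vs previous` = ifelse(is.na(pp), "", sprintf("%.3f", pp)),
    check.names = FALSE)
  print(tab, row.names = FALSE)
  cat(sprintf("\nslope: %.2f mm per 2 deg step; Pearson r(angle, mean) = %.3f\n",
              x$slope_per_step, x$pearson_r))
  cat(sprintf("(%d uncorrected pairwise comparisons)\n", x$n_comparisons))
  invisible(x)
}

#' @export
summary.cohort_summary <- function(object, ...) {
  print(object, ...)
}
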