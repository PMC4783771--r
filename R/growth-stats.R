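# Growth-curve statistics from first principles: log-linear OLS fits,
# slope and endpoint contrasts, chi-square proportion tests, and the
# percentile bootstrap engine. Statistics are computed here; only tail
# probabilities are delegated to base R's distribution functions.

new_test_result <- function(statistic, df, p_value, method) {
  structure(list(statistic = statistic, df = df,
                 p_value = min(max(p_value, 0), 1), method = method),
            class = "mito_test")
}

#' @export
print.mito_test <- function(x, ...) {
  cat(sprintf("<test> %s: statistic = %.4f, df = %s, p = %.4g\n",
              x$method, x$statistic, format(x$df), x$p_value))
  invisible(x)
}

#' Log-linear growth-curve fit
#'
#' Ordinary least squares of `ln(count)` on time over the points with
#' strictly positive counts (growth curves on a logarithmic scale fit to
#' linear functions). Zero counts are dropped, not pseudo-counted.
#'
#' @param times hours.
#' @param counts cells per well, same length.
#' @return An object of class `loglinear_fit`: `slope` (per hour),
#'   `intercept` (ln cells), `slope_se` (`NA` when only 2 points),
#'   `n_points`, `r2`.
#' @export
#' @examples
#' loglinear_fit(0:3, 100 * exp(0.5 * 0:3))  # slope 0.5, r2 1
loglinear_fit <- function(times, counts) {
  stopifnot(length(times) == length(counts))
  keep <- is.finite(counts) & counts > 0
  x <- as.numeric(times[keep]); y <- log(as.numeric(counts[keep]))
  n <- length(x)
  if (n < 2L)
    stop_mito("mitorate_fit_error",
              "need >= 2 strictly positive counts to fit (got %d)", n)
  xbar <- mean(x); ybar <- mean(y)
  sxx <- sum((x - xbar)^2)
  if (sxx == 0) stop_mito("mitorate_fit_error", "times are all identical")
  slope <- sum((x - xbar) * (y - ybar)) / sxx
  intercept <- ybar - slope * xbar
  res <- y - (intercept + slope * x)
  rss <- sum(res^2); tss <- sum((y - ybar)^2)
  r2 <- if (tss == 0 || rss < .Machine$double.eps^0.5 * max(tss, 1)) 1
        else max(0, min(1, 1 - rss / tss))
  se <- if (n > 2L) sqrt(rss / (n - 2L) / sxx) else NA_real_
  structure(list(slope = slope, intercept = intercept, slope_se = se,
                 n_points = n, r2 = r2),
            class = "loglinear_fit")
}

#' @export
print.loglinear_fit <- function(x, ...) {
  cat(sprintf("<loglinear_fit> slope = %.5f/h (se %s), intercept = %.3f, n = %d, R^2 = %.4f\n",
              x$slope, ifelse(is.na(x$slope_se), "NA", sprintf("%.5f", x$slope_se)),
              x$intercept, x$n_points, x$r2))
  invisible(x)
}

#' Contrast two growth-rate slopes
#'
#' Normal z test on the difference of two independent OLS slopes,
#' `z = (slopeA - slopeB) / sqrt(seA^2 + seB^2)`, two-sided. This is the
#' package's longitudinal trend test: a per-replicate slope contrast used
#' as a deliberate methodological replacement for generalized estimating
#' equations, not a reproduction of them.
#'
#' @param fitA,fitB `loglinear_fit` objects (or any list with `slope` and
#'   `slope_se`), both with available standard errors.
#' @return A `mito_test` (statistic = z, df = Inf).
#' @export
compare_slopes <- function(fitA, fitB) {
  seA <- fitA$slope_se; seB <- fitB$slope_se
  if (is.null(seA) || is.null(seB) || is.na(seA) || is.na(seB))
    stop_mito("mitorate_comparison_error",
              "slope standard error unavailable; use a replicate-level bootstrap instead")
  denom <- sqrt(seA^2 + seB^2)
  z <- if (denom == 0) {
    if (fitA$slope == fitB$slope) 0 else sign(fitA$slope - fitB$slope) * Inf
  } else (fitA$slope - fitB$slope) / denom
  new_test_result(z, Inf, 2 * stats::pnorm(-abs(z)), "slope contrast (normal z)")
}

#' Welch two-sample t test on endpoint counts
#'
#' Unequal-variance t statistic with Welch-Satterthwaite degrees of
#' freedom, two-sided; used to compare final-day counts between two
#' groups' replicates.
#'
#' @param repsA,repsB numeric vectors of per-replicate endpoint counts,
#'   each of length >= 2.
#' @return A `mito_test`.
#' @export
#' @examples
#' endpoint_welch_t(c(1, 2, 3), c(4, 5, 6))  # t = -3.674, df = 4
endpoint_welch_t <- function(repsA, repsB) {
  repsA <- as.numeric(repsA); repsB <- as.numeric(repsB)
  n1 <- length(repsA); n2 <- length(repsB)
  if (n1 < 2L || n2 < 2L)
    stop_mito("mitorate_test_error", "need >= 2 values per group")
  v1 <- stats::var(repsA) / n1; v2 <- stats::var(repsB) / n2
  se <- sqrt(v1 + v2)
  diff <- mean(repsA) - mean(repsB)
  if (se == 0) {
    tt <- if (diff == 0) 0 else sign(diff) * Inf
    df <- n1 + n2 - 2
  } else {
    tt <- diff / se
    df <- (v1 + v2)^2 / (v1^2 / (n1 - 1) + v2^2 / (n2 - 1))
  }
  new_test_result(tt, df, 2 * stats::pt(-abs(tt), df), "Welch two-sample t")
}

#' Pearson chi-square test on a 2x2 proportion table
#'
#' Compares two scored proportions k1/n1 vs k2/n2 via the Pearson
#' chi-square statistic on the table `[[k1, n1-k1], [k2, n2-k2]]`, df = 1.
#' No continuity correction by default: with >= 1000 cells scored per
#' sample the Yates correction is negligible (it is available via
#' `correct = TRUE`).
#'
#' @param k1,n1,k2,n2 positives and totals for the two groups.
#' @param correct apply the Yates continuity correction.
#' @return A `mito_test`. A zero column margin (e.g. no positives in
#'   either group) yields statistic 0, p 1, with a warning.
#' @export
#' @examples
#' chi2_2x2(10, 1000, 30, 1000)  # X^2 = 10.204, p = 0.0014
chi2_2x2 <- function(k1, n1, k2, n2, correct = FALSE) {
  for (v in list(k1 = k1, n1 = n1, k2 = k2, n2 = n2))
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v < 0)
      stop_mito("mitorate_test_error", "counts must be non-negative numbers")
  if (k1 > n1 || k2 > n2 || n1 < 1 || n2 < 1)
    stop_mito("mitorate_test_error", "need 0 <= k <= n and n >= 1 in both groups")
  obs <- rbind(c(k1, n1 - k1), c(k2, n2 - k2))
  colsum <- colSums(obs); rowsum <- rowSums(obs); N <- sum(obs)
  if (any(colsum == 0)) {
    warning("a column margin is zero; chi-square statistic set to 0",
            call. = FALSE)
    return(new_test_result(0, 1, 1, "Pearson chi-square (2x2)"))
  }
  expected <- outer(rowsum, colsum) / N
  dev <- abs(obs - expected)
  if (correct) dev <- pmax(dev - 0.5, 0)
  stat <- sum(dev^2 / expected)
  new_test_result(stat, 1, stats::pchisq(stat, df = 1, lower.tail = FALSE),
                  paste0("Pearson chi-square (2x2",
                         if (correct) ", Yates-corrected", ")"))
}

#' Percentile bootstrap confidence interval
#'
#' Generic engine: calls a user-supplied resampler `B` times under a fixed
#' seed and returns the `(alpha/2, 1 - alpha/2)` empirical quantiles of
#' the resampled statistics. Deterministic given `seed`; the caller's RNG
#' state is untouched.
#'
#' @param values_fn function of one argument (the iteration index)
#'   returning one numeric resampled statistic; it may use the RNG freely.
#' @param B number of bootstrap replicates, >= 1.
#' @param alpha two-sided miss level in (0, 1).
#' @param seed integer seed.
#' @return A list with `low`, `high`, and the vector of resampled
#'   statistics `stats`.
#' @export
#' @examples
#' x <- rnorm(50)
#' ci <- bootstrap_percentile_ci(
#'   function(i) mean(sample(x, replace = TRUE)), B = 1000, seed = 1)
bootstrap_percentile_ci <- function(values_fn, B, alpha = 0.05, seed) {
  if (!is.function(values_fn))
    stop_mito("mitorate_domain_error", "values_fn must be a function")
  if (B < 1) stop_mito("mitorate_domain_error", "B must be >= 1")
  if (alpha <= 0 || alpha >= 1)
    stop_mito("mitorate_domain_error", "alpha must be in (0, 1)")
  if (missing(seed)) stop_mito("mitorate_domain_error", "seed is mandatory")
  stats_vec <- with_seed(seed, {
    vapply(seq_len(B), function(i) {
      v <- tryCatch(values_fn(i), error = function(e)
        stop_mito("mitorate_bootstrap_error",
                  "resampler failed at iteration %d: %s", i, conditionMessage(e)))
      as.numeric(v)
    }, numeric(1))
  })
  q <- stats::quantile(stats_vec, c(alpha / 2, 1 - alpha / 2), names = FALSE,
                       type = 7)
  list(low = q[1], high = q[2], stats = stats_vec)
}
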