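# Deterministic birth-death kinetics: occupancy-index <-> rate conversion,
# exponential growth prediction, and reconciliation of predicted vs
# observed net growth.
#
# Model: dN/dt = (b - d) N, with the division rate b obtained from the
# mitotic index and the detectable death rate d from the apoptotic (TUNEL)
# index. Under the residence-time "flux" rule, a phase occupied for W hours
# by cells entering at rate r per hour has expected index r*W (exact for a
# stationary age profile when r*W << 1). An age-structured alternative for
# mitosis uses the exponential-age distribution of a growing population:
# MI = 2^(T_M/T_c) - 1 = exp(b*T_M) - 1, where T_c = ln2/b is the cell
# cycle time. Apoptotic cells are terminal, so death always uses the flux
# rule.

#' Expected occupancy index from a per-hour rate
#'
#' Forward model: the fraction of cells expected to be scored inside a
#' phase of duration `window` when cells enter it at `rate` per hour.
#'
#' @param rate per-hour entry rate, >= 0.
#' @param window phase duration in hours, > 0 (mitotic duration for the
#'   mitotic index; detection window for the apoptotic index).
#' @param convention `"flux"` (`index = rate * window`, capped at 1 with a
#'   warning) or `"age_structured"` (`index = exp(rate * window) - 1`,
#'   mitosis only).
#' @return Expected index fraction.
#' @seealso [rate_from_index()] for the exact inverse.
#' @export
#' @examples
#' index_from_rate(0.03, 1)                        # 0.03
#' index_from_rate(log(2) / 24, 24, "age_structured")  # 1
index_from_rate <- function(rate, window, convention = c("flux", "age_structured")) {
  convention <- match.arg(convention)
  if (!is.numeric(rate) || any(!is.finite(rate)) || any(rate < 0))
    stop_mito("mitorate_domain_error", "rate must be >= 0")
  if (!is.numeric(window) || any(window <= 0))
    stop_mito("mitorate_domain_error", "window must be > 0")
  if (convention == "flux") {
    idx <- rate * window
    if (any(idx >= 1)) {
      warning("flux index >= 1; capping at 1 (rate * window too large)",
              call. = FALSE)
      idx <- pmin(idx, 1)
    }
    idx
  } else {
    # 2^(window / T_c) - 1 with T_c = ln2 / rate, i.e. exp(rate*window) - 1
    expm1(rate * window)
  }
}

#' Per-hour rate from an observed occupancy index
#'
#' Exact inverse of [index_from_rate()] under each convention.
#'
#' @param index observed index fraction, >= 0.
#' @param window phase duration in hours, > 0.
#' @inheritParams index_from_rate
#' @return Rate per hour.
#' @export
#' @examples
#' rate_from_index(0.04, 0.5)                    # 0.08
#' rate_from_index(1, 24, "age_structured")      # log(2)/24
rate_from_index <- function(index, window, convention = c("flux", "age_structured")) {
  convention <- match.arg(convention)
  if (!is.numeric(index) || any(!is.finite(index)) || any(index < 0))
    stop_mito("mitorate_domain_error", "index must be >= 0")
  if (!is.numeric(window) || any(window <= 0))
    stop_mito("mitorate_domain_error", "window must be > 0")
  if (convention == "flux") {
    if (any(index >= 1))
      warning("index >= 1 under flux convention; rate computed anyway",
              call. = FALSE)
    index / window
  } else {
    log1p(index) / window
  }
}

#' Predicted kinetic rates from paired index measurements
#'
#' Converts a mitotic-index and an apoptotic-index measurement (or
#' replicate lists thereof) for one `(cell_line, condition)` group into
#' per-hour division and detectable-death rates. The division rate may use
#' either index convention; the death rate always uses the flux rule since
#' apoptotic cells are terminal.
#'
#' @param mi an `index_measurement` of kind `"mitotic"`, or a list of them
#'   (replicates; rates are averaged).
#' @param ai an `index_measurement` of kind `"apoptotic"`, or a list.
#' @param constants a [kinetic_constants()] giving `T_M_h` and `T_A_h`.
#' @param convention index convention for mitosis (see [index_from_rate()]).
#' @return An object of class `kinetic_rates`: `b`, `d_detected`,
#'   `k_pred = b - d_detected` (all per hour), plus labels, constants and
#'   convention.
#' @export
#' @examples
#' mi <- index_measurement("mitotic", 40, 1000, "DLD1", "standard")
#' ai <- index_measurement("apoptotic", 10, 1000, "DLD1", "standard")
#' predicted_rates(mi, ai, kinetic_constants(T_M_h = 1, T_A_h = 4))
predicted_rates <- function(mi, ai, constants = kinetic_constants(),
                            convention = c("flux", "age_structured")) {
  convention <- match.arg(convention)
  stopifnot(inherits(constants, "kinetic_constants"))
  mi <- if (inherits(mi, "index_measurement")) list(mi) else mi
  ai <- if (inherits(ai, "index_measurement")) list(ai) else ai
  if (!length(mi) || !length(ai))
    stop_mito("mitorate_pairing_error", "need at least one measurement of each kind")
  for (m in mi) if (m$kind != "mitotic")
    stop_mito("mitorate_pairing_error", "mi must contain mitotic measurements")
  for (m in ai) if (m$kind != "apoptotic")
    stop_mito("mitorate_pairing_error", "ai must contain apoptotic measurements")
  groups <- unique(vapply(c(mi, ai), function(m)
    group_key(m$cell_line, m$condition), ""))
  if (length(groups) != 1L)
    stop_mito("mitorate_pairing_error",
              "measurements span multiple groups: %s",
              paste(groups, collapse = "; "))
  b <- mean(vapply(mi, function(m)
    rate_from_index(m$index, constants$T_M_h, convention), 0))
  d <- mean(vapply(ai, function(m)
    rate_from_index(m$index, constants$T_A_h, "flux"), 0))
  structure(list(b = b, d_detected = d, k_pred = b - d,
                 convention = convention,
                 cell_line = mi[[1]]$cell_line, condition = mi[[1]]$condition,
                 T_M_h = constants$T_M_h, T_A_h = constants$T_A_h),
            class = "kinetic_rates")
}

#' @export
print.kinetic_rates <- function(x, ...) {
  cat(sprintf("<kinetic_rates> %s / %s (%s): b = %.5f/h, d_detected = %.5f/h, k_pred = %.5f/h\n",
              x$cell_line, x$condition, x$convention, x$b, x$d_detected,
              x$k_pred))
  invisible(x)
}

#' Deterministic exponential growth prediction
#'
#' `N(t) = N0 * exp(k t)`, the closed-form solution of `dN/dt = kN`.
#'
#' @param N0 initial cells per well, >= 0.
#' @param k net growth rate per hour.
#' @param times hours, ascending.
#' @return Predicted counts at `times`.
#' @export
#' @examples
#' predict_curve(150000, log(2) / 24, c(0, 24, 48))
predict_curve <- function(N0, k, times) {
  if (!is.numeric(N0) || length(N0) != 1L || !is.finite(N0) || N0 < 0)
    stop_mito("mitorate_domain_error", "N0 must be >= 0")
  times <- as.numeric(times)
  if (length(times) > 1L && any(diff(times) < 0))
    stop_mito("mitorate_domain_error", "times must be ascending")
  N0 * exp(k * times)
}

#' Population doubling time
#'
#' `ln 2 / k` hours. A negative value for a shrinking population is its
#' halving time with sign; `k = 0` yields `Inf`.
#'
#' @param k net growth rate per hour.
#' @return Doubling time in hours.
#' @export
doubling_time <- function(k) {
  if (!is.numeric(k) || any(!is.finite(k)))
    stop_mito("mitorate_domain_error", "k must be finite")
  ifelse(k == 0, Inf, log(2) / k)
}

# Per-replicate log-linear slopes; replicates with < 2 positive counts are
# excluded with a warning.
replicate_slopes <- function(curve) {
  stopifnot(inherits(curve, "growth_curve"))
  slopes <- c()
  for (r in names(curve$counts)) {
    y <- curve$counts[[r]]
    if (sum(y > 0) < 2L) {
      warning(sprintf("replicate '%s' has < 2 positive counts; excluded from slope fit", r),
              call. = FALSE)
      next
    }
    fit <- loglinear_fit(curve$times, y)
    slopes[r] <- fit$slope
  }
  if (!length(slopes))
    stop_mito("mitorate_reconciliation_error",
              "no usable replicate (need >= 2 positive counts in >= 1 replicate)")
  slopes
}

new_reconciliation_report <- function(cell_line, condition, k_obs, k_pred,
                                      ci_low, ci_high, B, seed, convention,
                                      T_M_h, T_A_h) {
  structure(list(cell_line = cell_line, condition = condition,
                 k_obs = k_obs, k_pred = k_pred,
                 d_excess = k_pred - k_obs,
                 ci_low = ci_low, ci_high = ci_high, B = as.integer(B),
                 seed = as.integer(seed),
                 hidden_death_flag = isTRUE(ci_low > 0),
                 convention = convention, T_M_h = T_M_h, T_A_h = T_A_h),
            class = "reconciliation_report")
}

#' @export
print.reconciliation_report <- function(x, ...) {
  cat(sprintf(paste0("<reconciliation_report> %s / %s\n",
                     "  k_obs  = %+.5f/h   k_pred = %+.5f/h\n",
                     "  d_excess = %+.5f/h  [%.5f, %.5f] (B = %d, seed = %d)\n",
                     "  hidden death detected: %s\n"),
              x$cell_line, x$condition, x$k_obs, x$k_pred, x$d_excess,
              x$ci_low, x$ci_high, x$B, x$seed,
              if (x$hidden_death_flag) "YES (CI excludes 0)" else "no"))
  invisible(x)
}

#' Reconcile observed growth with index-predicted kinetics
#'
#' The core comparison: the observed net growth rate `k_obs` is the mean
#' over replicates of per-replicate OLS slopes of `ln(count)` versus time
#' (positive counts only); the predicted rate `k_pred = b - d_detected`
#' comes from the mitotic and apoptotic indices. Their difference
#' `d_excess = k_pred - k_obs` is the death rate the indices fail to
#' account for — death occurring at rates higher than the apoptosis assay
#' detects. A percentile bootstrap CI resamples replicates with
#' replacement and, when index measurements are supplied, re-draws each
#' index count `k* ~ Binomial(n, k/n)`, recomputing the whole chain each
#' iteration.
#'
#' @param curve a [growth_curve()] with >= 2 positive counts in >= 1
#'   replicate.
#' @param mi,ai mitotic / apoptotic [index_measurement()]s (or lists of
#'   them), required unless `rates` is given.
#' @param constants [kinetic_constants()]; required with `mi`/`ai`.
#' @param rates optionally a precomputed `kinetic_rates` object; the
#'   bootstrap then resamples replicates only (no index re-draw).
#' @param convention mitotic index convention (see [index_from_rate()]).
#' @param B bootstrap replicates, >= 1.
#' @param seed integer RNG seed (mandatory: reports are reproducible).
#' @param alpha two-sided CI level (default 0.05 for a 95% CI).
#' @return A `reconciliation_report` with fields `k_obs`, `k_pred`,
#'   `d_excess`, `ci_low`, `ci_high`, `B`, `seed`, `hidden_death_flag`
#'   (true iff `ci_low > 0`), `convention`, `T_M_h`, `T_A_h`.
#' @export
reconcile_growth <- function(curve, mi = NULL, ai = NULL,
                             constants = kinetic_constants(), rates = NULL,
                             convention = c("flux", "age_structured"),
                             B = 2000, seed, alpha = 0.05) {
  convention <- match.arg(convention)
  if (B < 1) stop_mito("mitorate_domain_error", "B must be >= 1")
  if (missing(seed)) stop_mito("mitorate_domain_error", "seed is mandatory")
  slopes <- replicate_slopes(curve)
  k_obs <- mean(slopes)
  R <- length(slopes)

  if (is.null(rates)) {
    if (is.null(mi) || is.null(ai))
      stop_mito("mitorate_pairing_error",
                "supply either mi + ai + constants or a precomputed rates object")
    mi <- if (inherits(mi, "index_measurement")) list(mi) else mi
    ai <- if (inherits(ai, "index_measurement")) list(ai) else ai
    rates0 <- predicted_rates(mi, ai, constants, convention)
    resampler <- function(i) {
      b_star <- mean(vapply(mi, function(m)
        rate_from_index(stats::rbinom(1L, m$total, m$index) / m$total,
                        constants$T_M_h, convention), 0))
      d_star <- mean(vapply(ai, function(m)
        rate_from_index(stats::rbinom(1L, m$total, m$index) / m$total,
                        constants$T_A_h, "flux"), 0))
      k_obs_star <- mean(slopes[sample.int(R, R, replace = TRUE)])
      (b_star - d_star) - k_obs_star
    }
  } else {
    stopifnot(inherits(rates, "kinetic_rates"))
    rates0 <- rates
    resampler <- function(i) {
      rates0$k_pred - mean(slopes[sample.int(R, R, replace = TRUE)])
    }
  }

  ci <- bootstrap_percentile_ci(resampler, B = B, alpha = alpha, seed = seed)
  new_reconciliation_report(curve$cell_line, curve$condition,
                            k_obs = k_obs, k_pred = rates0$k_pred,
                            ci_low = ci$low, ci_high = ci$high, B = B,
                            seed = seed, convention = rates0$convention,
                            T_M_h = rates0$T_M_h, T_A_h = rates0$T_A_h)
}
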