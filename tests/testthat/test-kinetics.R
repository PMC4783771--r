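test_that("index <-> rate conversions match their closed forms", {
  expect_equal(index_from_rate(0.03, 1, "flux"), 0.03)
  expect_equal(index_from_rate(0, 5, "flux"), 0)
  expect_equal(index_from_rate(0, 5, "age_structured"), 0)
  # at T_M = T_c the age-structured index is 2^1 - 1 = 1
  expect_equal(index_from_rate(log(2) / 24, 24, "age_structured"), 1)
  expect_warning(capped <- index_from_rate(0.5, 4, "flux"), "capping")
  expect_equal(capped, 1)

  expect_equal(rate_from_index(0.04, 0.5, "flux"), 0.08)
  expect_equal(rate_from_index(1, 24, "age_structured"), log(2) / 24)
  expect_warning(rate_from_index(1.2, 1, "flux"), "computed anyway")
  expect_error(rate_from_index(-0.1, 1), class = "mitorate_domain_error")
  expect_error(index_from_rate(0.03, 0), class = "mitorate_domain_error")
})

test_that("rate_from_index inverts index_from_rate to 1e-12", {
  for (conv in c("flux", "age_structured"))
    for (b in c(0.001, 0.03, 0.1))
      for (w in c(0.5, 1, 3))
        expect_equal(rate_from_index(index_from_rate(b, w, conv), w, conv),
                     b, tolerance = 1e-12)
})

test_that("predicted_rates combines paired indices into per-hour rates", {
  mi <- index_measurement("mitotic", 40, 1000, "DLD1", "standard")
  ai <- index_measurement("apoptotic", 10, 1000, "DLD1", "standard")
  r <- predicted_rates(mi, ai, kinetic_constants(T_M_h = 1, T_A_h = 4))
  expect_equal(r$b, 0.04)
  expect_equal(r$d_detected, 0.0025)
  expect_equal(r$k_pred, 0.0375)

  z <- predicted_rates(index_measurement("mitotic", 0, 1000, "DLD1", "standard"),
                       index_measurement("apoptotic", 0, 1000, "DLD1", "standard"),
                       kinetic_constants())
  expect_equal(c(z$b, z$d_detected, z$k_pred), c(0, 0, 0))

  bal <- predicted_rates(index_measurement("mitotic", 20, 1000, "DLD1", "standard"),
                         index_measurement("apoptotic", 80, 1000, "DLD1", "standard"),
                         kinetic_constants(T_M_h = 1, T_A_h = 4))
  expect_equal(bal$k_pred, 0)

  other <- index_measurement("apoptotic", 10, 1000, "DLD1", "hypoxia")
  expect_error(predicted_rates(mi, other, kinetic_constants()),
               class = "mitorate_pairing_error")
  expect_error(predicted_rates(ai, ai, kinetic_constants()),
               class = "mitorate_pairing_error")
})

test_that("predict_curve is the exponential closed form with the semigroup property", {
  expect_equal(predict_curve(150000, 0, seq(0, 144, 24)), rep(150000, 7))
  expect_equal(predict_curve(150000, log(2) / 24, 24), 300000)
  expect_equal(predict_curve(0, 0.05, c(0, 10)), c(0, 0))

  set.seed(3)
  for (i in 1:20) {
    N0 <- runif(1, 1, 1e6); k <- runif(1, -0.05, 0.05)
    t1 <- runif(1, 0, 100); t2 <- runif(1, 0, 100)
    expect_equal(predict_curve(N0, k, t1 + t2),
                 predict_curve(predict_curve(N0, k, t1), k, t2))
  }
})

test_that("doubling_time handles growth, shrinkage, and stasis", {
  expect_equal(doubling_time(log(2)), 1)
  expect_equal(doubling_time(log(2) / 24), 24)
  expect_identical(doubling_time(0), Inf)
  expect_lt(doubling_time(-0.01), 0)  # halving time carries the sign
})

test_that("reconcile_growth is exact on noiseless self-consistent data", {
  mi <- index_measurement("mitotic", 30, 1000, "DLD1", "standard")
  ai <- index_measurement("apoptotic", 0, 1000, "DLD1", "standard")
  kc <- kinetic_constants(T_M_h = 1, T_A_h = 3)
  rates <- predicted_rates(mi, ai, kc)  # k_pred = 0.03 exactly
  curve <- noiseless_curve(0.03, reps = 3)
  rep1 <- reconcile_growth(curve, rates = rates, B = 500, seed = 1)
  expect_lt(abs(rep1$d_excess), 1e-10)
  expect_lte(rep1$ci_low, rep1$d_excess)
  expect_gte(rep1$ci_high, rep1$d_excess)
  expect_false(rep1$hidden_death_flag)
})

test_that("reconcile_growth measures a known rate deficit on noiseless data", {
  mi <- index_measurement("mitotic", 35, 1000, "DLD1", "standard")
  ai <- index_measurement("apoptotic", 0, 1000, "DLD1", "standard")
  rates <- predicted_rates(mi, ai, kinetic_constants())  # k_pred = 0.035
  curve <- noiseless_curve(0.02, reps = 2)
  rep1 <- reconcile_growth(curve, rates = rates, B = 200, seed = 2)
  expect_equal(rep1$d_excess, 0.015, tolerance = 1e-10)
  expect_equal(rep1$d_excess, rep1$k_pred - rep1$k_obs)  # exact identity
})

test_that("d_excess is monotone in the mitotic and apoptotic indices", {
  curve <- noiseless_curve(0.02, reps = 3)
  kc <- kinetic_constants(1, 3)
  d_excess_for <- function(k_mi, k_ai) {
    reconcile_growth(curve,
                     mi = index_measurement("mitotic", k_mi, 1000, "DLD1", "standard"),
                     ai = index_measurement("apoptotic", k_ai, 1000, "DLD1", "standard"),
                     constants = kc, B = 1, seed = 1)$d_excess
  }
  mi_grid <- c(10, 20, 40, 60)
  dx <- vapply(mi_grid, d_excess_for, 0, k_ai = 15)
  expect_true(all(diff(dx) > 0))  # strictly increasing in MI
  ai_grid <- c(0, 10, 30, 60)
  dx <- vapply(ai_grid, d_excess_for, 0, k_mi = 40)
  expect_true(all(diff(dx) < 0))  # strictly decreasing in AI
})

test_that("reconcile_growth bootstraps the full estimation chain deterministically", {
  curve <- noiseless_curve(0.025, reps = 3)
  mi <- index_measurement("mitotic", 40, 1000, "DLD1", "standard")
  ai <- index_measurement("apoptotic", 15, 1000, "DLD1", "standard")
  r1 <- reconcile_growth(curve, mi = mi, ai = ai, B = 400, seed = 77)
  r2 <- reconcile_growth(curve, mi = mi, ai = ai, B = 400, seed = 77)
  expect_identical(r1[c("ci_low", "ci_high", "d_excess")],
                   r2[c("ci_low", "ci_high", "d_excess")])
  # CI reflects index-sampling noise, so it has positive width here
  expect_gt(r1$ci_high, r1$ci_low)
})

test_that("degenerate replicates are excluded or rejected", {
  times <- c(0, 24, 48)
  curve <- growth_curve("DLD1", "standard", times,
                        list(r1 = c(100, 150, 225), r2 = c(0, 0, 0)))
  mi <- index_measurement("mitotic", 30, 1000, "DLD1", "standard")
  ai <- index_measurement("apoptotic", 5, 1000, "DLD1", "standard")
  expect_warning(rep1 <- reconcile_growth(curve, mi = mi, ai = ai, B = 50,
                                          seed = 1),
                 "excluded")
  expect_equal(rep1$k_obs, log(1.5) / 24, tolerance = 1e-10)

  dead <- growth_curve("DLD1", "standard", times, list(r1 = c(100, 0, 0)))
  expect_error(suppressWarnings(
    reconcile_growth(dead, mi = mi, ai = ai, B = 50, seed = 1)),
    class = "mitorate_reconciliation_error")
})
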