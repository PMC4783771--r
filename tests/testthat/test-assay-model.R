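test_that("domain type invariants are enforced", {
  expect_error(growth_curve("DLD1", "standard", c(24, 0), list(r1 = c(1, 2))),
               "ascending")
  expect_error(growth_curve("DLD1", "standard", c(0, 24), list(r1 = c(1, 2, 3))),
               "counts")
  expect_error(growth_curve("DLD1", "standard", c(0, 24), list(r1 = c(-1, 2))),
               "negative")
  expect_error(growth_curve("DLD1", "bogus", 0, list(r1 = 1)),
               "unknown condition")
  expect_silent(growth_curve("DLD1", "hypoxia", c(0, 24),
                             list(r1 = c(0, 0))))  # zero counts are valid data

  expect_error(index_measurement("mitotic", 11, 10, "DLD1", "standard"),
               "0 <= k <= n")
  expect_error(index_measurement("mitotic", -1, 10, "DLD1", "standard"),
               "0 <= k <= n")
  expect_warning(index_measurement("mitotic", 4, 500, "DLD1", "standard"),
                 "< 1000")
  m <- index_measurement("apoptotic", 41, 1000, "DLD1", "standard")
  expect_identical(m$index, 0.041)

  expect_error(colony_set(c(10, -2)), "> 0")
  expect_warning(invasion_record(c(5, 6, 7), "DLD1", "standard"),
                 "expected 6 fields")
  expect_error(invasion_record(c(1.5, 2, 3, 4, 5, 6)), "integers")
  expect_error(kinetic_constants(T_M_h = 0), "> 0")

  # condition enum is extendable through the hook
  expect_silent(growth_curve("DLD1", "heatshock", 0, list(r1 = 1),
                             growth_conditions("heatshock")))
})

test_that("load_dataset parses well-formed CSVs and validates groups", {
  g <- write_growth_csv(demo_growth_df())
  i <- write_growth_csv(demo_index_df())
  ds <- load_dataset(g, i)
  expect_length(ds$curves, 1)
  curve <- ds$curves[["DLD1|standard"]]
  expect_s3_class(curve, "growth_curve")
  expect_length(curve$counts, 1)
  expect_length(curve$times, 3)
  expect_length(ds$indices, 2)
  expect_equal(ds$indices[[1]]$index, 0.041)
  # groups absent from config get default constants
  expect_equal(ds$constants[["DLD1|standard"]]$T_M_h, 1.0)
})

test_that("load_dataset rejects malformed input with named errors", {
  bad <- demo_growth_df(); bad$count[2] <- -5
  expect_error(load_dataset(write_growth_csv(bad),
                            write_growth_csv(demo_index_df())),
               "row 2", class = "mitorate_validation_error")

  dup <- rbind(demo_growth_df(), demo_growth_df()[1, ])
  expect_error(load_dataset(write_growth_csv(dup),
                            write_growth_csv(demo_index_df())),
               class = "mitorate_duplicate_error")

  nocol <- demo_growth_df(); names(nocol)[5] <- "cells"
  expect_error(load_dataset(write_growth_csv(nocol),
                            write_growth_csv(demo_index_df())),
               "count", class = "mitorate_schema_error")

  expect_error(load_dataset(tempfile("absent"), write_growth_csv(demo_index_df())),
               "absent", class = "mitorate_io_error")
})

test_that("filter_colonies applies an inclusive threshold and is idempotent", {
  cs <- colony_set(c(10, 15, 20, 50))
  out <- filter_colonies(cs, 15)
  expect_equal(out$kept$sizes, c(15, 20, 50))
  expect_equal(out$n_kept, 3)

  expect_equal(filter_colonies(colony_set(numeric(0)), 15)$n_kept, 0)
  expect_equal(filter_colonies(colony_set(c(14.9, 15.0)), 15)$n_kept, 1)

  again <- filter_colonies(out$kept, 15)
  expect_identical(again$kept$sizes, out$kept$sizes)

  # order preserved on unsorted input
  shuffled <- colony_set(c(50, 10, 20, 15))
  expect_equal(filter_colonies(shuffled, 15)$kept$sizes, c(50, 20, 15))
})

test_that("summarize_fields computes mean/sem and is permutation-invariant", {
  expect_equal(summarize_fields(c(4, 4, 4)), list(mean = 4, sem = 0, n = 3))
  expect_equal(summarize_fields(c(2, 4)), list(mean = 3, sem = 1, n = 2))
  s1 <- summarize_fields(7)
  expect_equal(s1$mean, 7); expect_true(is.na(s1$sem)); expect_equal(s1$n, 1)
  expect_error(summarize_fields(numeric(0)), "no observations")

  set.seed(7)
  for (i in 1:20) {
    v <- rpois(sample(2:10, 1), 50)
    expect_equal(summarize_fields(v), summarize_fields(sample(v)))
  }
})

test_that("nuclei_count_from_density is the density x area product, linear in both", {
  expect_equal(nuclei_count_from_density(1000, 9.6), 9600)
  expect_equal(nuclei_count_from_density(0, 9.6), 0)
  expect_equal(nuclei_count_from_density(250.5, 9.6), 2404.8)
  expect_error(nuclei_count_from_density(-1), ">= 0")

  set.seed(11)
  for (i in 1:20) {
    d <- runif(1, 0, 5000); a <- runif(1, 0.5, 20); c1 <- runif(1, 0.1, 10)
    expect_equal(nuclei_count_from_density(c1 * d, a),
                 c1 * nuclei_count_from_density(d, a))
    expect_equal(nuclei_count_from_density(d, c1 * a),
                 c1 * nuclei_count_from_density(d, a))
  }
})

test_that("reports round-trip losslessly through JSON", {
  curve <- noiseless_curve(0.0312345678901, reps = 3)
  mi <- index_measurement("mitotic", 40, 1000, "DLD1", "standard")
  ai <- index_measurement("apoptotic", 10, 1000, "DLD1", "standard")
  rep1 <- reconcile_growth(curve, mi = mi, ai = ai,
                           constants = kinetic_constants(1, 4),
                           B = 50, seed = 9)
  path <- tempfile(fileext = ".json")
  write_report(list(rep1), path)
  back <- read_report(path)$reports[[1]]
  for (f in c("cell_line", "condition", "convention", "hidden_death_flag"))
    expect_identical(back[[f]], rep1[[f]])
  for (f in c("k_obs", "k_pred", "d_excess", "ci_low", "ci_high", "B",
              "seed", "T_M_h", "T_A_h"))
    expect_equal(back[[f]], rep1[[f]], tolerance = 0)  # bit-exact doubles

  # empty collection stays a valid, empty document
  p2 <- tempfile(fileext = ".json")
  write_report(list(), p2)
  expect_length(read_report(p2)$reports, 0)
})

test_that("growth CSVs round-trip through the loader", {
  cfg <- scenario_config(list(list(cell_line = "DLD1", condition = "fu5",
                                   b = 0.02, d_detected = 0.004,
                                   d_hidden = 0.002)), seed = 5)
  out <- generate_dataset(cfg, tempfile("rt"))
  ds <- load_dataset(out$growth_csv, out$index_csv)
  curve <- ds$curves[["DLD1|fu5"]]
  for (r in unique(out$growth$replicate)) {
    sub <- out$growth[out$growth$replicate == r, ]
    expect_equal(curve$counts[[r]], sub$count[order(sub$time_h)])
  }
})
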