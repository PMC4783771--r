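# Fixture builders: everything is generated in code at test time.

# Noiseless exponential growth curve N0 * exp(k t) at daily time points.
noiseless_curve <- function(k, N0 = 150000, days = 0:6, reps = 1,
                            cell_line = "DLD1", condition = "standard") {
  times <- days * 24
  counts <- stats::setNames(
    replicate(reps, N0 * exp(k * times), simplify = FALSE),
    paste0("r", seq_len(reps)))
  growth_curve(cell_line, condition, times, counts)
}

quiet_im <- function(...) suppressWarnings(index_measurement(...))

# Write a growth/index CSV pair for one or more groups.
write_growth_csv <- function(df, path = tempfile(fileext = ".csv")) {
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  path
}

demo_growth_df <- function() {
  data.frame(cell_line = "DLD1", condition = "standard", replicate = "r1",
             time_h = c(0, 24, 48), count = c(150000, 200000, 260000),
             stringsAsFactors = FALSE)
}

demo_index_df <- function() {
  data.frame(cell_line = "DLD1", condition = "standard", replicate = "r1",
             kind = c("mitotic", "apoptotic"), positives = c(41, 10),
             total = c(1000, 1000), stringsAsFactors = FALSE)
}

# JSON config with a one- or two-group scenario, for pipeline tests.
write_demo_config <- function(path = tempfile(fileext = ".json"), seed = 42,
                              B = 300, d_hidden = 0.010, two_lines = TRUE) {
  groups <- list(list(cell_line = "DLD1", condition = "standard",
                      b = 0.04, d_detected = 0.005, d_hidden = d_hidden,
                      N0 = 150000))
  if (two_lines)
    groups <- c(groups, list(list(cell_line = "DLD1p13",
                                  condition = "standard", b = 0.03,
                                  d_detected = 0.004, d_hidden = 0,
                                  N0 = 150000)))
  cfg <- list(global = list(seed = seed, bootstrap_B = B,
                            reference_line = "DLD1"),
              scenario = list(groups = groups))
  jsonlite::write_json(cfg, path, auto_unbox = TRUE, digits = NA)
  path
}
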