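# Tidy-CSV input, config parsing, and JSON report serialization.

#' Read a pipeline configuration file (JSON or YAML)
#'
#' The config carries per-group kinetic constants and global analysis
#' settings, and optionally a `scenario` block consumed by
#' [generate_dataset()] via [run_pipeline()]. Format is chosen by file
#' extension (`.json` vs `.yml`/`.yaml`).
#'
#' Schema:
#' \preformatted{
#' global:   {mi_convention, min_colony_size_um, bootstrap_B, seed,
#'            reference_line, extra_conditions}
#' groups:   [{cell_line, condition, T_M_h, T_A_h}, ...]
#' scenario: {groups: [{cell_line, condition, b, d_detected, d_hidden,
#'                      N0, T_M_h, T_A_h}, ...],
#'            sampling: {n_scored, n_chambers, chamber_fraction, days,
#'                       replicates, index_time_h}}
#' }
#'
#' @param path path to a `.json`, `.yml` or `.yaml` file.
#' @return A list with elements `global`, `constants` (named list of
#'   [kinetic_constants()] keyed `"cell_line|condition"`), `scenario` (raw
#'   list or `NULL`), and `allowed_conditions`.
#' @export
read_config <- function(path) {
  if (!file.exists(path))
    stop_mito("mitorate_io_error", "config file not found: %s", path)
  ext <- tolower(tools::file_ext(path))
  raw <- if (ext %in% c("yml", "yaml")) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop_mito("mitorate_io_error",
                "YAML config requires the 'yaml' package; use JSON instead")
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = FALSE)
  }
  global <- raw$global %||% list()
  defaults <- list(mi_convention = "flux", min_colony_size_um = 15,
                   bootstrap_B = 2000L, alpha = 0.05,
                   reference_line = NULL, extra_conditions = character())
  for (k in names(defaults)) global[[k]] <- global[[k]] %||% defaults[[k]]
  global$mi_convention <- match.arg(global$mi_convention,
                                    c("flux", "age_structured"))
  allowed <- growth_conditions(unlist(global$extra_conditions))
  constants <- list()
  for (g in raw$groups %||% list()) {
    if (is.null(g$cell_line) || is.null(g$condition))
      stop_mito("mitorate_schema_error",
                "config groups entries need cell_line and condition")
    check_condition(g$condition, allowed)
    constants[[group_key(g$cell_line, g$condition)]] <-
      kinetic_constants(g$T_M_h %||% 1.0, g$T_A_h %||% 3.0)
  }
  list(global = global, constants = constants,
       scenario = raw$scenario %||% NULL, allowed_conditions = allowed)
}

read_csv_checked <- function(path, required, label) {
  if (!file.exists(path))
    stop_mito("mitorate_io_error", "%s CSV not found: %s", label, path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(required, names(df))
  if (length(missing))
    stop_mito("mitorate_schema_error", "%s CSV %s is missing column(s): %s",
              label, path, paste(missing, collapse = ", "))
  df
}

#' Read a tidy growth-curve CSV
#'
#' Expects columns `cell_line, condition, replicate, time_h, count`; one
#' row per observation (cells per well).
#'
#' @param path CSV path.
#' @param allowed_conditions allowed condition labels.
#' @return A list of [growth_curve()] objects keyed `"cell_line|condition"`.
#' @export
read_growth_csv <- function(path, allowed_conditions = growth_conditions()) {
  df <- read_csv_checked(path, c("cell_line", "condition", "replicate",
                                 "time_h", "count"), "growth")
  bad <- which(!is.finite(df$count) | df$count < 0)
  if (length(bad))
    stop_mito("mitorate_validation_error",
              "growth CSV row %d has negative or non-finite count (%s)",
              bad[1], df$count[bad[1]])
  key4 <- paste(df$cell_line, df$condition, df$replicate, df$time_h, sep = "|")
  if (anyDuplicated(key4))
    stop_mito("mitorate_duplicate_error",
              "duplicate (cell_line, condition, replicate, time_h) row: %s",
              key4[duplicated(key4)][1])
  curves <- list()
  for (key in sort(unique(group_key(df$cell_line, df$condition)))) {
    sub <- df[group_key(df$cell_line, df$condition) == key, , drop = FALSE]
    times <- sort(unique(sub$time_h))
    counts <- list()
    for (r in sort(unique(sub$replicate))) {
      rs <- sub[sub$replicate == r, , drop = FALSE]
      rs <- rs[order(rs$time_h), , drop = FALSE]
      if (!identical(as.numeric(rs$time_h), as.numeric(times)))
        stop_mito("mitorate_validation_error",
                  "replicate '%s' of group %s does not cover the group's time grid",
                  r, key)
      counts[[as.character(r)]] <- rs$count
    }
    curves[[key]] <- growth_curve(sub$cell_line[1], sub$condition[1],
                                  times, counts, allowed_conditions)
  }
  curves
}

#' Read a tidy index-scoring CSV
#'
#' Expects columns
#' `cell_line, condition, replicate, kind, positives, total` with `kind`
#' one of `mitotic` / `apoptotic`.
#'
#' @inheritParams read_growth_csv
#' @return A list of [index_measurement()] objects.
#' @export
read_index_csv <- function(path, allowed_conditions = growth_conditions()) {
  df <- read_csv_checked(path, c("cell_line", "condition", "replicate",
                                 "kind", "positives", "total"), "index")
  lapply(seq_len(nrow(df)), function(i) {
    m <- try(index_measurement(df$kind[i], df$positives[i], df$total[i],
                               df$cell_line[i], df$condition[i],
                               df$replicate[i], allowed_conditions),
             silent = TRUE)
    if (inherits(m, "try-error"))
      stop_mito("mitorate_validation_error", "index CSV row %d: %s", i,
                attr(m, "condition")$message)
    m
  })
}

#' Read a soft-agar colony CSV
#'
#' Columns `cell_line, condition, field, size_um`; returns one
#' [colony_set()] per group with sizes pooled across fields.
#'
#' @inheritParams read_growth_csv
#' @return Named list of [colony_set()] objects keyed `"cell_line|condition"`.
#' @export
read_colony_csv <- function(path, allowed_conditions = growth_conditions()) {
  df <- read_csv_checked(path, c("cell_line", "condition", "field", "size_um"),
                         "colonies")
  out <- list()
  for (key in sort(unique(group_key(df$cell_line, df$condition)))) {
    sub <- df[group_key(df$cell_line, df$condition) == key, , drop = FALSE]
    check_condition(sub$condition[1], allowed_conditions)
    out[[key]] <- colony_set(sub$size_um, length(unique(sub$field)),
                             sub$cell_line[1], sub$condition[1])
  }
  out
}

#' Read a matrigel invasion CSV
#'
#' Columns `cell_line, condition, field, count`; returns one
#' [invasion_record()] per group.
#'
#' @inheritParams read_growth_csv
#' @return Named list of [invasion_record()] objects.
#' @export
read_invasion_csv <- function(path, allowed_conditions = growth_conditions()) {
  df <- read_csv_checked(path, c("cell_line", "condition", "field", "count"),
                         "invasion")
  out <- list()
  for (key in sort(unique(group_key(df$cell_line, df$condition)))) {
    sub <- df[group_key(df$cell_line, df$condition) == key, , drop = FALSE]
    check_condition(sub$condition[1], allowed_conditions)
    sub <- sub[order(sub$field), , drop = FALSE]
    out[[key]] <- invasion_record(sub$count, sub$cell_line[1], sub$condition[1])
  }
  out
}

#' Load and validate a full dataset
#'
#' Materializes growth curves, index measurements and per-group kinetic
#' constants from tidy CSVs plus a config file. Groups are keyed by
#' `(cell_line, condition)`; groups absent from the config fall back to
#' the default [kinetic_constants()].
#'
#' @param growth_csv_path,index_csv_path tidy CSV paths (see
#'   [read_growth_csv()], [read_index_csv()]).
#' @param config_path optional JSON/YAML config ([read_config()]).
#' @return A list with `curves`, `indices`, `constants`, and `config`.
#' @export
load_dataset <- function(growth_csv_path, index_csv_path, config_path = NULL) {
  config <- if (!is.null(config_path)) read_config(config_path)
            else list(global = read_config_defaults(), constants = list(),
                      scenario = NULL, allowed_conditions = growth_conditions())
  allowed <- config$allowed_conditions
  curves <- read_growth_csv(growth_csv_path, allowed)
  indices <- read_index_csv(index_csv_path, allowed)
  keys <- unique(c(names(curves),
                   vapply(indices, function(m) group_key(m$cell_line, m$condition), "")))
  constants <- stats::setNames(lapply(keys, function(k)
    config$constants[[k]] %||% kinetic_constants()), keys)
  list(curves = curves, indices = indices, constants = constants,
       config = config)
}

read_config_defaults <- function() {
  list(mi_convention = "flux", min_colony_size_um = 15, bootstrap_B = 2000L,
       alpha = 0.05, reference_line = NULL, extra_conditions = character())
}

#' Write a reconciliation report collection to JSON
#'
#' One record per `(cell_line, condition)`, full double precision, sorted
#' by group key so identical analyses yield byte-identical files. The
#' report round-trips losslessly through [read_report()].
#'
#' @param reports list of `reconciliation_report` objects
#'   (see [reconcile_growth()]).
#' @param path output path.
#' @param tests optional list of test-result records to embed under
#'   `"tests"`.
#' @param meta optional named list of run metadata (no timestamps here:
#'   they would break determinism; timestamps live in the run manifest).
#' @return `path`, invisibly.
#' @export
write_report <- function(reports, path, tests = NULL, meta = NULL) {
  recs <- lapply(reports, function(r) {
    stopifnot(inherits(r, "reconciliation_report"))
    list(cell_line = r$cell_line, condition = r$condition,
         k_obs_per_h = r$k_obs, k_pred_per_h = r$k_pred,
         d_excess_per_h = r$d_excess, ci_low = r$ci_low, ci_high = r$ci_high,
         B = r$B, seed = r$seed, hidden_death_flag = r$hidden_death_flag,
         convention = r$convention, T_M_h = r$T_M_h, T_A_h = r$T_A_h)
  })
  ord <- order(vapply(recs, function(r) group_key(r$cell_line, r$condition), ""))
  doc <- list(reports = recs[ord])
  if (!is.null(tests)) doc$tests <- tests
  if (!is.null(meta)) doc$meta <- meta
  con <- try(file(path, "w"), silent = TRUE)
  if (inherits(con, "try-error"))
    stop_mito("mitorate_io_error", "cannot write report to %s", path)
  on.exit(close(con))
  # digits = I(17) serializes doubles bit-exactly (digits = NA does not)
  writeLines(jsonlite::toJSON(doc, auto_unbox = TRUE, digits = I(17),
                              null = "null", pretty = TRUE), con)
  invisible(path)
}

#' Read a reconciliation report JSON back into objects
#'
#' @param path path written by [write_report()].
#' @return A list with `reports` (list of `reconciliation_report`),
#'   `tests`, and `meta`.
#' @export
read_report <- function(path) {
  if (!file.exists(path))
    stop_mito("mitorate_io_error", "report file not found: %s", path)
  doc <- jsonlite::read_json(path, simplifyVector = FALSE)
  reports <- lapply(doc$reports, function(r)
    new_reconciliation_report(
      cell_line = r$cell_line, condition = r$condition, k_obs = r$k_obs_per_h,
      k_pred = r$k_pred_per_h, ci_low = r$ci_low, ci_high = r$ci_high,
      B = r$B, seed = r$seed, convention = r$convention,
      T_M_h = r$T_M_h, T_A_h = r$T_A_h))
  list(reports = reports, tests = doc$tests %||% NULL, meta = doc$meta %||% NULL)
}
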