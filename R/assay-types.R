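# Domain types for assay quantification. Plain validated S3 records, in the
# style of survival::Surv / ape's phylo: cheap constructors that check
# invariants once, then downstream code trusts the class.

#' Recognised culture conditions
#'
#' The closed set of condition labels: standard medium, serum starvation,
#' 5-fluorouracil exposure, and hypoxia. Extendable through the config
#' `extra_conditions` hook (see [read_config()]) to avoid silent group
#' fragmentation from typos.
#'
#' @param extra character vector of additional allowed labels.
#' @return Character vector of allowed condition labels.
#' @export
growth_conditions <- function(extra = character()) {
  unique(c("standard", "serum_free", "fu5", "hypoxia", extra))
}

check_condition <- function(condition, allowed = growth_conditions()) {
  if (!(is.character(condition) && length(condition) == 1L &&
        condition %in% allowed))
    stop_mito("mitorate_validation_error",
              "unknown condition label '%s' (allowed: %s)",
              as.character(condition)[1], paste(allowed, collapse = ", "))
  condition
}

#' Growth curve for one cell line under one condition
#'
#' Timed cell counts per replicate well. Counts are stored as reals, not
#' integers: hemocytometer counts averaged over four chambers are generally
#' non-integer.
#'
#' @param cell_line character label, e.g. `"DLD1"`.
#' @param condition one of [growth_conditions()].
#' @param times numeric vector of hours since treatment start, strictly
#'   ascending.
#' @param counts named list mapping replicate id to a numeric vector of
#'   cells per well, one value per time point, all non-negative.
#' @param allowed_conditions allowed condition labels.
#' @return An object of class `growth_curve`.
#' @export
#' @examples
#' growth_curve("DLD1", "standard", c(0, 24, 48),
#'              list(r1 = c(150000, 190000, 250000)))
growth_curve <- function(cell_line, condition, times, counts,
                         allowed_conditions = growth_conditions()) {
  check_condition(condition, allowed_conditions)
  times <- as.numeric(times)
  if (length(times) < 1L || any(!is.finite(times)) || any(diff(times) <= 0))
    stop_mito("mitorate_validation_error", "times must be strictly ascending")
  if (!is.list(counts) || length(counts) < 1L)
    stop_mito("mitorate_validation_error", "need at least one replicate")
  if (is.null(names(counts)) || any(!nzchar(names(counts))))
    stop_mito("mitorate_validation_error", "replicates must be named")
  for (r in names(counts)) {
    v <- as.numeric(counts[[r]])
    if (length(v) != length(times))
      stop_mito("mitorate_validation_error",
                "replicate '%s' has %d counts for %d time points",
                r, length(v), length(times))
    if (any(!is.finite(v)) || any(v < 0))
      stop_mito("mitorate_validation_error",
                "replicate '%s' has negative or non-finite counts", r)
    counts[[r]] <- v
  }
  structure(list(cell_line = as.character(cell_line), condition = condition,
                 times = times, counts = counts),
            class = "growth_curve")
}

#' @export
print.growth_curve <- function(x, ...) {
  cat(sprintf("<growth_curve> %s / %s: %d time points (%g-%g h), %d replicate(s)\n",
              x$cell_line, x$condition, length(x$times), min(x$times),
              max(x$times), length(x$counts)))
  invisible(x)
}

#' Scored mitotic or apoptotic index measurement
#'
#' k positives out of n cells scored at a fixed instant. The mitotic index
#' is the fraction of cells in mitosis; the apoptotic index the fraction of
#' TUNEL-positive cells. Scoring fewer than 1,000 cells triggers a warning
#' (not an error), since the index's binomial noise then dominates
#' downstream rate estimates.
#'
#' @param kind `"mitotic"` or `"apoptotic"`.
#' @param positives integer count of positive cells (k).
#' @param total integer count of cells scored (n).
#' @param cell_line,condition group labels.
#' @param replicate optional replicate id.
#' @param allowed_conditions allowed condition labels.
#' @return An object of class `index_measurement` with an `index` field
#'   equal to `positives/total`.
#' @export
#' @examples
#' m <- index_measurement("mitotic", 41, 1000, "DLD1", "standard")
#' m$index  # 0.041
index_measurement <- function(kind, positives, total, cell_line, condition,
                              replicate = NA_character_,
                              allowed_conditions = growth_conditions()) {
  kind <- match.arg(kind, c("mitotic", "apoptotic"))
  check_condition(condition, allowed_conditions)
  positives <- as.integer(positives); total <- as.integer(total)
  if (is.na(total) || total < 1L)
    stop_mito("mitorate_validation_error", "total scored cells must be >= 1")
  if (is.na(positives) || positives < 0L || positives > total)
    stop_mito("mitorate_validation_error",
              "positives must satisfy 0 <= k <= n (got k=%s, n=%s)",
              positives, total)
  if (total < 1000L)
    warning(sprintf("only %d cells scored (< 1000); index estimate is noisy",
                    total), call. = FALSE)
  structure(list(kind = kind, positives = positives, total = total,
                 index = positives / total,
                 cell_line = as.character(cell_line), condition = condition,
                 replicate = as.character(replicate)),
            class = "index_measurement")
}

#' @export
print.index_measurement <- function(x, ...) {
  cat(sprintf("<index_measurement> %s %s/%s: %d/%d = %.4f\n", x$kind,
              x$cell_line, x$condition, x$positives, x$total, x$index))
  invisible(x)
}

#' Soft-agar colony size set
#'
#' Longest-axis colony sizes (micrometres) pooled over the imaged fields of
#' view for one cell line under one condition.
#'
#' @param sizes numeric vector of longest-axis lengths in micrometres, all
#'   positive.
#' @param n_fields integer number of fields of view imaged.
#' @param cell_line,condition group labels.
#' @return An object of class `colony_set`.
#' @export
colony_set <- function(sizes, n_fields = 10L, cell_line = "", condition = "standard") {
  sizes <- as.numeric(sizes)
  if (any(!is.finite(sizes)) || any(sizes <= 0))
    stop_mito("mitorate_validation_error", "colony sizes must be > 0")
  n_fields <- as.integer(n_fields)
  if (is.na(n_fields) || n_fields < 1L)
    stop_mito("mitorate_validation_error", "n_fields must be >= 1")
  structure(list(sizes = sizes, n_fields = n_fields,
                 cell_line = as.character(cell_line),
                 condition = as.character(condition)),
            class = "colony_set")
}

#' Matrigel invasion field counts
#'
#' Per-field invasive cell counts for one cell line under one condition.
#' The assay convention is 6 random fields of view; other lengths are
#' accepted with a warning.
#'
#' @param field_counts non-negative integer vector of per-field counts.
#' @param cell_line,condition group labels.
#' @return An object of class `invasion_record`.
#' @export
invasion_record <- function(field_counts, cell_line = "", condition = "standard") {
  field_counts <- as.numeric(field_counts)
  if (any(!is.finite(field_counts)) || any(field_counts < 0) ||
      any(field_counts != round(field_counts)))
    stop_mito("mitorate_validation_error",
              "field counts must be non-negative integers")
  if (length(field_counts) != 6L)
    warning(sprintf("expected 6 fields of view, got %d", length(field_counts)),
            call. = FALSE)
  structure(list(field_counts = as.integer(field_counts),
                 cell_line = as.character(cell_line),
                 condition = as.character(condition)),
            class = "invasion_record")
}

#' Kinetic phase-duration constants
#'
#' Mitotic duration `T_M_h` and apoptosis detection-window duration `T_A_h`
#' (both hours), the residence times that convert occupancy indices into
#' per-hour rates. Defaults: T_M = 1 h (typical human-cell mitosis is
#' 0.5-1 h) and T_A = 3 h (TUNEL-detectable window of a few hours); both
#' should be overridden per cell line x condition when measured values are
#' available.
#'
#' @param T_M_h mitotic duration, hours, > 0.
#' @param T_A_h apoptosis detection window, hours, > 0.
#' @return An object of class `kinetic_constants`.
#' @export
kinetic_constants <- function(T_M_h = 1.0, T_A_h = 3.0) {
  T_M_h <- as.numeric(T_M_h); T_A_h <- as.numeric(T_A_h)
  if (!is.finite(T_M_h) || T_M_h <= 0 || !is.finite(T_A_h) || T_A_h <= 0)
    stop_mito("mitorate_validation_error", "T_M_h and T_A_h must be > 0")
  structure(list(T_M_h = T_M_h, T_A_h = T_A_h), class = "kinetic_constants")
}

group_key <- function(cell_line, condition) paste(cell_line, condition, sep = "|")
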