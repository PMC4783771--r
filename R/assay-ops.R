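# Assay quantification rules: colony size filtering, field summaries, and
# nuclei-density conversion.

#' Filter soft-agar colonies at a minimum size
#'
#' Keeps colonies whose longest-axis size is at least `min_size`
#' micrometres, preserving order. The default 15 um is the mean size of
#' the dot-like single-cell structures formed by non-transformed control
#' cells, used as the lower size limit for what counts as a colony; the
#' threshold is inclusive so structures exactly at the measured baseline
#' size are kept.
#'
#' @param colonies a [colony_set()].
#' @param min_size minimum longest-axis size, micrometres, > 0.
#' @return A list with `kept` (a [colony_set()] restricted to sizes >=
#'   `min_size`) and `n_kept`. An empty input yields an empty `kept` with
#'   `n_kept = 0`.
#' @export
#' @examples
#' cs <- colony_set(c(10, 15, 20, 50))
#' filter_colonies(cs, 15)$n_kept  # 3
filter_colonies <- function(colonies, min_size = 15) {
  stopifnot(inherits(colonies, "colony_set"))
  if (!is.numeric(min_size) || length(min_size) != 1L || min_size <= 0)
    stop_mito("mitorate_validation_error", "min_size must be > 0")
  keep <- colonies$sizes >= min_size
  kept <- colonies
  kept$sizes <- colonies$sizes[keep]
  list(kept = kept, n_kept = sum(keep))
}

#' Mean and standard error over fields or replicates
#'
#' @param values numeric vector, length >= 1.
#' @return A list with `mean`, `sem` (sample-sd / sqrt(n); `NA` when
#'   n = 1), and `n`.
#' @export
#' @examples
#' summarize_fields(c(2, 4))  # mean 3, sem 1
summarize_fields <- function(values) {
  values <- as.numeric(values)
  if (length(values) == 0L)
    stop_mito("mitorate_validation_error", "no observations")
  if (any(!is.finite(values)))
    stop_mito("mitorate_validation_error", "non-finite observations")
  n <- length(values)
  list(mean = mean(values),
       sem = if (n > 1L) stats::sd(values) / sqrt(n) else NA_real_,
       n = n)
}

#' Convert a nuclei surface density to cells per well
#'
#' Imaging-based counting yields nuclei per square centimetre; the total
#' per-well cell number extrapolates by the culture well's growth area
#' (9.6 cm^2 for a standard 6-well plate).
#'
#' @param density nuclei per cm^2, >= 0.
#' @param well_area well growth area in cm^2, > 0.
#' @return Cells per well (`density * well_area`).
#' @export
#' @examples
#' nuclei_count_from_density(1000)  # 9600
nuclei_count_from_density <- function(density, well_area = 9.6) {
  if (!is.numeric(density) || any(!is.finite(density)) || any(density < 0))
    stop_mito("mitorate_validation_error", "density must be >= 0")
  if (!is.numeric(well_area) || length(well_area) != 1L || well_area <= 0)
    stop_mito("mitorate_validation_error", "well_area must be > 0")
  density * well_area
}
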