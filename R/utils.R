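#' @keywords internal
"_PACKAGE"

`%||%` <- function(x, y) if (is.null(x)) y else x

#' Evaluate an expression with a temporary RNG seed
#'
#' Saves the caller's RNG state, seeds the generator, evaluates `code`,
#' and restores the state on exit, so seeded helpers never perturb the
#' global random stream.
#'
#' @param seed integer seed, or `NULL` to use the current stream untouched.
#' @param code expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  if (is.null(seed)) return(code)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  code
}

#' Derive a deterministic per-stream sub-seed
#'
#' Maps a global seed and a stream label to a reproducible sub-seed via a
#' polynomial rolling hash modulo the Mersenne prime 2^31 - 1. Streams are
#' independent of each other's existence: adding a replicate or a group
#' never perturbs previously drawn streams.
#'
#' @param seed global integer seed.
#' @param label character scalar naming the stream
#'   (e.g. `"DLD1|standard|r1|growth"`).
#' @return An integer in `[1, 2^31 - 2]`.
#' @export
#' @examples
#' stream_seed(1L, "DLD1|standard|r1|growth")
stream_seed <- function(seed, label) {
  stopifnot(length(seed) == 1L, is.finite(seed), is.character(label),
            length(label) == 1L)
  m <- 2147483647  # 2^31 - 1, keeps every intermediate < 2^53 in doubles
  h <- as.numeric(seed) %% m
  for (code in utf8ToInt(label)) h <- (h * 31 + code) %% m
  as.integer(h %% (m - 1) + 1)
}

#' Stop with a classed condition
#' @noRd
stop_mito <- function(class, msg, ...) {
  stop(structure(class = c(class, "mitorate_error", "error", "condition"),
                 list(message = sprintf(msg, ...), call = sys.call(-1))))
}
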