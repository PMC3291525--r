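#' Construct a beat series
#'
#' A beat series is the fundamental tabular record of a pacing run: one row
#' per beat, holding the pacing cycle length `cl_ms` (t), the action
#' potential duration `apd_ms` (a) and the diastolic interval `di_ms` (d).
#' The conservation identity t = a + d holds on every row: a cycle consists
#' of the action potential followed by its diastolic interval.
#'
#' @param cl_ms numeric vector of per-beat cycle lengths (ms).
#' @param apd_ms numeric vector of action potential durations (ms).
#' @param di_ms diastolic intervals (ms); computed as `cl_ms - apd_ms` when
#'   omitted.
#' @param meta named list of run metadata (model id, BCL, SD, seed, ...).
#'
#' @return A tibble of class `beat_series` with columns `beat`, `cl_ms`,
#'   `apd_ms`, `di_ms` and a `meta` attribute.
#' @export
beat_series <- function(cl_ms, apd_ms, di_ms = NULL, meta = list()) {
  if (length(cl_ms) != length(apd_ms)) {
    abort("`cl_ms` and `apd_ms` must have equal length.",
          class = "stochpace_input_error")
  }
  if (is.null(di_ms)) di_ms <- cl_ms - apd_ms
  if (length(di_ms) != length(cl_ms)) {
    abort("`di_ms` must match the length of `cl_ms`.",
          class = "stochpace_input_error")
  }
  bad <- which(abs(cl_ms - apd_ms - di_ms) > 1e-6)
  if (length(bad)) {
    abort(sprintf("cl != apd + di beyond 1e-6 ms at beat %d.", bad[1]),
          class = "stochpace_validation_error")
  }
  if (any(!is.finite(cl_ms)) || any(!is.finite(apd_ms))) {
    abort("Beat series values must be finite.",
          class = "stochpace_validation_error")
  }
  if (any(cl_ms <= 0) || any(apd_ms <= 0)) {
    abort("Cycle lengths and APDs must be positive.",
          class = "stochpace_validation_error")
  }
  out <- tibble(
    beat = seq_along(cl_ms),
    cl_ms = as.numeric(cl_ms),
    apd_ms = as.numeric(apd_ms),
    di_ms = as.numeric(di_ms)
  )
  new_beat_series(out, meta)
}

new_beat_series <- function(df, meta = list()) {
  out <- as_tibble(df)
  class(out) <- c("beat_series", class(out))
  attr(out, "meta") <- meta
  out
}

#' Metadata of a beat series
#' @param series a [beat_series()].
#' @return The named metadata list.
#' @export
series_meta <- function(series) attr(series, "meta") %||% list()

# dplyr verbs strip custom attrs; internal accessor tolerant of plain frames
as_beat_frame <- function(series) {
  if (!all(c("cl_ms", "apd_ms") %in% names(series))) {
    abort("Expected columns `cl_ms` and `apd_ms`.",
          class = "stochpace_input_error")
  }
  series
}

#' @export
print.beat_series <- function(x, ...) {
  meta <- series_meta(x)
  if (length(meta)) {
    hdr <- paste(names(meta), vapply(meta, function(v)
      paste(format(v), collapse = ","), ""), sep = "=", collapse = " ")
    cat("# beat series:", hdr, "\n")
  }
  NextMethod()
}
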