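#' Read a beat series from CSV
#'
#' Expects the header `beat,cl_ms,apd_ms,di_ms` (`di_ms` optional;
#' reconstructed as `cl_ms - apd_ms` when absent). The conservation
#' identity `cl = apd + di` is verified within 1e-6 ms.
#'
#' @param path file path.
#' @return A [beat_series()].
#' @export
read_beats_csv <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE)
  need <- c("beat", "cl_ms", "apd_ms")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols)) {
    abort(sprintf("Missing column(s): %s.",
                  paste(missing_cols, collapse = ", ")),
          class = "stochpace_validation_error")
  }
  di <- if ("di_ms" %in% names(df)) df$di_ms else NULL
  if (!is.null(di) && any(di <= 0)) {
    abort("Non-positive DI in input.", class = "stochpace_validation_error")
  }
  if (any(df$apd_ms >= df$cl_ms)) {
    abort("APD >= CL in input (non-positive DI).",
          class = "stochpace_validation_error")
  }
  beat_series(df$cl_ms, df$apd_ms, di, meta = list(source = path))
}

#' Write a beat series to CSV
#' @param series a [beat_series()].
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_beats_csv <- function(series, path) {
  df <- as_beat_frame(series)
  readr::write_csv(df[, c("beat", "cl_ms", "apd_ms", "di_ms")], path)
  invisible(path)
}

# ---- JSON result serialization -------------------------------------------

complex_to_json <- function(z) {
  purrr::map(as.complex(z), function(v) list(re = Re(v), im = Im(v)))
}

json_sanitize <- function(x) {
  if (is.list(x)) return(purrr::map(x, json_sanitize))
  if (is.numeric(x) && any(is.nan(x))) {
    warn("NaN in results serialized as null.")
    x[is.nan(x)] <- NA_real_
  }
  x
}

#' Serializable representation of a result object
#' @param obj a result object.
#' @return A plain list ready for JSON encoding.
#' @export
as_result_list <- function(obj) UseMethod("as_result_list")

#' @export
as_result_list.eigen_summary <- function(obj) {
  list(schema_version = .schema_version, type = "eigen_summary",
       eigvals = complex_to_json(obj$eigvals),
       lambda_alt = list(re = Re(obj$lambda_alt), im = Im(obj$lambda_alt)),
       lambda_mem = list(re = Re(obj$lambda_mem), im = Im(obj$lambda_mem)),
       tau_mem_beats = obj$tau_mem_beats,
       tau_mem_ms = obj$tau_mem_ms,
       bcl_ms = obj$bcl)
}

#' @export
as_result_list.arma_fit <- function(obj) {
  list(schema_version = .schema_version, type = "arma_fit",
       order = obj$order, alpha = obj$alpha, beta = obj$beta,
       resid_var_fraction = obj$resid_var_fraction,
       n_cycles = obj$n_cycles,
       poles = complex_to_json(obj$poles),
       zeros = complex_to_json(obj$zeros),
       lambda_alt_hat = list(re = Re(obj$lambda_alt_hat),
                             im = Im(obj$lambda_alt_hat)),
       s_s1s2_hat = obj$s_s1s2_hat, s_dyn_hat = obj$s_dyn_hat,
       detrend = obj$detrend,
       condition_number = obj$condition_number)
}

#' @export
as_result_list.track_result <- function(obj) {
  list(schema_version = .schema_version, type = "track_result",
       window = attr(obj, "window"), step = attr(obj, "step"),
       windows = purrr::pmap(
         obj[, c("window_center_beat", "mean_bcl_ms", "lambda_alt",
                 "s_s1s2")],
         function(window_center_beat, mean_bcl_ms, lambda_alt, s_s1s2)
           list(window_center_beat = window_center_beat,
                mean_bcl_ms = mean_bcl_ms, lambda_alt = lambda_alt,
                s_s1s2 = s_s1s2)))
}

#' @export
as_result_list.onset_prediction <- function(obj) {
  c(list(schema_version = .schema_version, type = "onset_prediction"),
    obj[c("slope", "intercept", "cutoff", "predictor", "onset",
          "n_points")])
}

#' @export
as_result_list.transfer_fn <- function(obj) {
  list(schema_version = .schema_version, type = "transfer_fn",
       source = obj$source, num = obj$num, den = obj$den,
       poles = complex_to_json(obj$poles),
       zeros = complex_to_json(obj$zeros))
}

#' Write a result object to JSON
#'
#' Stable schemas with full-precision floats and a `schema_version` field;
#' `NaN` values are serialized as `null` with a warning.
#'
#' @param obj an `eigen_summary`, `arma_fit`, `track_result`,
#'   `onset_prediction` or `transfer_fn`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_results <- function(obj, path) {
  lst <- json_sanitize(as_result_list(obj))
  jsonlite::write_json(lst, path, auto_unbox = TRUE, digits = NA,
                       na = "null", null = "null")
  invisible(path)
}

#' Read a run configuration from YAML or JSON
#'
#' Validates the top-level structure (`model`, `protocol`, `analysis`,
#' `seed`; unknown keys rejected).
#'
#' @param path configuration file (`.yaml`/`.yml`/`.json`).
#' @return A list of class `run_config`.
#' @export
read_run_config <- function(path) {
  cfg <- if (grepl("\\.json$", path)) jsonlite::read_json(path,
                                                          simplifyVector = TRUE)
         else yaml::read_yaml(path)
  allowed <- c("model", "protocol", "analysis", "seed", "output")
  unknown <- setdiff(names(cfg), allowed)
  if (length(unknown)) {
    abort(sprintf("Unknown config key(s): %s.",
                  paste(unknown, collapse = ", ")),
          class = "stochpace_validation_error")
  }
  if (is.null(cfg$model$kind)) {
    abort("Config must provide model: kind.",
          class = "stochpace_validation_error")
  }
  structure(cfg, class = "run_config")
}

#' Write a run configuration to YAML
#' @param config a `run_config`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}
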