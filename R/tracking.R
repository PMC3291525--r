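#' Ramp pacing protocol (progressive BCL decrease with stochastic variation)
#'
#' After settling at `bcl_start`, the model is paced at
#' `cl_i = bcl_start + slope_ms_per_beat * i + N(0, sd)`. A capture failure
#' (expected deep in the alternans regime) truncates the series, recorded in
#' the `truncated_at` attribute rather than raising an error.
#'
#' @param model a [cell_model()].
#' @param bcl_start starting basic cycle length (ms).
#' @param slope_ms_per_beat ramp slope (ms per beat; negative for a
#'   downsweep).
#' @param sd standard deviation of the superimposed Gaussian cycle-length
#'   variations (ms).
#' @param n number of ramp beats.
#' @param seed optional integer seed.
#' @param settle_first settle at `bcl_start` before the ramp.
#' @return A [beat_series()]; attribute `truncated_at` gives the failing
#'   beat index (`NA` if the full ramp completed).
#' @export
ramp_protocol <- function(model, bcl_start, slope_ms_per_beat = -0.1,
                          sd = 1, n = 500, seed = NULL,
                          settle_first = TRUE) {
  if (!is.null(seed)) set.seed(seed)
  state <- if (settle_first) settle(model, bcl_start)$state
           else init_state(model)
  cls <- bcl_start + slope_ms_per_beat * seq_len(n)
  if (sd > 0) cls <- cls + rnorm(n, 0, sd)
  res <- model_run(model, state, cls)
  nd <- res$n_done
  if (nd == 0) {
    capture_error("Capture failure on the first ramp beat.", beat = 1L)
  }
  series <- beat_series(cls[seq_len(nd)], res$apd[seq_len(nd)],
                        meta = list(model_id = model$kind,
                                    protocol = "ramp", bcl = bcl_start,
                                    slope_ms_per_beat = slope_ms_per_beat,
                                    sd = sd, seed = seed))
  attr(series, "truncated_at") <- res$failed_beat
  series
}

#' Simulated drug application: slow drift of a model parameter
#'
#' Paces at a fixed mean cycle length while one model parameter is scaled to
#' `nominal * (1 - rate_fraction_per_s * elapsed_seconds)` before every
#' beat; elapsed time accumulates the actual cycle lengths. Mimics the slow
#' wash-in of a channel blocker.
#'
#' @inheritParams ramp_protocol
#' @param param_name name of the (positive) parameter to drift.
#' @param rate_fraction_per_s fractional reduction per second (e.g. 0.002
#'   for 0.2 percent per second).
#' @param bcl mean pacing cycle length (ms).
#' @return A [beat_series()] with an extra column `param_scale`; attribute
#'   `truncated_at` as for [ramp_protocol()].
#' @export
parameter_drift_protocol <- function(model, param_name, rate_fraction_per_s,
                                     bcl, sd = 1, n = 500, seed = NULL,
                                     settle_first = TRUE) {
  if (!param_name %in% names(model$params)) {
    abort(sprintf("Unknown parameter `%s` for %s model.", param_name,
                  model$kind),
          class = "stochpace_model_error")
  }
  nominal <- model$params[[param_name]]
  if (nominal <= 0) {
    abort("Drifted parameter must be positive.",
          class = "stochpace_model_error")
  }
  if (!is.null(seed)) set.seed(seed)
  state <- if (settle_first) settle(model, bcl)$state else init_state(model)
  cls <- rep(bcl, n)
  if (sd > 0) cls <- cls + rnorm(n, 0, sd)
  apd <- di <- scale_v <- rep(NA_real_, n)
  elapsed_s <- 0
  truncated <- NA_integer_
  m <- model
  for (i in seq_len(n)) {
    sc <- 1 - rate_fraction_per_s * elapsed_s
    if (sc <= 0) { truncated <- i; break }
    m$params[[param_name]] <- nominal * sc
    res <- tryCatch(model_beat(m, state, cls[i]),
                    stochpace_capture_error = function(e) e)
    if (inherits(res, "error")) { truncated <- i; break }
    state <- res$state
    apd[i] <- res$apd; di[i] <- res$di; scale_v[i] <- sc
    elapsed_s <- elapsed_s + cls[i] / 1000
  }
  nd <- if (is.na(truncated)) n else truncated - 1L
  if (nd == 0) {
    capture_error("Protocol failed on the first beat.", beat = 1L)
  }
  series <- beat_series(cls[seq_len(nd)], apd[seq_len(nd)],
                        meta = list(model_id = model$kind,
                                    protocol = "parameter_drift",
                                    param = param_name,
                                    rate_fraction_per_s = rate_fraction_per_s,
                                    bcl = bcl, sd = sd, seed = seed))
  series$param_scale <- scale_v[seq_len(nd)]
  attr(series, "truncated_at") <- truncated
  series
}

#' Windowed alternans-eigenvalue tracking
#'
#' Slides a window over a beat series, fits an ARMA model in each window and
#' records the real part of the pole closest to -1 together with the S1S2
#' slope estimate and the window mean BCL. Windows whose fit fails are
#' recorded as missing.
#'
#' @param series a [beat_series()].
#' @param window window length (beats); must be at least `10 * order`.
#' @param step window step (beats).
#' @param order ARMA order per window.
#' @param detrend deviation convention per window, see [fit_arma()].
#' @return Tibble of class `track_result` with columns
#'   `window_center_beat`, `mean_bcl_ms`, `lambda_alt`, `lambda_alt_im`,
#'   `s_s1s2`; attribute `fits` holds the per-window [arma_fit][fit_arma]
#'   objects.
#' @export
windowed_lambda <- function(series, window = 30, step = 15, order = 2,
                            detrend = c("mean", "linear")) {
  detrend <- match.arg(detrend)
  df <- as_beat_frame(series)
  n <- nrow(df)
  if (window > n) {
    abort("`window` exceeds the series length.",
          class = "stochpace_input_error")
  }
  if (window < 10 * order || step < 1) {
    abort("Need window >= 10 * order and step >= 1.",
          class = "stochpace_input_error")
  }
  starts <- seq(1, n - window + 1, by = step)
  fits <- vector("list", length(starts))
  rows <- purrr::map(seq_along(starts), function(j) {
    sel <- starts[j]:(starts[j] + window - 1)
    fit <- tryCatch(fit_arma(df[sel, ], order = order, detrend = detrend),
                    error = function(e) NULL)
    fits[[j]] <<- fit
    tibble(
      window_center_beat = mean(range(sel)),
      mean_bcl_ms = mean(df$cl_ms[sel]),
      lambda_alt = if (is.null(fit)) NA_real_ else Re(fit$lambda_alt_hat),
      lambda_alt_im = if (is.null(fit)) NA_real_
                      else Im(fit$lambda_alt_hat),
      s_s1s2 = if (is.null(fit)) NA_real_ else fit$s_s1s2_hat)
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("track_result", class(out))
  attr(out, "fits") <- fits
  attr(out, "window") <- window
  attr(out, "step") <- step
  out
}

#' Extrapolate the alternans onset from tracked eigenvalue estimates
#'
#' Ordinary least squares of the windowed `lambda_alt` estimates on a
#' predictor (window mean BCL for ramps, window centre beat for
#' parameter-drift protocols), restricted to points with
#' `lambda_alt > cutoff`; the onset is where the regression line reaches
#' -1. Windows with `|Im(lambda_alt)| > im_tol` are dropped from the
#' regression.
#'
#' @param track a [track_result][windowed_lambda].
#' @param predictor `"bcl"` or `"beat"`.
#' @param cutoff only points with `lambda_alt > cutoff` enter the
#'   regression.
#' @param im_tol imaginary-part tolerance for including a window.
#' @return List of class `onset_prediction`: `slope`, `intercept`,
#'   `cutoff`, `predictor`, `onset` (predicted BCL in ms or beat index),
#'   `n_points`.
#' @export
extrapolate_onset <- function(track, predictor = c("bcl", "beat"),
                              cutoff = -0.85, im_tol = 0.1) {
  predictor <- match.arg(predictor)
  x_all <- if (predictor == "bcl") track$mean_bcl_ms
           else track$window_center_beat
  keep <- is.finite(track$lambda_alt) & track$lambda_alt > cutoff &
    (!is.finite(track$lambda_alt_im) | abs(track$lambda_alt_im) <= im_tol)
  x <- x_all[keep]; y <- track$lambda_alt[keep]
  if (length(x) < 3) {
    abort("Fewer than 3 points above the cutoff.",
          class = "stochpace_input_error")
  }
  cf <- coef(lm.fit(cbind(1, x), y))
  intercept <- cf[1]; slope <- cf[2]
  if (!is.finite(slope) || slope == 0) {
    abort("Regression slope undefined.", class = "stochpace_input_error")
  }
  # direction of protocol progression over windows
  trend <- sign(tail(x_all[is.finite(x_all)], 1) -
                head(x_all[is.finite(x_all)], 1))
  if (trend == 0) trend <- 1
  if (slope * trend >= 0) {
    abort("No approach: lambda_alt moves away from -1 as the protocol progresses.",
          class = c("stochpace_no_approach", "stochpace_error"))
  }
  structure(
    list(slope = unname(slope), intercept = unname(intercept),
         cutoff = cutoff, predictor = predictor,
         onset = unname((-1 - intercept) / slope),
         n_points = length(x)),
    class = "onset_prediction")
}

#' Alternans eigenvalue from the decay of a post-step APD transient
#'
#' After a step change of BCL, the APD alternation decays geometrically with
#' ratio `|lambda_alt|`. Fits `|dAPD_n| = C * r^n` by log-linear least
#' squares over the initial strictly alternating beats with `|dAPD|` above a
#' floor, and returns `lambda = -r` (the sign follows from the alternating
#' pattern).
#'
#' @param series a [beat_series()] starting at the step, or an APD vector.
#' @param floor_ms minimum `|dAPD|` (ms) for a beat to enter the fit;
#'   defaults to `max(0.1, 3 * noise_sd)`.
#' @param noise_sd known APD measurement-noise SD (ms), used for the default
#'   floor.
#' @return List: `lambda`, `ratio`, `n_used`, `r_squared`.
#' @export
lambda_from_step_decay <- function(series, floor_ms = NULL, noise_sd = 0) {
  apd <- if (is.numeric(series)) series else as_beat_frame(series)$apd_ms
  floor_ms <- floor_ms %||% max(0.1, 3 * noise_sd)
  d <- diff(apd)
  ok <- abs(d) >= floor_ms
  altern <- sign(d[-1]) == -sign(d[-length(d)])
  # locate the first strictly alternating run above the floor (the first
  # post-step beats may be dominated by the memory-mode shift)
  s <- which(altern & ok[-length(ok)] & ok[-1])[1]
  if (is.na(s)) {
    abort("No decaying alternation detected after the step.",
          class = c("stochpace_no_alternation", "stochpace_error"))
  }
  e <- s
  while (e < length(d) - 1 && altern[e + 1] && ok[e + 2]) e <- e + 1
  idx <- s:(e + 1)
  if (length(idx) < 5) {
    abort("No decaying alternation detected after the step.",
          class = c("stochpace_no_alternation", "stochpace_error"))
  }
  ly <- log(abs(d[idx]))
  n_used <- length(idx)
  idx <- seq_along(idx)
  fit <- lm.fit(cbind(1, idx), ly)
  r <- exp(coef(fit)[2])
  ss_res <- sum(fit$residuals^2)
  ss_tot <- sum((ly - mean(ly))^2)
  list(lambda = -unname(r), ratio = unname(r), n_used = n_used,
       r_squared = if (ss_tot > 0) 1 - ss_res / ss_tot else NA_real_)
}

#' Add simulated APD measurement noise to a beat series
#'
#' Adds i.i.d. Gaussian error to the APD column and recomputes DI as
#' `cl - apd` so the conservation identity is preserved; the input series is
#' untouched.
#'
#' @param series a [beat_series()].
#' @param sd noise standard deviation (ms).
#' @param seed optional integer seed.
#' @return A new [beat_series()].
#' @export
add_apd_noise <- function(series, sd, seed = NULL) {
  if (sd < 0) abort("`sd` must be >= 0.", class = "stochpace_input_error")
  if (sd == 0) return(series)
  if (!is.null(seed)) set.seed(seed)
  df <- as_beat_frame(series)
  out <- series
  out$apd_ms <- df$apd_ms + rnorm(nrow(df), 0, sd)
  out$di_ms <- out$cl_ms - out$apd_ms
  out
}
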