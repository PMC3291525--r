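#' Synthetic beat series from an exact ARMA recursion
#'
#' Generates a beat series whose cycle-length-to-APD relation follows a
#' known ARMA model exactly: `dt ~ N(0, input_sd)` and
#' `da_n = -sum alpha_i da_(n-i) + sum beta_i dt_(n-i)`. The series is
#' offset to physiological APD/CL levels and serves as an oracle for
#' [fit_arma()] (the generating coefficients are the truth).
#'
#' @param alpha,beta ARMA coefficient vectors (equal length `M`); all roots
#'   of `z^M + alpha_1 z^(M-1) + ... + alpha_M` must lie inside the unit
#'   circle.
#' @param input_sd SD of the Gaussian cycle-length deviations (ms).
#' @param n number of beats.
#' @param seed optional integer seed.
#' @param apd_noise_sd optional output measurement noise SD (ms).
#' @param bcl,apd_level offsets (ms) applied to the deviation series.
#' @return A [beat_series()].
#' @export
arma_process <- function(alpha, beta, input_sd = 5, n = 200, seed = NULL,
                         apd_noise_sd = 0, bcl = 400, apd_level = 200) {
  M <- length(alpha)
  stopifnot(length(beta) == M)
  roots <- polyroot(rev(c(1, alpha)))
  if (any(Mod(roots) >= 1)) {
    abort("Unstable pole set: all roots must lie inside the unit circle.",
          class = "stochpace_input_error")
  }
  if (!is.null(seed)) set.seed(seed)
  dt <- rnorm(n, 0, input_sd)
  da <- numeric(n)
  for (i in seq_len(n)) {
    for (k in seq_len(min(M, i - 1))) {
      da[i] <- da[i] - alpha[k] * da[i - k] + beta[k] * dt[i - k]
    }
  }
  if (apd_noise_sd > 0) da <- da + rnorm(n, 0, apd_noise_sd)
  beat_series(bcl + dt, apd_level + da,
              meta = list(model_id = "arma_process", bcl = bcl,
                          sd = input_sd, seed = seed,
                          alpha = alpha, beta = beta))
}

#' Preset study configurations
#'
#' Named, seed-pinned configurations covering the regimes the package is
#' designed to probe: a steep memoryless map, the calcium-coupled map near
#' its bifurcation for both coupling signs, the ionic model at a routine
#' rate, and a stationary stochastic-pacing setup (BCL 400 ms, SD 5 ms,
#' 100 beats, 3rd-order ARMA) for worked identification examples.
#'
#' @param name one of `"map1d_steep"`, `"camap2d_pos_near_bif"`,
#'   `"camap2d_neg_near_bif"`, `"ms_ode_default"`, `"fig3_like"`.
#' @return A list of class `run_config` with elements `model`, `protocol`,
#'   `analysis`, `seed`.
#' @export
preset <- function(name) {
  presets <- list(
    map1d_steep = list(
      model = list(kind = "map1d", params = list(tau_f = 50)),
      protocol = list(kind = "stochastic", bcl = 340, sd = 5, n = 100),
      analysis = list(order = 3, detrend = "mean"),
      seed = 101L),
    camap2d_pos_near_bif = list(
      model = list(kind = "camap2d", params = list(gamma = 30)),
      protocol = list(kind = "stochastic", bcl = 430, sd = 5, n = 100),
      analysis = list(order = 3, detrend = "mean"),
      seed = 102L),
    camap2d_neg_near_bif = list(
      model = list(kind = "camap2d", params = list(gamma = -30)),
      protocol = list(kind = "stochastic", bcl = 430, sd = 5, n = 100),
      analysis = list(order = 3, detrend = "mean"),
      seed = 103L),
    ms_ode_default = list(
      model = list(kind = "ms_ode", params = list()),
      protocol = list(kind = "stochastic", bcl = 400, sd = 5, n = 100),
      analysis = list(order = 3, detrend = "mean"),
      seed = 104L),
    fig3_like = list(
      model = list(kind = "camap2d", params = list(gamma = 30)),
      protocol = list(kind = "stochastic", bcl = 430, sd = 5, n = 100),
      analysis = list(order = 3, detrend = "mean"),
      seed = 105L))
  if (!name %in% names(presets)) {
    abort(sprintf("Unknown preset `%s`; available: %s.", name,
                  paste(names(presets), collapse = ", ")),
          class = "stochpace_input_error")
  }
  structure(presets[[name]], class = "run_config", name = name)
}

#' Run a stochastic-pacing configuration
#'
#' Executes the stochastic-pacing protocol of a [preset()] (or equivalent
#' `run_config` list): settles the model at the configured BCL, paces with
#' Gaussian cycle-length variations and returns the recorded beat series.
#'
#' @param config a `run_config` (see [preset()]).
#' @return A [beat_series()].
#' @export
run_config_series <- function(config) {
  model <- cell_model(config$model$kind, config$model$params)
  pr <- config$protocol
  ss <- settle(model, pr$bcl)
  cls <- gaussian_cl_series(pr$bcl, pr$sd, pr$n, seed = config$seed,
                            apd_ref = ss$apd_ms)
  out <- run_beats(model, cls, state0 = ss$state)
  series <- out$series
  meta <- series_meta(series)
  meta$bcl <- pr$bcl
  meta$sd <- pr$sd
  meta$seed <- config$seed
  attr(series, "meta") <- meta
  series
}
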