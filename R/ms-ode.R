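# R-side plumbing for the minimal two-current ionic model (ms_ode).

ms_params_for_c <- function(model) model$params

#' @export
model_beat.ms_ode <- function(model, state, cl) {
  res <- .ms_run(state, cl, ms_params_for_c(model))
  if (!is.na(res$failed_beat)) {
    capture_error(sprintf(
      "Capture failure: no action potential / repolarization at CL %.2f ms.",
      cl))
  }
  apd <- res$apd[1]
  list(state = as.numeric(res$states[1, ]), apd = apd, di = cl - apd)
}

#' @export
model_run.ms_ode <- function(model, state, cl_series) {
  res <- .ms_run(state, cl_series, ms_params_for_c(model))
  list(states = res$states, apd = res$apd, di = cl_series - res$apd,
       n_done = res$n_done, failed_beat = res$failed_beat,
       state = as.numeric(res$state))
}

#' Simulate the voltage trace of one paced beat (`ms_ode` only)
#'
#' @param model an `ms_ode` [cell_model()].
#' @param state state `(v, h)` at stimulus onset.
#' @param cl cycle length (ms).
#' @return A tibble with columns `time_ms`, `v`, `h` sampled at the
#'   integration step.
#' @export
simulate_trace <- function(model, state, cl) {
  stopifnot(inherits(model, "ms_ode"))
  state <- check_state(model, state)
  as_tibble(as.data.frame(.ms_trace(state, cl, ms_params_for_c(model))))
}

# Diastolic stimulus-threshold search: smallest 1-ms pulse amplitude that
# elicits an AP from rest; the working amplitude is stim_mult times this.
ms_calibrate_stimulus <- function(model, lo = 1e-3, hi = 2, tol = 1e-3) {
  p <- model$params
  rest <- c(1e-4, 1.0)
  elicits <- function(amp) {
    p2 <- p; p2$stim_amp <- amp
    res <- .ms_run(rest, 600, p2)
    is.na(res$failed_beat)
  }
  if (!elicits(hi)) {
    abort("Stimulus threshold search failed: no capture at maximum amplitude.",
          class = "stochpace_model_error")
  }
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (elicits(mid)) hi <- mid else lo <- mid
  }
  p$stim_mult * hi
}

# model right-hand side without stimulus, used for the cycle-length
# sensitivity vector (dv/dt just before stimulus onset at steady state)
model_rhs <- function(model, state) UseMethod("model_rhs")

#' @export
model_rhs.ms_ode <- function(model, state) {
  p <- model$params
  v <- state[1]; h <- state[2]
  sg <- 1 / (1 + exp((v - p$v_gate) / p$k_gate))
  c(h * v^2 * (1 - v) / p$tau_in - v / p$tau_out,
    sg * (1 - h) / p$tau_open - (1 - sg) * h / p$tau_close)
}

#' Locate activation/repolarization markers on an action potential trace
#'
#' Threshold crossing times are located by linear interpolation between the
#' bracketing samples of a uniformly sampled trace; APD is the interval from
#' the upward crossing of `up_thr` to the subsequent downward crossing of
#' `down_thr`.
#'
#' @param time_ms uniform time grid (ms).
#' @param v voltage samples (any units; thresholds must be within range).
#' @param up_thr activation threshold (upward crossing).
#' @param down_thr repolarization threshold (downward crossing).
#' @return List with `t_act`, `t_rep`, `apd` (ms).
#' @export
measure_ap_markers <- function(time_ms, v, up_thr, down_thr) {
  if (length(time_ms) != length(v) || length(v) < 2) {
    abort("`time_ms` and `v` must be equal-length vectors (n >= 2).",
          class = "stochpace_input_error")
  }
  up <- which(v[-length(v)] < up_thr & v[-1] >= up_thr)
  if (!length(up)) {
    capture_error("No capture: trace never crosses the activation threshold.")
  }
  i <- up[1]
  t_act <- time_ms[i] + (time_ms[i + 1] - time_ms[i]) *
    (up_thr - v[i]) / (v[i + 1] - v[i])
  after <- seq(i + 1, length(v) - 1)
  dn <- after[v[after] >= down_thr & v[after + 1] < down_thr]
  if (!length(dn)) {
    capture_error("No repolarization crossing before the end of the trace.")
  }
  j <- dn[1]
  t_rep <- time_ms[j] + (time_ms[j + 1] - time_ms[j]) *
    (v[j] - down_thr) / (v[j] - v[j + 1])
  list(t_act = t_act, t_rep = t_rep, apd = t_rep - t_act)
}
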