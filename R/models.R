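#' Built-in beat-to-beat cardiac cell models
#'
#' Constructs a paced-cell model advanced one stimulus-to-stimulus cycle at a
#' time. The state vector is snapshotted at stimulus onset; one call to
#' [beat_update()] advances it across a full pacing cycle (action potential
#' followed by diastolic interval) and reports the APD and DI of that cycle.
#'
#' Available kinds:
#' \describe{
#'   \item{`map1d`}{Memoryless restitution map, state = upcoming APD.
#'     `a' = f(d)` with `f(d) = a_max - A * exp(-d / tau_f)`.}
#'   \item{`camap2d`}{Two-variable map coupling APD to sarcoplasmic-reticulum
#'     (SR) calcium load `l`. Release `r' = l * q(l) * s(d)` with a sigmoidal
#'     load dependence `q` and a diastolic-interval restitution of release
#'     `s(d) = 1 - kappa * exp(-d / tau_r)`; uptake refills toward `l_max`
#'     with time constant `tau_up`; APD `a' = f(d) + gamma * r'`. `gamma > 0`
#'     gives positive, `gamma < 0` negative calcium-to-APD coupling.}
#'   \item{`ms_ode`}{Minimal two-current ionic model (Mitchell-Schaeffer
#'     form) with a smoothed recovery gate, integrated by forward Euler;
#'     APD measured from threshold crossings of the simulated voltage trace.}
#'   \item{`linear2d`}{Affine two-variable diagnostic map
#'     `x' = M x + b + g * (cl - cl0)`, APD `= c . x + a0`; useful as an
#'     exactly linear system for validating the numerical linearization.}
#' }
#'
#' @param kind one of `"map1d"`, `"camap2d"`, `"ms_ode"`, `"linear2d"`.
#' @param ... named model parameters overriding the defaults. Unknown
#'   parameter names are rejected.
#'
#' @return An object of class `c(kind, "cell_model")` with elements `kind`,
#'   `params` and `state_dim`.
#' @examples
#' m <- cell_model("map1d", tau_f = 100)
#' beat_update(m, state = 240, cl = 350)
#' @export
cell_model <- function(kind, ...) {
  kinds <- c("map1d", "camap2d", "ms_ode", "linear2d")
  if (!is.character(kind) || length(kind) != 1 || !kind %in% kinds) {
    abort(sprintf("Unknown model kind %s; must be one of %s.",
                  deparse(substitute(kind)), paste(kinds, collapse = ", ")),
          class = "stochpace_model_error")
  }
  defaults <- model_defaults(kind)
  user <- list(...)
  if (length(user) == 1 && is.null(names(user)) && is.list(user[[1]])) {
    user <- user[[1]]
  }
  unknown <- setdiff(names(user), names(defaults))
  if (length(unknown)) {
    abort(sprintf("Unknown parameter(s) for %s model: %s.", kind,
                  paste(unknown, collapse = ", ")),
          class = "stochpace_model_error")
  }
  params <- modifyList(defaults, user)
  bad <- names(params)[!vapply(params, function(p)
    is.numeric(p) && length(p) == 1 && is.finite(p), TRUE)]
  bad <- setdiff(bad, "stim_amp")  # stim_amp may be NA until calibrated
  if (length(bad)) {
    abort(sprintf("Parameter(s) not finite scalars: %s.",
                  paste(bad, collapse = ", ")),
          class = "stochpace_model_error")
  }
  model <- structure(
    list(kind = kind, params = params,
         state_dim = switch(kind, map1d = 1L, camap2d = 2L,
                            ms_ode = 2L, linear2d = 2L)),
    class = c(kind, "cell_model"))
  if (kind == "ms_ode" && !is.finite(params$stim_amp)) {
    model$params$stim_amp <- ms_calibrate_stimulus(model)
  }
  model
}

model_defaults <- function(kind) {
  switch(kind,
    map1d = list(a_max = 300, A = 150, tau_f = 100),
    camap2d = list(a_max = 300, A = 150, tau_f = 300,
                   l_max = 2, l_c = 1.35, k_l = 0.08,
                   kappa = 0.8, tau_r = 80, tau_up = 400, gamma = 30),
    ms_ode = list(tau_in = 0.3, tau_out = 6, tau_open = 80, tau_close = 150,
                  v_gate = 0.13, k_gate = 0.005, dt = 0.02,
                  stim_dur = 1, stim_mult = 6, stim_amp = NA_real_,
                  v_up = 0.5, v_down = 0.05),
    linear2d = list(m11 = 0.5, m12 = 0, m21 = 0, m22 = 0.5,
                    b1 = 100, b2 = 0, g1 = 0, g2 = 0,
                    c1 = 1, c2 = 0, a0 = 0, cl0 = 400))
}

#' Default initial state for a model
#' @param model a [cell_model()].
#' @return Numeric state vector at stimulus onset.
#' @export
init_state <- function(model) UseMethod("init_state")
#' @export
init_state.map1d <- function(model) model$params$a_max / 2
#' @export
init_state.camap2d <- function(model) c(model$params$a_max / 2, 1.2)
#' @export
init_state.ms_ode <- function(model) c(0.001, 0.95)
#' @export
init_state.linear2d <- function(model) c(0, 0)

check_state <- function(model, state) {
  if (length(state) != model$state_dim || any(!is.finite(state))) {
    abort(sprintf("State must be a finite vector of length %d.",
                  model$state_dim),
          class = "stochpace_model_error")
  }
  as.numeric(state)
}

capture_error <- function(msg, beat = NA_integer_) {
  abort(msg, class = c("stochpace_capture_error", "stochpace_error"),
        beat = beat)
}

# one-beat update; returns list(state, apd, di)
model_beat <- function(model, state, cl) UseMethod("model_beat")

map1d_f <- function(d, p) p$a_max - p$A * exp(-d / p$tau_f)
map1d_fprime <- function(d, p) (p$A / p$tau_f) * exp(-d / p$tau_f)

#' @export
model_beat.map1d <- function(model, state, cl) {
  p <- model$params
  apd <- state[1]
  di <- cl - apd
  if (di <= 0) {
    capture_error(sprintf(
      "Capture failure: DI = %.3f ms <= 0 (APD %.3f at CL %.3f).",
      di, apd, cl))
  }
  list(state = map1d_f(di, p), apd = apd, di = di)
}

#' @export
model_beat.camap2d <- function(model, state, cl) {
  p <- model$params
  a <- state[1]; l <- state[2]
  di <- cl - a
  if (di <= 0) {
    capture_error(sprintf(
      "Capture failure: DI = %.3f ms <= 0 (APD %.3f at CL %.3f).", di, a, cl))
  }
  q <- 1 / (1 + exp(-(l - p$l_c) / p$k_l))
  s <- 1 - p$kappa * exp(-di / p$tau_r)
  r <- l * q * s
  l_rel <- l - r
  l_next <- l_rel + (p$l_max - l_rel) * (1 - exp(-cl / p$tau_up))
  a_next <- map1d_f(di, p) + p$gamma * r
  list(state = c(a_next, l_next), apd = a, di = di)
}

#' @export
model_beat.linear2d <- function(model, state, cl) {
  p <- model$params
  M <- matrix(c(p$m11, p$m21, p$m12, p$m22), 2, 2)
  apd <- p$c1 * state[1] + p$c2 * state[2] + p$a0
  di <- cl - apd
  st <- as.numeric(M %*% state) + c(p$b1, p$b2) +
    c(p$g1, p$g2) * (cl - p$cl0)
  list(state = st, apd = apd, di = di)
}

#' Advance a cell model by one pacing cycle
#'
#' @param model a [cell_model()].
#' @param state state vector at stimulus onset.
#' @param cl pacing cycle length of this beat (ms), `> 0`.
#'
#' @return List with `state` (state at the next stimulus onset), `apd` and
#'   `di` (ms); `apd + di == cl` (exactly for map models, within trace
#'   resolution for `ms_ode`).
#' @export
beat_update <- function(model, state, cl) {
  stopifnot(inherits(model, "cell_model"))
  state <- check_state(model, state)
  if (!is.numeric(cl) || length(cl) != 1 || !is.finite(cl) || cl <= 0) {
    abort("`cl` must be a positive finite scalar (ms).",
          class = "stochpace_input_error")
  }
  model_beat(model, state, cl)
}

# internal batch runner; returns list(states = n x N matrix of end states,
# apd, di, n_done, failed_beat (NA if none))
model_run <- function(model, state, cl_series) UseMethod("model_run")

#' @export
model_run.default <- function(model, state, cl_series) {
  n <- length(cl_series)
  states <- matrix(NA_real_, n, model$state_dim)
  apd <- di <- rep(NA_real_, n)
  failed <- NA_integer_
  for (i in seq_len(n)) {
    res <- tryCatch(model_beat(model, state, cl_series[i]),
                    stochpace_capture_error = function(e) e)
    if (inherits(res, "error")) { failed <- i; break }
    state <- res$state
    states[i, ] <- state
    apd[i] <- res$apd
    di[i] <- res$di
  }
  list(states = states, apd = apd, di = di,
       n_done = if (is.na(failed)) n else failed - 1L, failed_beat = failed,
       state = state)
}

#' Run a model over a series of pacing cycles
#'
#' @inheritParams beat_update
#' @param cl_series numeric vector of per-beat cycle lengths (ms).
#' @param state0 initial state at the first stimulus onset; defaults to
#'   [init_state()].
#'
#' @return List with `series` (a [beat_series()]) and `state` (the state at
#'   the stimulus onset following the last beat). Deterministic: identical
#'   inputs give bit-identical output. A capture failure aborts with the
#'   failing beat index.
#' @export
run_beats <- function(model, cl_series, state0 = init_state(model)) {
  stopifnot(inherits(model, "cell_model"))
  if (length(cl_series) == 0) {
    abort("`cl_series` must be non-empty.", class = "stochpace_input_error")
  }
  if (any(!is.finite(cl_series)) || any(cl_series <= 0)) {
    abort("All cycle lengths must be positive and finite.",
          class = "stochpace_input_error")
  }
  state0 <- check_state(model, state0)
  res <- model_run(model, state0, cl_series)
  if (!is.na(res$failed_beat)) {
    capture_error(sprintf("Capture failure at beat %d.", res$failed_beat),
                  beat = res$failed_beat)
  }
  series <- beat_series(cl_series, res$apd,
                        meta = list(model_id = model$kind,
                                    bcl = mean(cl_series)))
  list(series = series, state = res$state)
}

#' Pace a model to steady state
#'
#' Iterates the beat map at a fixed basic cycle length until the relative
#' beat-to-beat variation of every state variable falls below `rel_tol`
#' (period-1 steady state). If instead the variation between beats `i` and
#' `i - 2` satisfies the criterion while `i` vs `i - 1` does not, the pacing
#' regime is a period-2 (alternans) cycle and a classed condition
#' `"stochpace_alternans"` is signalled, carrying both alternating states.
#'
#' @inheritParams beat_update
#' @param bcl basic cycle length (ms).
#' @param rel_tol relative beat-to-beat variation threshold.
#' @param max_beats maximum number of beats.
#' @param state0 initial state.
#'
#' @return List of class `settle_result`: `state`, `apd_ms`, `di_ms`,
#'   `beats`, `status = "period1"`.
#' @export
settle <- function(model, bcl, rel_tol = 1e-7, max_beats = 1000,
                   state0 = init_state(model)) {
  stopifnot(inherits(model, "cell_model"))
  if (rel_tol <= 0) abort("`rel_tol` must be > 0.",
                          class = "stochpace_input_error")
  if (max_beats < 1) abort("`max_beats` must be >= 1.",
                           class = "stochpace_input_error")
  state <- check_state(model, state0)
  prev1 <- prev2 <- NULL
  apd_prev <- NA_real_
  apds <- numeric(max_beats)
  rel1_hist <- rep(NA_real_, max_beats)
  lookback <- 200L
  chunk <- 64L
  beats <- 0L
  while (beats < max_beats) {
    nb <- min(chunk, max_beats - beats)
    res <- model_run(model, state, rep(bcl, nb))
    if (!is.na(res$failed_beat)) {
      capture_error(sprintf("Capture failure at beat %d while settling.",
                            beats + res$failed_beat),
                    beat = beats + res$failed_beat)
    }
    for (i in seq_len(nb)) {
      st <- res$states[i, ]
      beats <- beats + 1L
      apds[beats] <- res$apd[i]
      if (!is.null(prev1)) {
        rel1 <- max(abs(st - prev1) / (abs(prev1) + 1e-12))
        rel1_hist[beats] <- rel1
        if (rel1 < rel_tol) {
          return(structure(list(state = st, apd_ms = res$apd[i],
                                di_ms = res$di[i], beats = beats,
                                status = "period1"),
                           class = "settle_result"))
        }
        if (!is.null(prev2)) {
          rel2 <- max(abs(st - prev2) / (abs(prev2) + 1e-12))
          # a genuine period-2 cycle must (i) have converged in the i vs i-2
          # sense, (ii) keep a non-vanishing alternation amplitude and
          # (iii) hold that amplitude over a lookback window -- a slowly
          # *decaying* alternation near threshold meets (i)+(ii) transiently
          amp_stable <- beats > lookback &&
            is.finite(rel1_hist[beats - lookback]) &&
            rel1 >= 0.98 * rel1_hist[beats - lookback]
          if (rel2 < rel_tol && rel1 > 1e3 * rel_tol && amp_stable) {
            abort(sprintf(
              "Alternans regime at BCL %.1f ms (period-2 after %d beats).",
              bcl, beats),
              class = c("stochpace_alternans", "stochpace_error"),
              state_a = prev1, state_b = st,
              apd_a = apd_prev, apd_b = res$apd[i], beats = beats)
          }
        }
      }
      prev2 <- prev1; prev1 <- st; apd_prev <- res$apd[i]
    }
    state <- res$state
  }
  apds <- apds[seq_len(beats)]
  abort(sprintf(
    "No steady state or period-2 cycle within %d beats at BCL %.1f ms.",
    max_beats, bcl),
    class = c("stochpace_no_convergence", "stochpace_error"),
    state = state, apds = apds, beats = beats)
}

#' Classify the pacing regime at a given cycle length
#'
#' Wraps [settle()]; when neither the period-1 nor the period-2 criterion is
#' met within `max_beats` (as happens close to the bifurcation where
#' perturbations decay or grow very slowly), the regime is classified by the
#' growth or decay trend of the APD alternation amplitude over the final
#' beats.
#'
#' @inheritParams settle
#' @return List with `status` (`"period1"` or `"alternans"`), `bcl` and,
#'   when available, the settled `state`/`apd_ms` or both alternating APDs.
#' @export
pacing_regime <- function(model, bcl, rel_tol = 1e-7, max_beats = 1000,
                          state0 = init_state(model)) {
  tryCatch({
    s <- settle(model, bcl, rel_tol, max_beats, state0)
    list(status = "period1", bcl = bcl, state = s$state, apd_ms = s$apd_ms,
         beats = s$beats)
  },
  stochpace_alternans = function(e) {
    list(status = "alternans", bcl = bcl,
         apd_a = e$apd_a, apd_b = e$apd_b,
         amplitude = abs(e$apd_a - e$apd_b), beats = e$beats)
  },
  stochpace_no_convergence = function(e) {
    # trend of |dAPD| over the tail: growing => alternans side
    apds <- e$apds
    n <- length(apds)
    dif <- abs(diff(apds[max(1, n - 200):n]))
    dif <- dif[dif > 0]
    status <- "period1"
    if (length(dif) >= 10) {
      idx <- seq_along(dif)
      slope <- coef(lm.fit(cbind(1, idx), log(dif)))[2]
      if (is.finite(slope) && slope > 0) status <- "alternans"
    }
    list(status = status, bcl = bcl, beats = e$beats, converged = FALSE)
  })
}
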