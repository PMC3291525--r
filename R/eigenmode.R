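#' Finite-difference Jacobian of the one-beat map
#'
#' Column `c` is the central finite difference of the stimulus-to-stimulus
#' state map with respect to state element `c`, evaluated at the settled
#' period-1 state. The perturbation is `delta_c = max(delta_rel * |v_c|,
#' delta_min)` per element; on a capture failure the perturbation is reduced
#' tenfold once before failing.
#'
#' @param model a [cell_model()].
#' @param bcl basic cycle length (ms).
#' @param v_ss settled period-1 state at `bcl`; settled internally when
#'   omitted.
#' @param delta_rel,delta_min finite-difference perturbation controls.
#' @return `N x N` Jacobian matrix.
#' @export
beat_jacobian <- function(model, bcl, v_ss = NULL,
                          delta_rel = 1e-6, delta_min = 1e-9) {
  v_ss <- v_ss %||% settle(model, bcl)$state
  N <- model$state_dim
  J <- matrix(NA_real_, N, N)
  for (cc in seq_len(N)) {
    J[, cc] <- fd_column(model, v_ss, bcl, cc, delta_rel, delta_min,
                         function(res) res$state)
  }
  J
}

# central difference of `extract(model_beat(...))` w.r.t. state element cc,
# with one automatic delta/10 retry on capture failure
fd_column <- function(model, v_ss, cl, cc, delta_rel, delta_min, extract) {
  delta <- max(delta_rel * abs(v_ss[cc]), delta_min)
  for (attempt in 1:2) {
    up <- dn <- v_ss
    up[cc] <- up[cc] + delta
    dn[cc] <- dn[cc] - delta
    res <- tryCatch({
      a <- model_beat(model, up, cl)
      b <- model_beat(model, dn, cl)
      (extract(a) - extract(b)) / (2 * delta)
    }, stochpace_capture_error = function(e) e)
    if (!inherits(res, "error")) return(res)
    delta <- delta / 10
  }
  abort(sprintf(
    "Perturbed beat lost capture for state element %d (delta down to %g).",
    cc, delta * 10),
    class = c("stochpace_capture_error", "stochpace_error"))
}

#' APD-sensitivity vector
#'
#' Element `c` is the sensitivity of the APD of the beat triggered at the
#' state snapshot to state element `c`, by central finite differences at the
#' settled state (same perturbation policy as [beat_jacobian()]).
#'
#' @inheritParams beat_jacobian
#' @return Numeric vector of length `N`.
#' @export
apd_sensitivity_vector <- function(model, bcl, v_ss = NULL,
                                   delta_rel = 1e-6, delta_min = 1e-9) {
  v_ss <- v_ss %||% settle(model, bcl)$state
  vapply(seq_len(model$state_dim), function(cc)
    fd_column(model, v_ss, bcl, cc, delta_rel, delta_min,
              function(res) res$apd),
    numeric(1))
}

#' Cycle-length-sensitivity vector
#'
#' Sensitivity of the next stimulus-onset state to the length of the
#' preceding pacing cycle. For map models this is a central finite
#' difference of the one-beat map with respect to `cl`; for ODE models it is
#' evaluated from the model right-hand side at the settled state just before
#' the stimulus (`dv/dt` at `v_ss`), the two routes agreeing because
#' lengthening the cycle lets the state evolve freely for the extra time.
#'
#' @inheritParams beat_jacobian
#' @param method `"auto"` (RHS for ODE models, finite difference for maps),
#'   `"fd"` or `"rhs"`.
#' @param delta_cl cycle-length perturbation (ms) for the finite-difference
#'   route.
#' @return Numeric vector of length `N` (state units per ms).
#' @export
cl_sensitivity_vector <- function(model, bcl, v_ss = NULL,
                                  method = c("auto", "fd", "rhs"),
                                  delta_cl = 1e-3) {
  method <- match.arg(method)
  v_ss <- v_ss %||% settle(model, bcl)$state
  if (method == "auto") {
    method <- if (inherits(model, "ms_ode")) "rhs" else "fd"
  }
  if (method == "rhs") {
    return(model_rhs(model, v_ss))
  }
  # for fixed-step ODE models the cycle length is quantized to the
  # integration step; the perturbation must be a whole number of steps
  if (!is.null(model$params$dt)) {
    dt <- model$params$dt
    delta_cl <- max(dt, round(delta_cl / dt) * dt)
  }
  a <- model_beat(model, v_ss, bcl + delta_cl)
  b <- model_beat(model, v_ss, bcl - delta_cl)
  (a$state - b$state) / (2 * delta_cl)
}

#' Full linearization of the beat map at steady state
#'
#' Convenience wrapper settling the model and assembling the Jacobian `J`,
#' the APD-sensitivity vector `a_vec` and the cycle-length-sensitivity
#' vector `vprime` in one object.
#'
#' @inheritParams beat_jacobian
#' @return List of class `jacobian_pack` with elements `J`, `a_vec`,
#'   `vprime`, `bcl`, `v_ss`, `fd_delta`.
#' @export
jacobian_pack <- function(model, bcl, v_ss = NULL,
                          delta_rel = 1e-6, delta_min = 1e-9) {
  v_ss <- v_ss %||% settle(model, bcl)$state
  structure(
    list(J = beat_jacobian(model, bcl, v_ss, delta_rel, delta_min),
         a_vec = apd_sensitivity_vector(model, bcl, v_ss, delta_rel,
                                        delta_min),
         vprime = cl_sensitivity_vector(model, bcl, v_ss),
         bcl = bcl, v_ss = v_ss,
         fd_delta = pmax(delta_rel * abs(v_ss), delta_min)),
    class = "jacobian_pack")
}

#' Eigenvalue summary of a beat-map Jacobian
#'
#' The eigenvalue closest to −1 (complex distance) is the alternans
#' eigenvalue `lambda_alt`; the eigenvalue closest to +1 is the principal
#' memory eigenvalue `lambda_mem`. Ties are broken toward the more negative
#' (resp. more positive) real part. The memory time constant is
#' `tau_mem_beats = -1 / log(|lambda_mem|)` when `0 < |lambda_mem| < 1`
#' (otherwise `NA`), and `tau_mem_ms = tau_mem_beats * bcl`. Eigenvalues of
#' modulus below 0.1 are retained but flagged negligible (such modes
#' dissipate by more than 99 percent within two beats).
#'
#' @param J Jacobian matrix or a [jacobian_pack()].
#' @param bcl basic cycle length (ms), used for `tau_mem_ms`; taken from the
#'   pack when available.
#' @return List of class `eigen_summary`.
#' @export
eigen_summary <- function(J, bcl = NULL) {
  if (inherits(J, "jacobian_pack")) {
    bcl <- bcl %||% J$bcl
    J <- J$J
  }
  if (any(!is.finite(J))) abort("`J` must be finite.",
                                class = "stochpace_input_error")
  ev <- eigen(J, only.values = TRUE)$values
  pick <- function(target, tie_sign) {
    d <- Mod(ev - target)
    cand <- which(d <= min(d) + 1e-12)
    cand[order(tie_sign * Re(ev[cand]))][1]
  }
  i_alt <- pick(-1 + 0i, +1)   # more negative real part wins ties
  i_mem <- pick(+1 + 0i, -1)   # more positive real part wins ties
  lam_mem <- ev[i_mem]
  tau_beats <- if (Mod(lam_mem) > 0 && Mod(lam_mem) < 1)
    -1 / log(Mod(lam_mem)) else NA_real_
  structure(
    list(eigvals = ev,
         lambda_alt = ev[i_alt],
         lambda_mem = lam_mem,
         tau_mem_beats = tau_beats,
         tau_mem_ms = if (!is.null(bcl)) tau_beats * bcl else NA_real_,
         negligible = Mod(ev) < 0.1,
         bcl = bcl),
    class = "eigen_summary")
}

#' @export
print.eigen_summary <- function(x, ...) {
  cat("Eigen summary", if (!is.null(x$bcl)) sprintf("(BCL %.1f ms)", x$bcl),
      "\n")
  cat("  eigenvalues:",
      paste(sprintf("%.4f%+.4fi", Re(x$eigvals), Im(x$eigvals)),
            collapse = ", "), "\n")
  cat(sprintf("  lambda_alt = %.4f%+.4fi  lambda_mem = %.4f%+.4fi\n",
              Re(x$lambda_alt), Im(x$lambda_alt),
              Re(x$lambda_mem), Im(x$lambda_mem)))
  cat(sprintf("  tau_mem = %.1f beats\n", x$tau_mem_beats))
  invisible(x)
}
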