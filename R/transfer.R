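# Rational transfer functions H_{t->a}(z), H_{t->d}(z) between cycle-length
# deviations and APD/DI deviations, in descending powers of z with a monic
# denominator.

# ---- small polynomial helpers (descending coefficient order) ----

poly_from_roots <- function(r) {
  cf <- 1
  for (ri in r) cf <- c(cf, 0) - c(0, cf * ri)
  cf
}

# characteristic polynomial det(zI - A), monic descending, real coefficients
char_poly <- function(A) {
  ev <- eigen(A, only.values = TRUE)$values
  cf <- poly_from_roots(ev)
  if (max(abs(Im(cf))) > 1e-8 * max(1, max(abs(cf)))) {
    warn("Characteristic polynomial has non-negligible imaginary part.")
  }
  Re(cf)
}

polyval_c <- function(cf, z) {
  out <- rep(cf[1] + 0i, length(z))
  for (k in seq_along(cf)[-1]) out <- out * z + cf[k]
  out
}

trim_poly <- function(cf, tol = 1e-12) {
  scale <- max(abs(cf), 1)
  nz <- which(abs(cf) > tol * scale)
  if (!length(nz)) return(0)
  cf[nz[1]:length(cf)]
}

unwrap_phase <- function(ph) {
  if (length(ph) < 2) return(ph)
  d <- diff(ph)
  adj <- -2 * pi * round(d / (2 * pi))
  ph + c(0, cumsum(adj))
}

new_transfer_fn <- function(num, den, source, poles = NULL, zeros = NULL,
                            freqs = NULL, response = NULL, path = NULL) {
  structure(list(num = num, den = den,
                 poles = poles %||% polyroot(rev(den)),
                 zeros = zeros %||%
                   (if (length(num) > 1 || abs(num[1]) > 0)
                     polyroot(rev(num)) else complex(0)),
                 source = source, freqs = freqs, response = response,
                 path = path),
            class = "transfer_fn")
}

#' Evaluate a rational transfer function
#' @param tf a `transfer_fn`.
#' @param z complex evaluation points.
#' @return Complex values `H(z)`.
#' @export
evaluate_tf <- function(tf, z) {
  if (tf$source == "dft") {
    abort("A DFT-sampled transfer function cannot be evaluated at arbitrary z.",
          class = "stochpace_input_error")
  }
  polyval_c(tf$num, z) / polyval_c(tf$den, z)
}

#' Transfer function from the beat-map linearization
#'
#' Builds the rational cycle-length-to-APD transfer function
#' `H(z) = a' (zI - J)^{-1} v'` as a ratio of polynomials. The denominator
#' is the characteristic polynomial of `J` (so the poles are the eigenvalues
#' of `J`); the numerator is obtained from the determinant identity
#' `det(zI - J + v' a') = P_d(z) (1 + H(z))`, i.e. as the difference of two
#' characteristic polynomials. The construction is validated by direct
#' evaluation of `a' (zI - J)^{-1} v'` at 16 points on a circle of radius 2
#' (relative error < 1e-8); if validation fails (e.g. a defective `J`), the
#' numerator is re-fit from samples of `H(z) P_d(z)` and the object records
#' which path was used.
#'
#' @param J beat-map Jacobian, or a [jacobian_pack()] (in which case
#'   `a_vec`/`vprime` are taken from it).
#' @param a_vec APD-sensitivity vector.
#' @param vprime cycle-length-sensitivity vector.
#' @return A `transfer_fn` (source `"eigen"`, strictly proper).
#' @export
tf_from_state_space <- function(J, a_vec = NULL, vprime = NULL) {
  if (inherits(J, "jacobian_pack")) {
    a_vec <- a_vec %||% J$a_vec
    vprime <- vprime %||% J$vprime
    J <- J$J
  }
  N <- nrow(J)
  stopifnot(length(a_vec) == N, length(vprime) == N)
  den <- char_poly(J)
  num_full <- char_poly(J - vprime %*% t(a_vec)) - den
  num <- trim_poly(num_full[-1])  # leading terms cancel: strictly proper
  direct <- function(z) vapply(z, function(zz)
    sum(a_vec * solve(diag(N) * zz - J, vprime)), complex(1))
  zs <- 2 * exp(2i * pi * (seq_len(16) - 0.37) / 16)
  href <- direct(zs)
  happ <- polyval_c(num, zs) / polyval_c(den, zs)
  rel <- max(Mod(happ - href) / pmax(Mod(href), 1e-12))
  path <- "charpoly"
  if (!is.finite(rel) || rel > 1e-8) {
    # fall back: fit numerator coefficients from samples of H(z) P_d(z)
    zf <- 1.5 * exp(2i * pi * (seq_len(N) - 0.29) / N)
    g <- direct(zf) * polyval_c(den, zf)
    V <- t(vapply(zf, function(zz) zz^((N - 1):0), complex(N)))
    cf <- solve(V, g)
    num <- trim_poly(Re(cf))
    path <- "fit"
  }
  new_transfer_fn(num, den, source = "eigen",
                  poles = eigen(J, only.values = TRUE)$values, path = path)
}

#' Complementary DI transfer function
#'
#' Because every cycle splits exactly into APD and DI, the cycle-length-to-DI
#' transfer function is `H_d = 1 - H_a` over the same denominator (the poles
#' are unchanged, the zeros are recomputed).
#'
#' @param tf the cycle-length-to-APD `transfer_fn`.
#' @return A `transfer_fn` for DI.
#' @export
complement_tf <- function(tf) {
  if (tf$source == "dft") {
    return(new_transfer_fn(1, 1, source = "dft", freqs = tf$freqs,
                           response = 1 - tf$response))
  }
  num_a <- c(rep(0, length(tf$den) - length(tf$num)), tf$num)
  num_d <- trim_poly(tf$den - num_a)
  new_transfer_fn(num_d, tf$den, source = tf$source, poles = tf$poles)
}

#' Frequency response of a transfer function
#'
#' Evaluates `H` at `z = exp(2 pi i f)` with the per-beat frequency `f` in
#' `[0, 0.5]`; `f = 0.5` beat^-1 is the alternans frequency (once every two
#' beats). DFT-sampled transfer functions return their own sample grid.
#'
#' @param tf a `transfer_fn`.
#' @param freqs frequencies (beat^-1) in `[0, 0.5]`.
#' @return Tibble with `f_per_beat`, `gain_db`, `phase_rad` (unwrapped along
#'   the grid) and `infinite` (`TRUE` where a pole sits on the unit circle
#'   at the requested frequency).
#' @export
frequency_response <- function(tf, freqs = seq(0, 0.5, by = 0.005)) {
  if (tf$source == "dft") {
    h <- tf$response
    return(tibble(f_per_beat = tf$freqs,
                  gain_db = 20 * log10(Mod(h)),
                  phase_rad = unwrap_phase(Arg(h)),
                  infinite = FALSE))
  }
  if (any(freqs < 0 | freqs > 0.5)) {
    abort("`freqs` must lie in [0, 0.5] beat^-1.",
          class = "stochpace_input_error")
  }
  z <- exp(2i * pi * freqs)
  denv <- polyval_c(tf$den, z)
  inf_flag <- Mod(denv) < 1e-12 * max(abs(tf$den))
  h <- polyval_c(tf$num, z) / denv
  tibble(f_per_beat = freqs,
         gain_db = ifelse(inf_flag, Inf, 20 * log10(Mod(h))),
         phase_rad = unwrap_phase(ifelse(inf_flag, NA_real_, Arg(h))),
         infinite = inf_flag)
}

#' Restitution slopes from a transfer function
#'
#' The S1S2 slope is the one-beat gain: the leading numerator coefficient of
#' a strictly proper `H` (equivalently `lim z H(z)` as `z` grows, and equal
#' to `a' . v'` for an eigen-derived transfer function). The dynamic slope
#' is the steady-state (f = 0, z = 1) response ratio
#' `S_dyn = H_a(1) / H_d(1) = H_a(1) / (1 - H_a(1))`.
#'
#' @param tf the cycle-length-to-APD `transfer_fn` (strictly proper).
#' @return List with `s_s1s2`, `s_dyn` and `s_dyn_infinite` (`TRUE` when
#'   `H_d(1) = 0`).
#' @export
restitution_slopes_from_tf <- function(tf) {
  if (tf$source == "dft") {
    abort("Slopes require a rational transfer function.",
          class = "stochpace_input_error")
  }
  deg_gap <- length(tf$den) - length(tf$num)
  if (deg_gap < 1) {
    abort("`tf` must be strictly proper.", class = "stochpace_input_error")
  }
  s_s1s2 <- if (deg_gap == 1) tf$num[1] / tf$den[1] else 0
  h1 <- evaluate_tf(tf, 1 + 0i)
  hd1 <- 1 - h1
  inf_flag <- Mod(hd1) < 1e-10
  s_dyn <- if (inf_flag) Inf else Re(h1 / hd1)
  list(s_s1s2 = Re(s_s1s2), s_dyn = s_dyn, s_dyn_infinite = inf_flag)
}

#' @export
print.transfer_fn <- function(x, ...) {
  cat(sprintf("Transfer function (source: %s)\n", x$source))
  if (x$source == "dft") {
    cat(sprintf("  %d frequency samples in (0, 0.5] beat^-1\n",
                length(x$freqs)))
  } else {
    cat("  num:", signif(x$num, 6), "\n")
    cat("  den:", signif(x$den, 6), "\n")
    cat("  poles:", paste(sprintf("%.4f%+.4fi", Re(x$poles), Im(x$poles)),
                          collapse = ", "), "\n")
  }
  invisible(x)
}
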