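#' Gaussian stochastic pacing cycle lengths
#'
#' Draws i.i.d. Gaussian cycle lengths around `bcl`. A draw is rejected and
#' redrawn (at most `max_tries` times per beat) when it falls below
#' `bcl - 4 * sd`, or when `apd_ref` is supplied and the expected diastolic
#' interval `draw - apd_ref` would fall below `min_di`.
#'
#' @param bcl mean basic cycle length (ms).
#' @param sd standard deviation of the cycle-length variations (ms).
#' @param n number of beats.
#' @param seed optional integer seed for reproducibility.
#' @param min_di minimum admissible expected DI (ms).
#' @param apd_ref reference APD (ms) used for the expected-DI guard;
#'   `NULL` disables that guard.
#' @param max_tries redraw budget per beat.
#' @return Numeric vector of `n` cycle lengths (ms).
#' @export
gaussian_cl_series <- function(bcl, sd, n, seed = NULL, min_di = 5,
                               apd_ref = NULL, max_tries = 100) {
  if (sd < 0 || n < 1) {
    abort("`sd` must be >= 0 and `n` >= 1.", class = "stochpace_input_error")
  }
  if (!is.null(seed)) set.seed(seed)
  if (sd == 0) return(rep(bcl, n))
  lo <- bcl - 4 * sd
  draw_ok <- function(x) {
    x >= lo && (is.null(apd_ref) || (x - apd_ref) >= min_di)
  }
  out <- numeric(n)
  for (i in seq_len(n)) {
    for (try in seq_len(max_tries)) {
      x <- rnorm(1, bcl, sd)
      if (draw_ok(x)) break
      x <- NA_real_
    }
    if (is.na(x)) {
      abort(sprintf("Redraw budget exhausted at beat %d.", i),
            class = "stochpace_input_error")
    }
    out[i] <- x
  }
  out
}

#' Fit an ARMA input-output model to a stochastically paced beat series
#'
#' Least-squares identification of the memory model
#' `da_n = -sum_i alpha_i da_(n-i) + sum_i beta_i dt_(n-i)` (i = 1..M)
#' relating cycle-length deviations (input) to APD deviations (output),
#' where deviations are taken from the window mean (or from a best linear
#' trend for ramp windows). The poles of the identified transfer function
#' are the roots of the monic polynomial
#' `z^M + alpha_1 z^(M-1) + ... + alpha_M`; the pole closest to -1 estimates
#' the alternans eigenvalue.
#'
#' @param series a [beat_series()] (or data frame with `cl_ms`, `apd_ms`).
#' @param order memory depth `M` (number of previous cycles).
#' @param detrend `"mean"` or `"linear"` deviation convention.
#' @return Object of class `arma_fit`: `order`, `alpha`, `beta`,
#'   `resid_var_fraction` (residual variance / APD deviation variance),
#'   `n_cycles`, `poles`, `zeros`, `lambda_alt_hat`, `s_s1s2_hat`,
#'   `s_dyn_hat`, `detrend`, `condition_number`.
#' @export
fit_arma <- function(series, order = 3, detrend = c("mean", "linear")) {
  detrend <- match.arg(detrend)
  df <- as_beat_frame(series)
  M <- as.integer(order)
  n <- nrow(df)
  if (M < 1 || n < 10 * M) {
    abort(sprintf("Need order >= 1 and n >= 10 * order (n = %d, M = %d).",
                  n, M),
          class = "stochpace_input_error")
  }
  if (var(df$cl_ms) == 0) {
    abort("Constant pacing: cycle-length variance is zero.",
          class = "stochpace_input_error")
  }
  dev <- function(x) {
    if (detrend == "mean") return(x - mean(x))
    idx <- seq_along(x)
    x - stats::fitted(stats::lm(x ~ idx))
  }
  da <- dev(df$apd_ms)
  dt <- dev(df$cl_ms)
  idx <- (M + 1):n
  X <- cbind(
    sapply(seq_len(M), function(i) da[idx - i]),
    sapply(seq_len(M), function(i) dt[idx - i]))
  y <- da[idx]
  qr_x <- qr(X)
  if (qr_x$rank < ncol(X)) {
    abort(sprintf("Rank-deficient regression (rank %d < %d).",
                  qr_x$rank, ncol(X)),
          class = "stochpace_input_error")
  }
  cf <- qr.coef(qr_x, y)
  alpha <- -cf[seq_len(M)]
  beta <- cf[M + seq_len(M)]
  resid <- y - X %*% cf
  rvf <- if (var(y) > 0) as.numeric(var(resid) / var(y)) else 0
  poles <- polyroot(rev(c(1, alpha)))
  zeros <- if (any(abs(beta) > 0)) polyroot(rev(beta)) else complex(0)
  i_alt <- which.min(Mod(poles - (-1)))
  denom <- 1 + sum(alpha) - sum(beta)
  structure(
    list(order = M,
         alpha = unname(alpha), beta = unname(beta),
         resid_var_fraction = min(max(rvf, 0), 1),
         n_cycles = n,
         poles = poles, zeros = zeros,
         lambda_alt_hat = poles[i_alt],
         s_s1s2_hat = unname(beta[1]),
         s_dyn_hat = if (abs(denom) < 1e-10) Inf else sum(beta) / denom,
         s_dyn_infinite = abs(denom) < 1e-10,
         detrend = detrend,
         condition_number = kappa(qr_x$qr)),
    class = "arma_fit")
}

#' Transfer function of an identified ARMA model
#'
#' `H(z) = (beta_1 z^(M-1) + ... + beta_M) / (z^M + alpha_1 z^(M-1) + ... +
#' alpha_M)`; the DI transfer function follows via [complement_tf()].
#'
#' @param fit an [arma_fit][fit_arma], or a list with `alpha` and `beta`.
#' @return A `transfer_fn` (source `"arma"`).
#' @export
tf_from_arma <- function(fit) {
  alpha <- fit$alpha; beta <- fit$beta
  stopifnot(length(alpha) == length(beta))
  new_transfer_fn(num = trim_poly(beta), den = c(1, alpha), source = "arma")
}

#' Restitution slopes from an identified ARMA model
#'
#' `S_S1S2 = beta_1` (the one-beat gain) and
#' `S_dyn = sum(beta) / (1 + sum(alpha) - sum(beta))`, the steady-state
#' (z = 1) response ratio. The dynamic-slope estimate is flagged low
#' confidence: it depends on the transfer function at f = 0, where ARMA
#' identification from short stochastic-pacing records is least reliable.
#'
#' @inheritParams tf_from_arma
#' @return List with `s_s1s2`, `s_dyn`, `s_dyn_infinite`,
#'   `s_dyn_low_confidence = TRUE`.
#' @export
slopes_from_arma <- function(fit) {
  denom <- 1 + sum(fit$alpha) - sum(fit$beta)
  list(s_s1s2 = fit$beta[1],
       s_dyn = if (abs(denom) < 1e-10) Inf else sum(fit$beta) / denom,
       s_dyn_infinite = abs(denom) < 1e-10,
       s_dyn_low_confidence = TRUE)
}

#' Nonparametric DFT transfer-function estimate
#'
#' Estimates the cycle-length-to-APD (or DI) transfer function as the ratio
#' of discrete Fourier transforms of the mean-removed series at the Fourier
#' frequencies in `(0, 0.5]` beat^-1. With `blocks > 1` the series is split
#' into non-overlapping blocks and cross- and auto-spectra are averaged
#' (Welch-style) before the ratio.
#'
#' @param series a [beat_series()].
#' @param output `"apd"` or `"di"`.
#' @param blocks number of non-overlapping averaging blocks.
#' @return A `transfer_fn` with `source = "dft"` (fields `freqs`,
#'   `response`).
#' @export
dft_transfer <- function(series, output = c("apd", "di"), blocks = 1) {
  output <- match.arg(output)
  df <- as_beat_frame(series)
  n <- nrow(df)
  if (n < 64) {
    abort("Need at least 64 cycles for a DFT transfer estimate.",
          class = "stochpace_input_error")
  }
  if (var(df$cl_ms) == 0) {
    abort("Constant pacing: cycle-length variance is zero.",
          class = "stochpace_input_error")
  }
  y_all <- if (output == "apd") df$apd_ms else df$di_ms
  x_all <- df$cl_ms
  bl <- floor(n / blocks)
  cross <- pow <- 0
  for (b in seq_len(blocks)) {
    sel <- ((b - 1) * bl + 1):(b * bl)
    x <- x_all[sel] - mean(x_all[sel])
    y <- y_all[sel] - mean(y_all[sel])
    fx <- fft(x); fy <- fft(y)
    cross <- cross + fy * Conj(fx)
    pow <- pow + Mod(fx)^2
  }
  k <- seq_len(floor(bl / 2))
  h <- (cross / pow)[k + 1]
  new_transfer_fn(NULL, NULL, source = "dft",
                  poles = complex(0), zeros = complex(0),
                  freqs = k / bl, response = h)
}
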