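# analytic oracles used across the suite

# steady-state APD of the memoryless map a = f(bcl - a)
map1d_steady <- function(params, bcl) {
  f <- function(d) params$a_max - params$A * exp(-d / params$tau_f)
  uniroot(function(a) f(bcl - a) - a, c(1, bcl - 1e-6), tol = 1e-12)$root
}

map1d_slope <- function(params, d) (params$A / params$tau_f) * exp(-d / params$tau_f)

# BCL at which the memoryless map has restitution slope alpha
map1d_bcl_for_slope <- function(params, alpha) {
  d <- -params$tau_f * log(alpha * params$tau_f / params$A)
  a <- params$a_max - params$A * exp(-d / params$tau_f)
  a + d
}

# analytic onset BCL of the memoryless map (slope = 1)
map1d_onset <- function(params) map1d_bcl_for_slope(params, 1)

# hand-derived 2x2 Jacobian of the calcium-coupled map at state (a, l), cycle t
camap2d_jacobian <- function(p, state, t) {
  a <- state[1]; l <- state[2]
  d <- t - a
  q <- 1 / (1 + exp(-(l - p$l_c) / p$k_l))
  s <- 1 - p$kappa * exp(-d / p$tau_r)
  dq_dl <- q * (1 - q) / p$k_l
  ds_dd <- (p$kappa / p$tau_r) * exp(-d / p$tau_r)
  r <- l * q * s
  dr_da <- l * q * ds_dd * (-1)
  dr_dl <- q * s + l * dq_dl * s
  fprime <- (p$A / p$tau_f) * exp(-d / p$tau_f)
  u <- exp(-t / p$tau_up)
  matrix(c(-fprime + p$gamma * dr_da, p$gamma * dr_dl,
           -dr_da * u, (1 - dr_dl) * u),
         2, 2, byrow = TRUE)
}

# exact ARMA filtering of an arbitrary input deviation series
arma_filter <- function(alpha, beta, dt_series) {
  M <- length(alpha)
  n <- length(dt_series)
  da <- numeric(n)
  for (i in seq_len(n)) {
    for (k in seq_len(min(M, i - 1))) {
      da[i] <- da[i] - alpha[k] * da[i - k] + beta[k] * dt_series[i - k]
    }
  }
  da
}

expect_close <- function(actual, expected, tol) {
  expect_true(all(abs(actual - expected) <= tol),
              label = sprintf("max|diff| = %g (tol %g)",
                              max(abs(actual - expected)), tol))
}
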