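test_that("stochastic pacing series have the requested moments and guards", {
  expect_identical(gaussian_cl_series(400, 0, 5), rep(400, 5))
  x <- gaussian_cl_series(400, 5, 10000, seed = 11)
  expect_lt(abs(mean(x) - 400), 0.2)
  expect_lt(abs(sd(x) - 5), 0.15)
  expect_gte(min(x), 400 - 20)
  expect_identical(gaussian_cl_series(400, 5, 100, seed = 3),
                   gaussian_cl_series(400, 5, 100, seed = 3))
  # impossible DI guard exhausts the redraw budget
  expect_error(gaussian_cl_series(400, 1, 10, seed = 1, apd_ref = 399,
                                  min_di = 5),
               class = "stochpace_input_error")
})

test_that("a first-order fit recovers the pole of the linearized map", {
  m <- cell_model("map1d", tau_f = 100)
  bcl <- map1d_bcl_for_slope(m$params, 0.6)
  ss <- settle(m, bcl)
  for (seed in c(2, 5, 9)) {
    cls <- gaussian_cl_series(bcl, 5, 100, seed = seed, apd_ref = ss$apd_ms)
    fit <- fit_arma(run_beats(m, cls, state0 = ss$state)$series, order = 1)
    expect_lt(abs(Re(fit$lambda_alt_hat) - (-0.6)), 0.02)
    expect_lt(abs(fit$s_s1s2_hat - 0.6), 0.05)
  }
})

test_that("known ARMA(2) coefficients are recovered from synthetic series", {
  alpha <- c(-0.2, -0.35); beta <- c(0.3, 0.1)
  ser <- arma_process(alpha, beta, input_sd = 5, n = 2000, seed = 42)
  fit <- fit_arma(ser, order = 2)
  expect_close(fit$alpha, alpha, 0.03)
  expect_close(fit$beta, beta, 0.03)
  expect_close(sort(Re(fit$poles)), c(-0.5, 0.7), 0.05)
  expect_lt(fit$resid_var_fraction, 0.01)
})

test_that("degenerate identification inputs are rejected", {
  m <- cell_model("map1d", tau_f = 100)
  ser <- run_beats(m, rep(340, 50))$series
  expect_error(fit_arma(ser, order = 2), class = "stochpace_input_error")
  ser2 <- arma_process(c(0.5), c(0.5), n = 15, seed = 1)
  expect_error(fit_arma(ser2, order = 2), class = "stochpace_input_error")
})

test_that("the ARMA transfer function reproduces printed worked-example poles", {
  fit <- list(alpha = c(-0.2329, -0.7401, 0.0395),
              beta = c(0.1351, -0.1058, -0.0293))
  tf <- tf_from_arma(fit)
  expect_close(sort(Re(tf$poles)), c(-0.780, 0.053, 0.961), 5e-4)
  expect_close(Im(tf$poles), 0, 1e-9)
  # first-order case by construction
  tf1 <- tf_from_arma(list(alpha = 0.5, beta = 0.5))
  expect_close(tf1$num, 0.5, 1e-12)
  expect_close(tf1$den, c(1, 0.5), 1e-12)
})

test_that("slopes from ARMA coefficients reduce correctly", {
  for (a in c(0.4, 1)) {
    sl <- slopes_from_arma(list(alpha = a, beta = a))
    expect_equal(sl$s_s1s2, a)
    expect_equal(sl$s_dyn, a, tolerance = 1e-12)
  }
  sl0 <- slopes_from_arma(list(alpha = c(0.2, 0.1), beta = c(0, 0)))
  expect_equal(sl0$s_s1s2, 0)
  expect_equal(sl0$s_dyn, 0)
  expect_true(sl0$s_dyn_low_confidence)
})

test_that("DFT transfer estimate equals the rational response at a probed tone", {
  alpha <- 0.5; beta <- 0.3
  n <- 256
  dt <- 3 * sin(2 * pi * 0.25 * seq_len(n + 64))
  da <- arma_filter(alpha, beta, dt)
  keep <- 65:(64 + n)
  ser <- beat_series(400 + dt[keep], 200 + da[keep])
  tfd <- dft_transfer(ser)
  h_ref <- 0.3 / (exp(2i * pi * 0.25) + 0.5)
  h_hat <- tfd$response[which.min(abs(tfd$freqs - 0.25))]
  expect_lt(Mod(h_hat - h_ref) / Mod(h_ref), 0.01)
  expect_error(dft_transfer(ser[1:10, ]), class = "stochpace_input_error")
})

test_that("DFT and ARMA spectra agree on white-noise pacing", {
  ser <- arma_process(c(-0.2, -0.35), c(0.3, 0.1), input_sd = 5, n = 512,
                      seed = 7)
  tfd <- dft_transfer(ser, blocks = 4)
  tfa <- tf_from_arma(fit_arma(ser, order = 2))
  frd <- frequency_response(tfd)
  sel <- frd$f_per_beat >= 0.05
  ga <- frequency_response(tfa, frd$f_per_beat[sel])$gain_db
  expect_lt(median(abs(frd$gain_db[sel] - ga)), 1)
})

test_that("residual variance is tiny and does not improve beyond low orders", {
  mc <- cell_model("camap2d")
  ss <- settle(mc, 430)
  cls <- gaussian_cl_series(430, 5, 200, seed = 15, apd_ref = ss$apd_ms)
  ser <- run_beats(mc, cls, state0 = ss$state)$series
  f3 <- fit_arma(ser, order = 3)
  f6 <- fit_arma(ser, order = 6)
  expect_lt(f3$resid_var_fraction, 0.01)
  # deeper memory buys essentially nothing on a 2-variable system
  expect_gt(f6$resid_var_fraction, 0.9 * f3$resid_var_fraction - 1e-9)
})
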