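test_that("ramp protocol generates the requested cycle-length course", {
  m <- cell_model("map1d", tau_f = 100)
  r0 <- ramp_protocol(m, 340, -0.2, sd = 0, n = 100)
  expect_close(r0$cl_ms, 340 - 0.2 * (1:100), 1e-12)
  r1 <- ramp_protocol(m, 340, -0.2, sd = 1, n = 400, seed = 3)
  cf <- coef(lm(r1$cl_ms ~ r1$beat))
  expect_lt(abs(cf[2] - (-0.2)), 2 * 1 / sqrt(400))
  expect_identical(ramp_protocol(m, 340, -0.2, sd = 1, n = 50, seed = 5)$cl_ms,
                   ramp_protocol(m, 340, -0.2, sd = 1, n = 50, seed = 5)$cl_ms)
})

test_that("parameter drift scales the parameter from accumulated time", {
  m <- cell_model("map1d", tau_f = 100)
  dr <- parameter_drift_protocol(m, "tau_f", 0.002, bcl = 500, sd = 0,
                                 n = 201)
  # after 200 beats of 500 ms (100 s) at 0.2 %/s the scale is 0.80 exactly
  expect_equal(dr$param_scale[201], 0.8, tolerance = 1e-12)
  expect_error(parameter_drift_protocol(m, "nosuch", 0.002, bcl = 500),
               class = "stochpace_model_error")
  # zero rate reduces to stationary stochastic pacing
  dr0 <- parameter_drift_protocol(m, "tau_f", 0, bcl = 340, sd = 2, n = 50,
                                  seed = 8)
  expect_close(dr0$param_scale, 1, 1e-12)
})

test_that("windowed identification tracks a known stationary pole", {
  ser <- arma_process(c(0.7), c(0.5), input_sd = 5, n = 600, seed = 21)
  tr <- windowed_lambda(ser, window = 60, step = 30, order = 1)
  expect_lt(abs(mean(tr$lambda_alt) - (-0.7)), 0.05)
  mc <- cell_model("camap2d")
  ss <- settle(mc, 430)
  lam <- Re(eigen_summary(jacobian_pack(mc, 430, v_ss = ss$state))$lambda_alt)
  cls <- gaussian_cl_series(430, 5, 400, seed = 22, apd_ref = ss$apd_ms)
  serc <- run_beats(mc, cls, state0 = ss$state)$series
  trc <- windowed_lambda(serc, window = 50, step = 25, order = 3)
  expect_lt(abs(mean(trc$lambda_alt) - lam), 0.05)
  expect_error(windowed_lambda(ser, window = 1000),
               class = "stochpace_input_error")
})

test_that("onset extrapolation inverts an exact linear eigenvalue course", {
  bcl <- seq(350, 310, by = -5)
  track <- tibble::tibble(
    window_center_beat = seq_along(bcl) * 15,
    mean_bcl_ms = bcl,
    lambda_alt = -1 + 0.01 * (bcl - 300),
    lambda_alt_im = 0,
    s_s1s2 = 0.5)
  class(track) <- c("track_result", class(track))
  pred <- extrapolate_onset(track, predictor = "bcl")
  expect_equal(pred$onset, 300, tolerance = 1e-9)
  expect_s3_class(pred, "onset_prediction")

  # noisy replicates stay near the truth in most repetitions; with 7 points
  # above the cutoff and sd 0.01 the extrapolation SE is ~1.4 ms
  hits <- 0
  for (r in 1:20) {
    set.seed(100 + r)
    tr2 <- track
    tr2$lambda_alt <- track$lambda_alt + rnorm(nrow(track), 0, 0.01)
    on <- tryCatch(extrapolate_onset(tr2, "bcl")$onset,
                   error = function(e) NA)
    if (is.finite(on) && abs(on - 300) <= 3) hits <- hits + 1
  }
  expect_gte(hits, 18)

  # all points below the cutoff
  tr3 <- track
  tr3$lambda_alt <- rep(-0.95, nrow(track))
  expect_error(extrapolate_onset(tr3, "bcl"),
               class = "stochpace_input_error")
  # eigenvalue receding from -1 as the protocol progresses
  tr4 <- track
  tr4$lambda_alt <- -0.7 - 0.004 * (tr4$mean_bcl_ms - 300)
  expect_error(extrapolate_onset(tr4, "bcl"),
               class = "stochpace_no_approach")
})

test_that("step-decay fitting reads the alternans eigenvalue off a transient", {
  d <- 8 * 0.8^(1:40) * (-1)^(1:40)
  apd <- 200 + cumsum(d)
  est <- lambda_from_step_decay(apd)
  expect_equal(est$lambda, -0.8, tolerance = 1e-6)
  expect_gt(est$r_squared, 0.999)
  # monotone convergence carries no alternation
  expect_error(lambda_from_step_decay(200 + 10 * 0.9^(1:40)),
               class = "stochpace_no_alternation")
  # against the map linearization
  mp <- cell_model("camap2d")
  lam <- Re(eigen_summary(jacobian_pack(mp, 425,
    v_ss = settle(mp, 425, max_beats = 4000)$state))$lambda_alt)
  step_run <- run_beats(mp, rep(425, 60),
                        state0 = settle(mp, 440)$state)$series
  expect_lt(abs(lambda_from_step_decay(step_run)$lambda - lam), 0.02)
})

test_that("APD measurement noise is additive, seeded and identity-preserving", {
  ser <- arma_process(c(0.5), c(0.4), input_sd = 5, n = 10000, seed = 31)
  expect_identical(add_apd_noise(ser, 0), ser)
  n1 <- add_apd_noise(ser, 1, seed = 5)
  expect_identical(n1$apd_ms, add_apd_noise(ser, 1, seed = 5)$apd_ms)
  dev <- n1$apd_ms - ser$apd_ms
  expect_gt(sd(dev), 0.97)
  expect_lt(sd(dev), 1.03)
  expect_close(n1$cl_ms - n1$apd_ms - n1$di_ms, 0, 1e-12)
})
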