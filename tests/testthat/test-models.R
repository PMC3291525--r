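test_that("model construction validates kind and parameters", {
  expect_error(cell_model("nosuch"), class = "stochpace_model_error")
  expect_error(cell_model("map1d", foo = 1), class = "stochpace_model_error")
  expect_error(cell_model("map1d", a_max = NA_real_),
               class = "stochpace_model_error")
  m <- cell_model("map1d", a_max = 300, A = 150, tau_f = 100)
  expect_s3_class(m, "cell_model")
  expect_identical(m$state_dim, 1L)
  expect_identical(cell_model("camap2d")$state_dim, 2L)
})

test_that("one beat splits exactly into APD and DI at the map fixed point", {
  m <- cell_model("map1d", tau_f = 100)
  bcl <- 340
  a_star <- map1d_steady(m$params, bcl)
  res <- beat_update(m, a_star, bcl)
  expect_equal(res$apd, a_star)
  expect_equal(res$di, bcl - a_star)
  expect_equal(res$state, a_star, tolerance = 1e-12)
  # tightly settled calcium-map state maps to itself
  mc <- cell_model("camap2d")
  st <- settle(mc, 450, rel_tol = 1e-12, max_beats = 20000)
  nxt <- beat_update(mc, st$state, 450)
  expect_close(nxt$state, st$state, 1e-9 * max(abs(st$state)))
})

test_that("decoupled calcium map reproduces the memoryless map", {
  mc <- cell_model("camap2d", gamma = 0)
  m1 <- cell_model("map1d", tau_f = mc$params$tau_f)
  cls <- c(500, 480, 460, 470, 450, 455, 440, 445, 430, 450)
  a0 <- 180
  s2 <- run_beats(mc, cls, state0 = c(a0, 1.2))$series
  s1 <- run_beats(m1, cls, state0 = a0)$series
  expect_equal(s2$apd_ms, s1$apd_ms, tolerance = 1e-12)
})

test_that("run_beats is deterministic, conserves t = a + d, rejects bad input", {
  m <- cell_model("camap2d")
  cls <- seq(460, 420, length.out = 50)
  r1 <- run_beats(m, cls)
  r2 <- run_beats(m, cls)
  expect_identical(r1$series$apd_ms, r2$series$apd_ms)
  expect_close(r1$series$cl_ms - r1$series$apd_ms - r1$series$di_ms, 0, 1e-12)
  expect_error(run_beats(m, numeric(0)), class = "stochpace_input_error")
  expect_error(run_beats(m, c(400, -1)), class = "stochpace_input_error")
  # capture failure carries the failing beat index
  err <- tryCatch(run_beats(cell_model("map1d"), c(400, 150)),
                  stochpace_capture_error = function(e) e)
  expect_s3_class(err, "stochpace_capture_error")
  expect_identical(err$beat, 2L)
})

test_that("settle converges geometrically on a linear contraction map", {
  m <- cell_model("linear2d")  # x' = 0.5 x + b, contraction factor 0.5
  res <- settle(m, 400, rel_tol = 1e-7, max_beats = 1000, state0 = c(0, 0))
  expect_lte(res$beats, 30)
  expect_close(res$state, c(200, 0), 1e-4)
  expect_error(settle(m, 400, max_beats = 1, state0 = c(0, 0)),
               class = "stochpace_no_convergence")
})

test_that("settle signals the alternans regime with both states", {
  mc <- cell_model("camap2d")
  cond <- tryCatch(settle(mc, 395, max_beats = 4000),
                   stochpace_alternans = function(e) e)
  expect_s3_class(cond, "stochpace_alternans")
  expect_gt(abs(cond$apd_a - cond$apd_b), 1)
  # the two states map onto each other
  st1 <- beat_update(mc, cond$state_a, 395)$state
  expect_close(st1, cond$state_b, 1e-4 * max(abs(cond$state_b)))
})

test_that("ionic model produces one action potential per cycle with t = a + d", {
  ms <- cell_model("ms_ode")
  b <- beat_update(ms, init_state(ms), 500)
  expect_gt(b$apd, 150)
  expect_lt(b$apd, 350)
  expect_equal(b$apd + b$di, 500)
  expect_error(beat_update(ms, init_state(ms), 100),
               class = "stochpace_capture_error")
})

test_that("AP markers are located by interpolation on a synthetic trace", {
  # trapezoid: 0 -> 1 over t in [0, 4], plateau, 1 -> 0 over [200, 204];
  # up-crossing of 0.5 at t = 2, down-crossing of 0.05 at t = 203.8
  tt <- seq(0, 250, by = 0.5)
  v <- approx(c(0, 2, 4, 200, 204, 250), c(0, 0.5, 1, 1, 0, 0), xout = tt)$y
  mk <- measure_ap_markers(tt, v, up_thr = 0.5, down_thr = 0.05)
  expect_equal(mk$t_act, 2, tolerance = 1e-9)
  expect_equal(mk$apd, 203.8 - 2, tolerance = 1e-9)
  expect_error(measure_ap_markers(tt, rep(0, length(tt)), 0.5, 0.05),
               class = "stochpace_capture_error")
})

test_that("APD from refined sampling converges within one step", {
  ms <- cell_model("ms_ode")
  st <- settle(ms, 500)$state
  tr1 <- simulate_trace(ms, st, 500)
  ms2 <- cell_model("ms_ode", dt = 0.01, stim_amp = ms$params$stim_amp)
  tr2 <- simulate_trace(ms2, st, 500)
  a1 <- measure_ap_markers(tr1$time_ms, tr1$v, 0.5, 0.05)$apd
  a2 <- measure_ap_markers(tr2$time_ms, tr2$v, 0.5, 0.05)$apd
  expect_lt(abs(a1 - a2), 0.02)
})
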