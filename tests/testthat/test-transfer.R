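test_that("the memoryless map yields H_t>a = alpha/(z + alpha)", {
  m <- cell_model("map1d", tau_f = 100)
  bcl <- 340
  alpha <- map1d_slope(m$params, bcl - map1d_steady(m$params, bcl))
  tf <- tf_from_state_space(jacobian_pack(m, bcl))
  expect_close(tf$num, alpha, 1e-6)
  expect_close(tf$den, c(1, alpha), 1e-6)
  td <- complement_tf(tf)
  expect_close(td$num, c(1, 0), 1e-6)   # H_t>d = z/(z + alpha)
  expect_close(td$den, c(1, alpha), 1e-6)
})

test_that("state-space transfer functions match hand partial fractions", {
  # H = 0.1/(z - 0.9) + 0.2/(z + 0.8) = (0.3 z - 0.1)/(z^2 - 0.1 z - 0.72)
  J <- diag(c(0.9, -0.8))
  tf <- tf_from_state_space(J, a_vec = c(1, 1), vprime = c(0.1, 0.2))
  expect_close(tf$num, c(0.3, -0.1), 1e-10)
  expect_close(tf$den, c(1, -0.1, -0.72), 1e-10)
  expect_close(sort(Re(tf$poles)), c(-0.8, 0.9), 1e-10)
  # zero APD sensitivity nulls the transfer function
  tf0 <- tf_from_state_space(J, a_vec = c(0, 0), vprime = c(0.1, 0.2))
  expect_close(Mod(evaluate_tf(tf0, c(2 + 0i, -1.3 + 0.4i))), 0, 1e-12)
  sl0 <- restitution_slopes_from_tf(tf0)
  expect_equal(sl0$s_s1s2, 0)
  expect_equal(sl0$s_dyn, 0)
})

test_that("APD and DI transfer functions are complementary", {
  mc <- cell_model("camap2d")
  tf <- tf_from_state_space(jacobian_pack(mc, 440))
  td <- complement_tf(tf)
  set.seed(1)
  z <- complex(real = runif(10, -2, 2), imaginary = runif(10, -2, 2))
  expect_close(Mod(evaluate_tf(tf, z) + evaluate_tf(td, z) - 1), 0, 1e-12)
  # complement of the null transfer function is identity
  t1 <- complement_tf(tf_from_state_space(diag(c(0.5, -0.5)),
                                          c(0, 0), c(1, 1)))
  fr <- frequency_response(t1, c(0, 0.25, 0.5))
  expect_close(fr$gain_db, 0, 1e-10)
  expect_close(fr$phase_rad, 0, 1e-10)
})

test_that("frequency response matches analytic values on the unit circle", {
  tf <- tf_from_state_space(matrix(-0.5), 1, 0.5)  # H = 0.5/(z + 0.5)
  fr <- frequency_response(tf, c(0, 0.5))
  expect_equal(fr$gain_db[1], 20 * log10(1 / 3), tolerance = 1e-9)  # -9.54 dB
  expect_equal(fr$gain_db[2], 0, tolerance = 1e-9)                  # H(-1) = -1
  expect_equal(abs(fr$phase_rad[2] - fr$phase_rad[1]), pi, tolerance = 1e-9)
  expect_error(frequency_response(tf, 0.7), class = "stochpace_input_error")
  # pole on the unit circle flags infinite gain at the alternans frequency
  tf1 <- tf_from_state_space(matrix(-1), 1, 1)
  expect_true(frequency_response(tf1, 0.5)$infinite)
})

test_that("slopes from the transfer function reduce to the map slope", {
  for (alpha in c(0.3, 0.5, 1)) {
    tf <- tf_from_state_space(matrix(-alpha), 1, alpha)
    sl <- restitution_slopes_from_tf(tf)
    expect_equal(sl$s_s1s2, alpha, tolerance = 1e-12)
    expect_equal(sl$s_dyn, alpha, tolerance = 1e-12)
  }
  # at the period-doubling threshold the pole sits at -1
  tf1 <- tf_from_state_space(matrix(-1), 1, 1)
  expect_close(Re(tf1$poles), -1, 1e-12)
})

test_that("poles of eigen-derived transfer functions equal the Jacobian spectrum", {
  mc <- cell_model("camap2d")
  jp <- jacobian_pack(mc, 440)
  tf <- tf_from_state_space(jp)
  ev <- sort(Re(eigen(jp$J, only.values = TRUE)$values))
  expect_close(sort(Re(polyroot(rev(tf$den)))), ev, 1e-8)
  expect_close(sort(Re(tf$poles)), ev, 1e-8)
})

test_that("DI gain at the alternans frequency rises along a downsweep", {
  gain_half <- function(m, bcls) {
    vapply(bcls, function(b) {
      st <- settle(m, b, max_beats = 4000)
      td <- complement_tf(tf_from_state_space(jacobian_pack(m, b,
                                                            v_ss = st$state)))
      frequency_response(td, 0.5)$gain_db
    }, numeric(1))
  }
  g1 <- gain_half(cell_model("map1d", tau_f = 100), c(330, 300, 270, 250))
  expect_true(all(diff(g1) > 0))
  g2 <- gain_half(cell_model("camap2d", gamma = -30), c(520, 490, 460, 430))
  expect_true(all(diff(g2) > 0))
  g3 <- gain_half(cell_model("ms_ode"), c(370, 340, 315))
  expect_true(all(diff(g3) > 0))
})

test_that("a DI-transfer zero beyond -1 produces the -2pi APD phase signature", {
  # in this calcium-coupled map the zero z_td1 tracks lambda_alt and crosses
  # -1 for positive coupling near the bifurcation
  mp <- cell_model("camap2d", gamma = 30)
  st <- settle(mp, 420, max_beats = 4000)
  tf <- tf_from_state_space(jacobian_pack(mp, 420, v_ss = st$state))
  td <- complement_tf(tf)
  expect_lt(min(Re(td$zeros)), Re(td$poles[which.min(Re(td$poles))]))
  fr <- frequency_response(tf, seq(0, 0.5, by = 0.002))
  expect_equal(tail(fr$phase_rad, 1), -2 * pi, tolerance = 0.3)
  # the opposite sign stays on the -pi branch
  mn <- cell_model("camap2d", gamma = -30)
  stn <- settle(mn, 420, max_beats = 4000)
  tfn <- tf_from_state_space(jacobian_pack(mn, 420, v_ss = stn$state))
  frn <- frequency_response(tfn, seq(0, 0.5, by = 0.002))
  expect_equal(tail(frn$phase_rad, 1), -pi, tolerance = 0.3)
})
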