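test_that("sensor dynamics give a first-order lag with gain alpha", {
  p <- default_sensor
  # equilibrium: constant G with S = alpha * G
  expect_equal(sensor_dynamics(p$alpha * 100, 100, p), 0)
  # steady-state current at 100 mg/dL is 23 nA
  expect_equal(p$alpha * 100, 23)
  # 63% of the equilibrium change is reached at t = tau
  expect_equal(sensor_step_response(p$tau, p), 1 - exp(-1))
  sim <- simulate_sensor(function(t) if (t <= 0) 100 else 200,
                         duration = 40, p = p, noise = FALSE)
  frac <- (sim$raw$S - 23) / (p$alpha * 200 - 23)
  at_tau <- approx(sim$raw$t, frac, xout = p$tau)$y
  # within one raw sample of the analytic 63.2%
  one_sample <- abs(sensor_step_response(p$tau + 1 / 6, p) -
                    sensor_step_response(p$tau, p))
  expect_lt(abs(at_tau - (1 - exp(-1))), one_sample)
  expect_error(sensor_dynamics(0, 100, sensor_params(tau = -1)), "tau")
})

test_that("raw samples carry seeded Gaussian noise of the stated variance", {
  p <- default_sensor
  expect_identical(sample_raw(23, sensor_params(noise_variance = 0)), 23)
  set.seed(42)
  s <- sample_raw(rep(23, 1e5), p)
  expect_equal(var(s), 100, tolerance = 0.03)
  expect_equal(mean(s), 23, tolerance = 0.01)
  set.seed(7); a <- sample_raw(rep(23, 100), p)
  set.seed(7); b <- sample_raw(rep(23, 100), p)
  expect_identical(a, b)
})

test_that("readings are 5-min averages, saturated and correctly cadenced", {
  p <- default_sensor
  # constant current converts back through the gain
  r <- emit_reading(rep(23, 30), t = 5, p)
  expect_equal(r$G_est, 100)
  # saturation applies to the converted estimate
  r_hi <- emit_reading(rep(p$alpha * 500, 30), t = 5, p)
  expect_equal(r_hi$G_est, 400)
  r_lo <- emit_reading(rep(p$alpha * 10, 30), t = 5, p)
  expect_equal(r_lo$G_est, 40)
  expect_error(emit_reading(rep(23, 10), t = 5, p), "partial")
  # 288 readings per day; every reading equals G once equilibrated
  sim <- simulate_sensor(function(t) 100, duration = 1440, p = p,
                         noise = FALSE, S0 = 23)
  expect_identical(nrow(sim$readings), 288L)
  expect_true(all(abs(sim$readings$G_est - 100) < 1e-9))
  expect_true(all(sim$readings$G_est >= 40 & sim$readings$G_est <= 400))
})

test_that("a slow sinusoid is recovered with an effective lag close to tau", {
  p <- default_sensor
  period <- 240
  g_fun <- function(t) 100 + 20 * sin(2 * pi * t / period)
  sim <- simulate_sensor(g_fun, duration = 960, p = p, noise = FALSE)
  g_rec <- sim$raw$S / p$alpha
  tt <- sim$raw$t
  # lag maximizing agreement with the shifted true signal
  lags <- seq(4, 8, by = 1 / 6)
  rss <- vapply(lags, function(L)
    sum((g_rec[tt > 100] - g_fun(tt[tt > 100] - L))^2), numeric(1))
  best <- lags[which.min(rss)]
  # phase lag of a first-order filter at this frequency
  expected <- atan(2 * pi / period * p$tau) / (2 * pi / period)
  expect_lt(abs(best - expected), 1 / 6 + 1e-9)
  expect_lt(abs(best - p$tau), 0.5)
})

test_that("a nonzero transport lag delays the step response", {
  p <- sensor_params(T_D = 2)
  sim <- simulate_sensor(function(t) if (t <= 0) 100 else 200,
                         duration = 40, p = p, noise = FALSE)
  frac <- (sim$raw$S - 23) / (p$alpha * 200 - 23)
  # essentially no response before the transport lag has elapsed
  expect_lt(max(frac[sim$raw$t <= p$T_D]), 0.05)
  at <- approx(sim$raw$t, frac, xout = p$T_D + p$tau)$y
  expect_equal(at, 1 - exp(-1), tolerance = 0.05)
})
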