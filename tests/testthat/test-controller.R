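test_that("trend aggregate A is a zero-sum per-minute trend estimate", {
  p <- default_controller
  expect_equal(p$a0 + p$a5 + p$a10, 0)
  expect_identical(diff_parameter_A(glucose_history(100, 100, 100), p), 0)
  # rising 1 mg/dL per minute
  a_up <- diff_parameter_A(glucose_history(110, 105, 100), p)
  expect_gt(a_up, 0)
  expect_equal(a_up, 1)  # backward-difference per-minute trend
  # reversing the trend flips the sign exactly
  a_dn <- diff_parameter_A(glucose_history(100, 105, 110), p)
  expect_equal(a_dn, -a_up)
  # warm-up: missing history gives zero
  expect_identical(diff_parameter_A(glucose_history(100, NA, NA), p), 0)
  expect_error(controller_params(a0 = 0.5, a5 = -0.4, a10 = 0.1),
               "sum to zero")
})

test_that("differential factor is odd, zero at zero, K2-gained for small A", {
  p <- default_controller
  expect_identical(diff_factor_DF(0, p), 0)
  for (A in c(0.1, 0.5, 1, 3, 10))
    expect_equal(diff_factor_DF(-A, p), -diff_factor_DF(A, p))
  # small-trend gain governed by K2 = 10
  expect_equal(diff_factor_DF(0.01, p) / 0.01, p$K2, tolerance = 1e-3)
  # |DF| increases with |A| for small A
  small <- seq(0, 1, by = 0.1)
  expect_true(all(diff(vapply(small, diff_factor_DF, numeric(1), p = p)) > 0))
  # bounded: never exceeds K2 / (2 sqrt(K1))
  big <- seq(-100, 100, by = 0.5)
  expect_true(all(abs(vapply(big, diff_factor_DF, numeric(1), p = p)) <=
                    p$K2 / (2 * sqrt(p$K1)) + 1e-12))
})

test_that("tanh insulin law hits half-maximum at B and saturates", {
  p <- default_controller
  expect_equal(insulin_infusion_law(p$B, 0, p), p$M / 2)
  expect_equal(insulin_infusion_law(p$B - 10, 10, p), p$M / 2)
  expect_lt(insulin_infusion_law(-1000 + p$B, 0, p), 1e-6)
  expect_gt(insulin_infusion_law(1000 + p$B, 0, p), p$M - 1e-6)
  # strictly increasing in G0 and DF
  g <- seq(60, 250, by = 5)
  expect_true(all(diff(vapply(g, insulin_infusion_law,
                              numeric(1), DF = 0, p = p)) > 0))
  expect_gt(insulin_infusion_law(120, 5, p), insulin_infusion_law(120, -5, p))
})

test_that("glucose rescue law is threshold-linear with gain K_G", {
  p <- default_controller
  expect_identical(glucose_infusion_law(100, p), 0)
  expect_identical(glucose_infusion_law(p$G_crit, p), 0)
  p2 <- controller_params(K_G = 2)
  expect_equal(glucose_infusion_law(50, p2), 20)
})

test_that("emergency logic switches the two pumps exclusively", {
  p <- default_controller
  em <- emergency_logic(55, 100, glucose_infusion_law(55, p), p)
  expect_true(em$emergency_active)
  expect_equal(em$IR, p$IR_min)
  expect_gt(em$GR, 0)
  ok <- emergency_logic(100, 100, 0, p)
  expect_false(ok$emergency_active)
  expect_equal(ok$IR, 100)
  expect_identical(ok$GR, 0)
  # recovery: crossing G_crit upward disables the glucose line
  hist <- glucose_history()
  seqs <- c(70, 55, 58, 62, 80)
  states <- logical(length(seqs))
  for (i in seq_along(seqs)) {
    cs <- controller_step(list(t = 5 * i, G_est = seqs[i]), hist, p)
    hist <- cs$history
    states[i] <- cs$output$emergency_active
    if (seqs[i] >= p$G_crit) expect_identical(cs$output$GR, 0)
  }
  expect_identical(states, c(FALSE, TRUE, TRUE, FALSE, FALSE))
})

test_that("controller step composes trend, DF and the tanh law", {
  p <- default_controller
  hist <- glucose_history()
  # warm-up: first two steps are purely proportional (A = 0)
  s1 <- controller_step(list(t = 5, G_est = 100), hist, p)
  s2 <- controller_step(list(t = 10, G_est = 105), s1$history, p)
  expect_identical(s1$output$A, 0)
  expect_identical(s2$output$A, 0)
  s3 <- controller_step(list(t = 15, G_est = 110), s2$history, p)
  expect_gt(s3$output$A, 0)
  # rising readings command strictly more insulin at each step
  hist <- glucose_history()
  irs <- numeric(3)
  for (i in seq_along(c(100, 130, 160))) {
    cs <- controller_step(list(t = 5 * i, G_est = c(100, 130, 160)[i]),
                          hist, p)
    hist <- cs$history
    irs[i] <- cs$output$IR
  }
  expect_true(all(diff(irs) > 0))
  # out-of-order timestamps are a sequencing error
  expect_error(controller_step(list(t = 5 * 2, G_est = 100), hist, p),
               "sequencing")
})

test_that("zeroed trend coefficients reduce to a pure proportional law", {
  p <- controller_params(a0 = 0, a5 = 0, a10 = 0)
  hist <- glucose_history()
  t <- 0
  for (g in c(100, 140, 95, 170)) {
    t <- t + 5
    cs <- controller_step(list(t = t, G_est = g), hist, p)
    hist <- cs$history
    expect_identical(cs$output$DF, 0)
    expect_equal(cs$output$IR_prime, insulin_infusion_law(g, 0, p))
  }
})

test_that("controller outputs respect bounds at every step of a noisy run", {
  res <- challenge_runs("severe")[[1]]
  tr <- res$trace
  p <- default_controller
  expect_true(all(tr$IR_mIU >= p$IR_min - 1e-9))
  expect_true(all(tr$IR_mIU <= p$M + 1e-9))
  expect_true(all(tr$GR_mLh >= 0))
  # glucose delivery only when the triggering reading was hypoglycemic
  expect_true(all(tr$G_est[tr$GR_mLh > 0] < p$G_crit))
  expect_identical(tr$emergency == 1, tr$G_est < p$G_crit)
})
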