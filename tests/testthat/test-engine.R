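test_that("unchallenged noise-free loop holds the band at the fixed point", {
  res <- run_closed_loop(scn = scenario(list(), duration = 720, name = "none"),
                         seed = 1, noise = FALSE)
  g <- res$series$G[res$series$t > 120]
  expect_true(all(g >= 90 & g <= 120))
  expect_equal(mean(g), 100, tolerance = 0.01)
  expect_identical(res$n_clipped, 0L)
})

test_that("a 24-h run emits one reading per 5 minutes and holds rates between", {
  res <- challenge_runs("mild")[[1]]
  expect_identical(nrow(res$trace), 288L)
  expect_equal(res$trace$t, seq(5, 1440, by = 5))
  # pump rate changes only at controller boundaries
  s <- res$series
  changes <- which(diff(s$IR_mLh) != 0)
  off <- s$t[changes + 1] %% 5
  expect_true(all(pmin(off, 5 - off) < 1e-6))
})

test_that("identical seeds reproduce the whole result bit-for-bit", {
  a <- run_closed_loop(scn = build_scenario("severe"), seed = 101)
  b <- run_closed_loop(scn = build_scenario("severe"), seed = 101)
  expect_identical(a$series, b$series)
  expect_identical(a$trace, b$trace)
  expect_identical(unclass(a$metrics), unclass(b$metrics))
  d <- run_closed_loop(scn = build_scenario("severe"), seed = 102)
  expect_false(identical(a$series$G, d$series$G))
})

test_that("halving the step changes the 24-h trajectory negligibly", {
  a <- run_closed_loop(scn = build_scenario("mild"), seed = 1, noise = FALSE,
                       dt = 1 / 12)
  b <- run_closed_loop(scn = build_scenario("mild"), seed = 1, noise = FALSE,
                       dt = 1 / 24)
  ga <- a$series$G
  gb <- b$series$G[seq(1, nrow(b$series), by = 2)]
  expect_lt(max(abs(ga - gb)), 0.5)
})

test_that("explicit-Euler reference engine matches the compiled integrator", {
  scn <- scenario(list(challenge_event("meal_complex_CHO", 60, 50)),
                  duration = 360, name = "mild6h")
  prod <- run_closed_loop(scn = scn, seed = 1, noise = FALSE)
  ref <- run_closed_loop_reference(scn = scn, dt = 1 / 120, noise = FALSE)
  # compare on the coarser production grid
  g_ref <- approx(ref$series$t, ref$series$G, xout = prod$series$t)$y
  expect_lt(max(abs(prod$series$G - g_ref)), 0.1)
})

test_that("the controller measurably shortens the hyperglycemic excursion", {
  active <- run_closed_loop(scn = build_scenario("severe"), seed = 3)
  # frozen-at-basal controller: tanh flattened around the KVO rate
  frozen <- controller_params(M = 2 * 1000 / 60 + 1e-6, S_slope = 1e-9,
                              B = 153)
  passive <- run_closed_loop(controller = frozen,
                             scn = build_scenario("severe"), seed = 3)
  expect_gt(passive$metrics$overshoot_duration,
            active$metrics$overshoot_duration)
})

test_that("insulin line never stops across a severe day", {
  for (res in challenge_runs("severe")[1:3]) {
    expect_true(all(res$series$IR_mLh >= 1.0 - 1e-9))
    expect_true(all(res$trace$IR_mIU > 0))
  }
})

test_that("sweeps are reproducible and summarized per cell", {
  sw1 <- sweep_table(weights = 70, sh_values = c(0.3, 0.7), kinds = "severe",
                     replicates = 3, seed = 5)
  sw2 <- sweep_table(weights = 70, sh_values = c(0.3, 0.7), kinds = "severe",
                     replicates = 3, seed = 5)
  expect_identical(sw1$runs, sw2$runs)
  expect_identical(nrow(sw1$runs), 6L)
  expect_identical(nrow(sw1$summary), 2L)
  expect_true(all(c("overshoot_peak", "settling_time_Ts",
                    "any_undershoot") %in% names(sw1$summary)))
})

test_that("late noise-free recovery is free of sustained oscillation", {
  for (kind in c("mild", "severe")) {
    res <- run_closed_loop(scn = build_scenario(kind), seed = 1, noise = FALSE)
    tail4h <- res$series$G[res$series$t > 1200]
    expect_lt(sd(tail4h), 10)
    expect_true(all(is.finite(res$series$G)))
  }
})
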