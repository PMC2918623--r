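test_that("gastric emptying conserves mass and follows a symmetric profile", {
  p <- default_patient
  ev <- challenge_event("oral_glucose", t_start = 0, amount = 50)
  # no pending meal
  st <- patient_state(t = 100)
  expect_identical(gastric_emptying_flux(st, NULL, p), 0)
  # before the meal starts
  ev_late <- challenge_event("oral_glucose", t_start = 200, amount = 50)
  expect_identical(gastric_emptying_flux(st, ev_late, p), 0)

  # numeric integration oracle of the configured profile
  tt <- seq(0, 600, by = 0.01)
  flux <- vapply(tt, function(ti)
    gastric_emptying_flux(patient_state(t = ti), ev, p), numeric(1))
  expect_true(all(flux >= 0))
  total <- sum(flux) * 0.01
  expect_equal(total, 50000, tolerance = 1e-3)
  # symmetric trapezoid: half the mass is emptied by the profile midpoint
  prof_end <- tt[max(which(flux > 0))] + 0.01
  half_mass <- cumsum(flux)[findInterval(prof_end / 2, tt)] * 0.01
  expect_equal(half_mass, 25000, tolerance = 1e-2)

  # complex-CHO meals empty at half the plateau rate
  ev_meal <- challenge_event("meal_complex_CHO", t_start = 0, amount = 50)
  st_mid <- patient_state(t = 30)
  expect_equal(gastric_emptying_flux(st_mid, ev_meal, p),
               p$gut$emptying_vmax * p$gut$meal_slowdown)

  expect_error(challenge_event("oral_glucose", 0, -5), "amount")
})

test_that("gut absorption is saturating, zero on empty gut, and lossless", {
  p <- default_patient
  expect_identical(gut_absorption(patient_state(Ggut = 0), p), 0)
  vg <- p$glucose_dist_volume * p$body_weight
  # saturating level approaches the configured maximum rate
  g_in_sat <- gut_absorption(patient_state(Ggut = 1e9), p)
  expect_equal(g_in_sat, 60 * p$gut$absorption_vmax / vg, tolerance = 1e-4)
  # conservation: stomach -> gut -> blood, integrated to emptiness
  ev <- challenge_event("oral_glucose", t_start = 0, amount = 50)
  dt <- 0.05; tt <- seq(0, 1440, by = dt)
  ggut <- 0; absorbed <- 0
  for (ti in tt) {
    ge <- gastric_emptying_flux(patient_state(t = ti), ev, p)
    ab <- aiisim:::gut_absorption_mass(ggut, p)
    ggut <- max(ggut + dt * (ge - ab), 0)
    absorbed <- absorbed + dt * ab
  }
  expect_equal(absorbed + ggut, 50000, tolerance = 1e-3)
  expect_lt(ggut / 50000, 0.001)  # gut effectively empty within 24 h
})

test_that("peripheral utilization is linear in insulin with slope c*Sp", {
  p <- default_patient
  u0 <- peripheral_utilization(100, 0, p)
  expect_equal(u0, p$insulin_independent_util)  # insulin-independent only
  # constant incremental slope governed by c = 0.045
  d1 <- peripheral_utilization(100, 11, p) - peripheral_utilization(100, 10, p)
  d2 <- peripheral_utilization(100, 51, p) - peripheral_utilization(100, 50, p)
  expect_equal(d1, d2)
  expect_equal(d1, 60 * 0.045 * p$Sp, tolerance = 1e-10)
  # doubling Sp doubles the insulin-dependent component
  p2 <- p; p2$Sp <- p$Sp / 2
  p2 <- aiisim:::validate_patient(unclass(p2))
  dep_full <- peripheral_utilization(100, 20, p) - u0
  dep_half <- peripheral_utilization(100, 20, p2) - u0
  expect_equal(dep_full, 2 * dep_half)
  # monotone non-decreasing in both arguments
  gs <- seq(20, 300, by = 20)
  expect_true(all(diff(vapply(gs, peripheral_utilization,
                              numeric(1), I_eq = 30, p = p)) >= 0))
  is <- seq(0, 200, by = 10)
  expect_true(all(diff(vapply(is, function(i)
    peripheral_utilization(120, i, p), numeric(1))) >= 0))
})

test_that("net hepatic glucose balance is monotone and bounded", {
  p <- default_patient
  w <- p$body_weight
  # table endpoints: max production at zero insulin, net uptake at high insulin
  expect_equal(net_hepatic_glucose_balance(100, 0, p), 180 * w)
  expect_lt(net_hepatic_glucose_balance(100, 500, p), 0)
  # increasing Sh never increases NHGB at identical plasma insulin
  p03 <- p; p03$Sh <- 0.3; p03 <- aiisim:::validate_patient(unclass(p03))
  p07 <- p; p07$Sh <- 0.7; p07 <- aiisim:::validate_patient(unclass(p07))
  for (I in c(5, 20, 60, 150))
    expect_gte(net_hepatic_glucose_balance(100, I, p03),
               net_hepatic_glucose_balance(100, I, p07))
  # monotone non-increasing in glucose (above the hypo-override region)
  gs <- seq(90, 300, by = 10)
  vals <- vapply(gs, net_hepatic_glucose_balance, numeric(1), I = 30, p = p)
  expect_true(all(diff(vals) <= 1e-9))
  # bounded by the configured limits
  expect_lte(max(vals) / w, p$nhgb_max)
  expect_gte(min(vals) / w, p$nhgb_min)
})

test_that("renal excretion is a threshold-linear function of glycemia", {
  p <- default_patient
  expect_identical(renal_excretion(100, p), 0)
  expect_identical(renal_excretion(p$renal_threshold, p), 0)
  d <- 15
  one <- renal_excretion(p$renal_threshold + d, p)
  two <- renal_excretion(p$renal_threshold + 2 * d, p)
  expect_equal(two, 2 * one)
  expect_equal(one, 60 * p$renal_clearance * d)
})

test_that("insulin kinetics follow linear PK with a lagging active pool", {
  p <- default_patient
  vi <- p$insulin_dist_volume * p$body_weight
  # zero infusion from zero stays at zero
  st <- patient_state(G = 100, I = 0, Ia = 0)
  k <- insulin_kinetics(st, 0, 0, p)
  expect_identical(k$dI, 0)
  # steady state I = R / (k_el * V_I), simulated from the ODE
  R <- 25
  st <- patient_state(G = 100, I = 0, Ia = 0)
  dt <- 0.05
  I <- 0; Ia <- 0
  for (i in seq_len(round(240 / dt))) {
    kk <- insulin_kinetics(patient_state(G = 100, I = I, Ia = Ia), R, 0, p)
    I <- I + dt * kk$dI; Ia <- Ia + dt * kk$dIa
  }
  expect_equal(I, R / (p$insulin_elim_rate * vi), tolerance = 0.01)
  # active pool converges to (build/decay) * I, i.e. tracks plasma insulin
  expect_equal(Ia, I, tolerance = 0.01)
  # calibrated basal: 1.0 IU/h holds plasma insulin near 20 uIU/mL
  expect_equal(basal_plasma_insulin(p, 1000 / 60), 20, tolerance = 0.25)
})

test_that("IV insulin bolus follows the closed-form two-compartment response", {
  m <- bolus_insulin_model()
  expect_equal(iv_insulin_bolus(10, 1e6, m), 0, tolerance = 1e-10)
  # initial concentration is dose / V1
  expect_equal(iv_insulin_bolus(10, 0, m), 10 * 1000 / m$V1)
  # AUC equals dose / (k_el * V1); numeric integration oracle
  tt <- seq(0, 2000, by = 0.01)
  auc <- sum(iv_insulin_bolus(10, tt, m)) * 0.01
  expect_equal(auc, 10 * 1000 / (m$k_el * m$V1), tolerance = 1e-3)
  # a 10 IU bolus into the default patient peaks near 3300 uIU/mL
  p <- default_patient
  v1 <- p$bolus_model$V1_per_kg * p$body_weight
  expect_equal(10 * 1000 / v1, 3333, tolerance = 0.01)
})

test_that("glucose balance assembles fluxes with consistent units", {
  p <- default_patient
  st <- patient_state(G = 100)
  vg <- p$glucose_dist_volume * p$body_weight
  expect_identical(glucose_balance(st, 0, 0, 0, 0, 0, p), 0)
  # exact balance gives zero derivative
  gout <- 120  # mg/kg/h
  nhgb <- gout * p$body_weight  # mg/h
  expect_equal(glucose_balance(st, 0, nhgb, gout, 0, 0, p), 0)
  # uncompensated IV bolus of 10 g raises G by 10000 / V_g
  rate <- 10000 / 0.5  # mg/min over 30 s
  dGdt_h <- glucose_balance(st, 0, 0, 0, 0, rate, p)
  expect_equal(dGdt_h / 60 * 0.5, 10000 / vg)
})

test_that("single patient step matches linear closed forms and guards state", {
  p <- default_patient
  # I decay matches the analytic exponential to 1e-6 at dt = 0.1 min
  st <- patient_state(G = 100, I = 50, Ia = 50)
  stepped <- patient_step(st, list(), 0.1, p)
  expect_equal(stepped[["I"]], 50 * exp(-p$insulin_elim_rate * 0.1),
               tolerance = 1e-6)
  # basal fixed point leaves glycemia essentially unchanged
  I0 <- basal_plasma_insulin(p, 1000 / 60)
  st0 <- patient_state(G = 100, I = I0, Ia = I0)
  adv <- patient_step(st0, list(insulin_mIU_min = 1000 / 60), 1, p)
  expect_equal(adv[["G"]], 100, tolerance = 1e-6)
  # non-finite states are reported with the offending variable
  bad <- patient_state(G = 100); bad[["I"]] <- Inf
  expect_error(patient_step(bad, list(), 0.1, p), "non-finite")
})
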