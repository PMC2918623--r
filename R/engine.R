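# Orchestration of patient + sensor + controller + pumps over a scenario.

# Assemble the flat parameter list consumed by the compiled core.
engine_par <- function(patient, sensor, controller, pumps) {
  list(
    w = patient$body_weight, Sh = patient$Sh, Sp = patient$Sp, c = patient$c,
    renal_thr = patient$renal_threshold, renal_cl = patient$renal_clearance,
    vg = patient$glucose_dist_volume * patient$body_weight,
    vi = patient$insulin_dist_volume * patient$body_weight,
    ke = patient$insulin_elim_rate,
    ka_build = patient$active_insulin_rates[["build"]],
    ka_decay = patient$active_insulin_rates[["decay"]],
    ka_sat = patient$active_insulin_sat,
    u_ii = patient$insulin_independent_util,
    util_km = patient$util_km, util_gref = patient$util_gref,
    nhgb_gslope = patient$nhgb_glucose_slope,
    nhgb_min = patient$nhgb_min, nhgb_max = patient$nhgb_max,
    nhgb_hypo_thr = patient$nhgb_hypo_threshold,
    nhgb_hypo_slope = patient$nhgb_hypo_slope,
    nhgb_hypo_ins_sup = patient$nhgb_hypo_insulin_sup,
    abs_vmax = patient$gut$absorption_vmax, abs_km = patient$gut$absorption_km,
    bol_k12 = patient$bolus_model$k12, bol_k21 = patient$bolus_model$k21,
    bol_kel = patient$bolus_model$k_el,
    bol_v1 = patient$bolus_model$V1_per_kg * patient$body_weight,
    alpha = sensor$alpha, tau = sensor$tau,
    sat_lo = sensor$sat_low, sat_hi = sensor$sat_high,
    M = controller$M, S_slope = controller$S_slope, B = controller$B,
    K1 = controller$K1, K2 = controller$K2,
    a0 = controller$a0, a5 = controller$a5, a10 = controller$a10,
    IR_min = controller$IR_min, G_crit = controller$G_crit,
    K_G = controller$K_G,
    ins_min = pumps$insulin$rate_min, ins_max = pumps$insulin$rate_max,
    ins_step = pumps$insulin$rate_step, ins_kvo = pumps$insulin$kvo_rate,
    ins_conc = pumps$insulin$concentration,
    glc_min = pumps$glucose$rate_min, glc_max = pumps$glucose$rate_max,
    glc_step = pumps$glucose$rate_step, glc_kvo = pumps$glucose$kvo_rate,
    glc_conc = pumps$glucose$concentration
  )
}

# Encode scenario events for the compiled core.  Oral events carry the
# trapezoidal profile breakpoints relative to t_start; IV events carry an
# absolute administration window, degenerating to an impulse when shorter
# than one integration step.
engine_events <- function(scn, patient, dt) {
  lapply(scn$events, function(e) {
    dur_min <- e$duration / 60
    if (e$kind %in% c("meal_complex_CHO", "oral_glucose")) {
      prof <- gastric_profile(e, patient)
      list(kind = 1L, t_start = prof$t0, t_end = prof$t_end,
           slope = prof$slope, vmax = prof$vmax, t_up = prof$t_up,
           t_down = prof$t_down_start)
    } else if (e$kind == "iv_glucose_bolus") {
      if (dur_min < dt) {
        list(kind = 5L, t_start = e$t_start, t_end = e$t_start,
             amount = e$amount * 1000)
      } else {
        list(kind = 3L, t_start = e$t_start, t_end = e$t_start + dur_min,
             rate = e$amount * 1000 / dur_min)
      }
    } else {  # iv_insulin_bolus, dose in IU -> mIU
      if (dur_min < dt) {
        list(kind = 6L, t_start = e$t_start, t_end = e$t_start,
             amount = e$amount * 1000)
      } else {
        list(kind = 4L, t_start = e$t_start, t_end = e$t_start + dur_min,
             rate = e$amount * 1000 / dur_min)
      }
    }
  })
}

# Draw the sensor-noise stream for a run without disturbing the caller's
# RNG state.
draw_sensor_noise <- function(n, variance, seed) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  rnorm(n, 0, sqrt(variance))
}

# Basal initial state: closed-loop fixed point of the calibrated system.
basal_state <- function(patient, sensor, controller, pumps) {
  kvo_mIU <- delivered_dose(pumps$insulin$kvo_rate, pumps$insulin)
  I0 <- basal_plasma_insulin(patient, kvo_mIU)
  Ia0 <- I0 * patient$active_insulin_rates[["build"]] /
    patient$active_insulin_rates[["decay"]]
  c(G = controller$G_ref, I = I0, Ia = Ia0, Ggut = 0,
    S = sensor$alpha * controller$G_ref, B1 = 0, B2 = 0)
}

#' Run the closed loop over a scenario
#'
#' Integrates the virtual patient together with the sensor current using
#' fixed-step RK4, samples the noisy sensor current every 10 s, emits a
#' 5-minute averaged reading, executes the PD controller on each reading
#' and holds the quantized pump rates until the next one.  The run starts
#' at the calibrated basal fixed point; the pre-challenge span of the
#' scenario acts as closed-loop warm-up.
#'
#' @param patient [patient_params()].
#' @param sensor [sensor_params()].
#' @param controller [controller_params()].
#' @param pumps List with elements `insulin` and `glucose`, each a
#'   [pump_spec()].
#' @param scn An [scenario()] or [build_scenario()] result.
#' @param seed Integer seed for the sensor-noise stream.  The global RNG
#'   state of the session is left untouched.
#' @param dt Integration step, min.  Must divide the raw sampling period.
#' @param noise Set `FALSE` to disable sensor noise (deterministic run).
#' @return An object of class `aiis_result`: list with `series` (data
#'   frame: `t`, `G`, `I`, `Ia`, `Ggut`, `S`, `I_plasma`, `IR_mLh`,
#'   `GR_mLh` at every step), `trace` (one row per controller execution:
#'   `t`, `G_est`, `A`, `DF`, `IR_prime_mIU`, `IR_mIU`, `GR_prime_mLh`,
#'   `GR_mLh`, `emergency`, `IR_mLh`), `metrics`
#'   ([compute_metrics()] from the challenge time), `n_clipped`, `seed`,
#'   and `config` (the full parameter snapshot).
#' @examples
#' \donttest{
#' res <- run_closed_loop(scn = build_scenario("severe"), seed = 1)
#' res$metrics
#' }
#' @export
run_closed_loop <- function(patient = patient_params(),
                            sensor = sensor_params(),
                            controller = controller_params(),
                            pumps = default_pumps(),
                            scn = build_scenario("mild"),
                            seed = 1L, dt = 1 / 12, noise = TRUE) {
  sp_min <- sensor$sample_period / 60
  steps_per_sample <- sp_min / dt
  if (abs(steps_per_sample - round(steps_per_sample)) > 1e-9)
    stop("dt must divide the raw sampling period")
  steps_per_sample <- as.integer(round(steps_per_sample))
  steps_per_reading <- as.integer(round(sensor$averaging_window / dt))
  n_steps <- round(scn$duration / dt)
  n_samples <- n_steps %/% steps_per_sample

  eps <- if (isFALSE(noise) || sensor$noise_variance == 0) numeric(n_samples)
         else draw_sensor_noise(n_samples, sensor$noise_variance, seed)

  par <- engine_par(patient, sensor, controller, pumps)
  ev <- engine_events(scn, patient, dt)
  y0 <- basal_state(patient, sensor, controller, pumps)

  out <- cpp_run_closed_loop(
    unname(y0), par, ev,
    patient$nhgb_table$ieff, patient$nhgb_table$nhgb,
    eps, scn$duration, dt, steps_per_sample, steps_per_reading,
    sensor$T_D, pumps$insulin$kvo_rate, 0.0)

  series <- as.data.frame(out$series)
  trace <- as.data.frame(out$trace)
  challenge_t <- if (length(scn$events)) scn$events[[1]]$t_start else 0
  metrics <- compute_metrics(series[, c("t", "G")], challenge_t,
                             band_low = controller$band_low,
                             band_high = controller$band_high)
  structure(list(series = series, trace = trace, metrics = metrics,
                 n_clipped = out$n_clipped, seed = seed,
                 challenge_t = challenge_t, scenario = scn$name,
                 config = list(patient = unclass(patient),
                               sensor = unclass(sensor),
                               controller = unclass(controller),
                               pumps = lapply(pumps, unclass),
                               engine = list(dt = dt,
                                             duration = scn$duration))),
            class = "aiis_result")
}

#' Default pair of infusion pumps
#'
#' Insulin at 1 IU/mL and 50% dextrose (500 mg/mL), both with the
#' 1.0--500 mL/h range, 0.1 mL/h steps and a 1.0 mL/h KVO floor.
#' @return List with [pump_spec()] elements `insulin` and `glucose`.
#' @export
default_pumps <- function() {
  d <- aiis_defaults()$pumps
  list(insulin = do.call(pump_spec, d$insulin),
       glucose = do.call(pump_spec, d$glucose))
}

#' @export
print.aiis_result <- function(x, ...) {
  cat(sprintf("Closed-loop run: scenario '%s', %.0f min, seed %.0f\n",
              x$scenario, max(x$series$t), x$seed))
  print(x$metrics)
  invisible(x)
}

#' Reference closed-loop engine (explicit Euler, pure R)
#'
#' Independent re-implementation of the closed loop built directly from
#' the exported R model operations, integrated with explicit Euler at a
#' small fixed step.  Serves as the cross-check oracle for the compiled
#' production engine; it is orders of magnitude slower and intended for
#' short horizons.
#'
#' @inheritParams run_closed_loop
#' @param noise Numeric vector of per-sample noise (nA) or `FALSE`.
#' @return List with `series` (data frame `t`, `G`, `I`, `Ia`, `Ggut`,
#'   `S`, `I_plasma`, `IR_mLh`, `GR_mLh`, one row per step) and `trace`.
#' @export
run_closed_loop_reference <- function(patient = patient_params(),
                                      sensor = sensor_params(),
                                      controller = controller_params(),
                                      pumps = default_pumps(),
                                      scn = build_scenario("mild"),
                                      dt = 1 / 120, noise = FALSE) {
  sp_min <- sensor$sample_period / 60
  steps_per_sample <- round(sp_min / dt)
  stopifnot(abs(sp_min / dt - steps_per_sample) < 1e-9)
  steps_per_reading <- round(sensor$averaging_window / dt)
  n_steps <- round(scn$duration / dt)
  n_samples <- n_steps %/% steps_per_sample
  eps <- if (isFALSE(noise)) numeric(n_samples) else rep_len(noise, n_samples)

  y <- basal_state(patient, sensor, controller, pumps)
  orals <- Filter(function(e) e$kind %in% c("meal_complex_CHO", "oral_glucose"),
                  scn$events)
  ivg <- Filter(function(e) e$kind == "iv_glucose_bolus", scn$events)
  ivi <- Filter(function(e) e$kind == "iv_insulin_bolus", scn$events)
  profs <- lapply(orals, gastric_profile, p = patient)

  rate_at <- function(evts, t) {
    r <- 0
    for (e in evts) {
      dur <- max(e$duration / 60, dt)  # sub-step boluses spread over one step
      if (t >= e$t_start && t < e$t_start + dur)
        r <- r + e$amount * 1000 / dur
    }
    r
  }

  ir_mlh <- pumps$insulin$kvo_rate; gr_mlh <- 0
  hist <- glucose_history()
  buf <- numeric(0)
  sample_i <- 0
  n_keep <- n_steps + 1
  series <- matrix(NA_real_, n_keep, 9)
  colnames(series) <- c("t", "G", "I", "Ia", "Ggut", "S",
                        "I_plasma", "IR_mLh", "GR_mLh")
  trace <- list()
  v1 <- patient$bolus_model$V1_per_kg * patient$body_weight
  series[1, ] <- c(0, y[["G"]], y[["I"]], y[["Ia"]], y[["Ggut"]], y[["S"]],
                   y[["I"]] + y[["B1"]] / v1, ir_mlh, gr_mlh)

  for (step in seq_len(n_steps)) {
    t0 <- (step - 1) * dt
    st <- structure(c(G = y[["G"]], I = y[["I"]], Ia = y[["Ia"]],
                      Ggut = y[["Ggut"]], B1 = y[["B1"]], B2 = y[["B2"]],
                      t = t0), class = "aiis_state")
    ge <- 0
    for (pr in profs) ge <- ge + eval_gastric_profile(pr, t0)
    inputs <- list(
      insulin_mIU_min = delivered_dose(ir_mlh, pumps$insulin),
      iv_glucose_mg_min = rate_at(ivg, t0) +
        delivered_dose(gr_mlh, pumps$glucose),
      bolus_insulin_mIU_min = rate_at(ivi, t0),
      ge_flux_mg_min = ge)
    d <- patient_derivs(st, inputs, patient)
    dS <- sensor_dynamics(y[["S"]], y[["G"]], sensor)
    y[c("G", "I", "Ia", "Ggut", "B1", "B2")] <-
      pmax(y[c("G", "I", "Ia", "Ggut", "B1", "B2")] +
             dt * d[c("G", "I", "Ia", "Ggut", "B1", "B2")], 0)
    y[["S"]] <- y[["S"]] + dt * dS
    t1 <- t0 + dt

    if (step %% steps_per_sample == 0) {
      sample_i <- sample_i + 1
      buf <- c(buf, y[["S"]] + eps[sample_i])
    }
    if (step %% steps_per_reading == 0 && length(buf) > 0) {
      reading <- emit_reading(buf, t1, sensor)
      buf <- numeric(0)
      cs <- controller_step(reading, hist, controller)
      hist <- cs$history
      out <- cs$output
      ir_req_mlh <- out$IR * 60 / 1000 / pumps$insulin$concentration
      ir_mlh <- max(quantize_rate(ir_req_mlh, pumps$insulin),
                    pumps$insulin$kvo_rate)
      gr_mlh <- if (out$emergency_active)
        quantize_rate(out$GR, pumps$glucose) else 0
      trace[[length(trace) + 1]] <-
        data.frame(t = t1, G_est = reading$G_est, A = out$A, DF = out$DF,
                   IR_mLh = ir_mlh, GR_mLh = gr_mlh,
                   emergency = out$emergency_active)
    }
    series[step + 1, ] <- c(t1, y[["G"]], y[["I"]], y[["Ia"]], y[["Ggut"]],
                            y[["S"]], y[["I"]] + y[["B1"]] / v1,
                            ir_mlh, gr_mlh)
  }
  list(series = as.data.frame(series),
       trace = if (length(trace)) do.call(rbind, trace) else NULL)
}

#' Sweep challenges across body weight and hepatic sensitivity
#'
#' Runs the closed loop for every combination of weight, hepatic
#' sensitivity, challenge kind and replicate, and returns one metrics row
#' per run plus per-cell medians across replicates (sensor noise makes
#' each run stochastic).
#'
#' @param weights Body weights, kg.
#' @param sh_values Hepatic sensitivities.
#' @param kinds Challenge kinds (see [build_scenario()]).
#' @param replicates Runs per cell; odd values give unambiguous medians.
#' @param seed Global seed; per-run seeds are drawn from it.
#' @param patient Template [patient_params()] supplying all non-swept
#'   fields.
#' @param ... Passed to [run_closed_loop()] (e.g. `sensor`, `controller`).
#' @return List with data frames `runs` (per-run metrics) and `summary`
#'   (per-cell medians of the numeric metrics).
#' @export
sweep_table <- function(weights = c(60, 70, 80),
                        sh_values = c(0.3, 0.5, 0.7),
                        kinds = c("mild", "moderate", "severe"),
                        replicates = 11, seed = 1L,
                        patient = patient_params(), ...) {
  stopifnot(replicates >= 1)
  grid <- expand.grid(replicate = seq_len(replicates), Sh = sh_values,
                      weight = weights, kind = kinds,
                      stringsAsFactors = FALSE)
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  set.seed(seed)
  grid$seed <- sample.int(.Machine$integer.max - 1L, nrow(grid))
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())

  rows <- lapply(seq_len(nrow(grid)), function(i) {
    g <- grid[i, ]
    pat <- patient
    pat$body_weight <- g$weight
    pat$Sh <- g$Sh
    pat <- validate_patient(unclass(pat))
    res <- run_closed_loop(patient = pat, scn = build_scenario(g$kind),
                           seed = g$seed, ...)
    m <- res$metrics
    data.frame(kind = g$kind, weight = g$weight, Sh = g$Sh,
               replicate = g$replicate, seed = g$seed,
               overshoot_peak = m$g_max,
               overshoot_duration = m$overshoot_duration,
               undershoot_peak = m$g_min,
               undershoot_duration = m$undershoot_duration,
               had_overshoot = m$had_overshoot,
               had_undershoot = m$had_undershoot,
               settling_time_Ts = m$settling_time_Ts,
               ts_first_below_high = m$ts_first_below_high)
  })
  runs <- do.call(rbind, rows)
  num <- c("overshoot_peak", "overshoot_duration", "undershoot_peak",
           "undershoot_duration", "settling_time_Ts",
           "ts_first_below_high")
  summary <- aggregate(runs[num],
                       by = runs[c("kind", "weight", "Sh")],
                       FUN = function(v) median(v))
  summary$any_undershoot <- aggregate(runs$had_undershoot,
    by = runs[c("kind", "weight", "Sh")], FUN = any)$x
  list(runs = runs, summary = summary)
}
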