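#' Virtual type-1 diabetic patient parameters
#'
#' Builds the parameter set of the compartmental glucose--insulin model: a
#' single extracellular glucose compartment fed by gut absorption and net
#' hepatic glucose balance (NHGB) and drained by insulin-dependent plus
#' insulin-independent utilization and renal excretion, coupled to plasma
#' and "active" insulin pools.  The patient secretes no endogenous insulin;
#' all insulin arrives intravenously.
#'
#' @param body_weight Body weight, kg.
#' @param Sh Hepatic insulin sensitivity, dimensionless in `[0, 1]`.
#'   Multiplies plasma insulin to give the effective insulin seen by the
#'   liver.
#' @param Sp Peripheral insulin sensitivity, dimensionless in `[0, 1]`.
#'   Multiplies the insulin-dependent utilization slope `c`.
#' @param ... Overrides for any other field of
#'   `aiis_defaults()$patient` (e.g. `renal_threshold`, `gut`,
#'   `nhgb_table`, `bolus_model`).  Nested lists are merged element-wise.
#' @return An object of class `aiis_patient`: a validated named list.
#' @examples
#' p <- patient_params(body_weight = 70, Sh = 0.5)
#' p$glucose_dist_volume * p$body_weight # glucose space, dL
#' @export
patient_params <- function(body_weight = 70, Sh = 0.5, Sp = 1.0, ...) {
  p <- modifyList(aiis_defaults()$patient,
                  c(list(body_weight = body_weight, Sh = Sh, Sp = Sp),
                    list(...)))
  validate_patient(p)
}

validate_patient <- function(p) {
  p$active_insulin_rates <- unlist(p$active_insulin_rates)
  p$nhgb_table <- lapply(p$nhgb_table, unlist)
  stopifnot(
    "body_weight must be > 0" = p$body_weight > 0,
    "Sh must lie in [0, 1]" = p$Sh >= 0 && p$Sh <= 1,
    "Sp must lie in [0, 1]" = p$Sp >= 0 && p$Sp <= 1,
    "c must be > 0" = p$c > 0,
    "volumes and rates must be > 0" =
      all(c(p$renal_clearance, p$glucose_dist_volume, p$insulin_dist_volume,
            p$insulin_elim_rate, p$active_insulin_rates, p$active_insulin_sat,
            p$insulin_independent_util, p$util_km,
            p$gut$emptying_vmax, p$gut$emptying_ramp,
            p$gut$absorption_vmax, p$gut$absorption_km,
            unlist(p$bolus_model)) > 0),
    "renal_threshold must be >= 0" = p$renal_threshold >= 0,
    "meal_slowdown must lie in (0, 1]" =
      p$gut$meal_slowdown > 0 && p$gut$meal_slowdown <= 1,
    "nhgb table needs >= 2 increasing insulin knots" =
      length(p$nhgb_table$ieff) >= 2 && !is.unsorted(p$nhgb_table$ieff),
    "nhgb table must be monotone non-increasing" =
      all(diff(p$nhgb_table$nhgb) <= 0)
  )
  structure(p, class = "aiis_patient")
}

#' Instantaneous physiological state of the virtual patient
#'
#' @param G Glycemia, mg/dL.
#' @param I Plasma insulin from infusion, mIU/L (numerically uIU/mL).
#' @param Ia Active insulin pool, mIU/L.
#' @param Ggut Glucose mass in the gut, mg.
#' @param B1,B2 Central/peripheral mass of the IV-bolus insulin model, mIU.
#' @param t Simulation time, min.
#' @return An object of class `aiis_state` (named numeric vector).
#' @export
patient_state <- function(G = 100, I = 0, Ia = 0, Ggut = 0,
                          B1 = 0, B2 = 0, t = 0) {
  stopifnot(G >= 0, I >= 0, Ia >= 0, Ggut >= 0, B1 >= 0, B2 >= 0)
  structure(c(G = G, I = I, Ia = Ia, Ggut = Ggut, B1 = B1, B2 = B2, t = t),
            class = "aiis_state")
}

#' Timed challenge event
#'
#' A single perturbation of the 24-h simulation: a complex-carbohydrate
#' meal, oral glucose, an IV dextrose bolus, or an IV insulin bolus.
#'
#' @param kind One of `"meal_complex_CHO"`, `"oral_glucose"`,
#'   `"iv_glucose_bolus"`, `"iv_insulin_bolus"`.
#' @param t_start Start time, min.
#' @param amount Grams of carbohydrate/glucose, or IU of insulin for
#'   `"iv_insulin_bolus"`.
#' @param duration Administration duration in seconds; defaults: 30 s for
#'   IV glucose, 2 s for IV insulin, 0 for oral routes (the oral profile
#'   duration is set by gastric emptying, not by this field).
#' @export
challenge_event <- function(kind, t_start, amount,
                            duration = switch(kind,
                                              iv_glucose_bolus = 30,
                                              iv_insulin_bolus = 2,
                                              0)) {
  kinds <- c("meal_complex_CHO", "oral_glucose",
             "iv_glucose_bolus", "iv_insulin_bolus")
  if (!kind %in% kinds)
    stop("unknown challenge kind: ", kind)
  if (!is.numeric(amount) || amount <= 0)
    stop("invalid event: amount must be > 0")
  if (duration < 0) stop("invalid event: duration must be >= 0")
  structure(list(kind = kind, t_start = t_start, amount = amount,
                 duration = duration), class = "aiis_event")
}

#' Two-compartment IV insulin bolus model parameters
#'
#' @param k12,k21 Central/peripheral transfer constants, min^-1.
#' @param k_el Central elimination constant, min^-1.
#' @param V1 Central distribution volume, L.
#' @export
bolus_insulin_model <- function(k12 = 0.05, k21 = 0.02, k_el = 0.15, V1 = 3.0) {
  stopifnot(k12 > 0, k21 > 0, k_el > 0, V1 > 0)
  structure(list(k12 = k12, k21 = k21, k_el = k_el, V1 = V1),
            class = "aiis_bolus_model")
}

# Piecewise ramp-plateau-ramp gastric emptying profile for one oral event.
# Returns a list of breakpoints used by both engines.  When the load is too
# small to reach the plateau the profile degenerates to a triangle with the
# same ramp slope so that the time integral always equals the load.
gastric_profile <- function(event, p) {
  vmax <- p$gut$emptying_vmax *
    if (event$kind == "meal_complex_CHO") p$gut$meal_slowdown else 1
  tr <- p$gut$emptying_ramp
  load <- event$amount * 1000  # g -> mg
  slope <- vmax / tr
  if (load >= vmax * tr) {
    tp <- (load - vmax * tr) / vmax  # plateau duration
    list(t0 = event$t_start, slope = slope, vmax = vmax,
         t_up = tr, t_down_start = tr + tp, t_end = 2 * tr + tp)
  } else {
    tpk <- sqrt(load / slope)        # triangular profile
    list(t0 = event$t_start, slope = slope, vmax = slope * tpk,
         t_up = tpk, t_down_start = tpk, t_end = 2 * tpk)
  }
}

eval_gastric_profile <- function(prof, t) {
  u <- t - prof$t0
  if (u <= 0 || u >= prof$t_end) return(0)
  if (u < prof$t_up) return(prof$slope * u)
  if (u < prof$t_down_start) return(prof$vmax)
  prof$vmax - prof$slope * (u - prof$t_down_start)
}

#' Gastric emptying flux
#'
#' Rate at which carbohydrate leaves the stomach for the gut, following a
#' trapezoidal ramp--plateau--ramp profile whose plateau height is the
#' maximum gastric emptying rate (halved for complex-carbohydrate meals)
#' and whose area equals the ingested carbohydrate mass.
#'
#' @param state An [patient_state()] (only `state["t"]` is used).
#' @param event An oral [challenge_event()] (`meal_complex_CHO` or
#'   `oral_glucose`), or `NULL` for no pending meal.
#' @param p [patient_params()].
#' @return Flux in mg/min.
#' @export
gastric_emptying_flux <- function(state, event, p) {
  if (is.null(event)) return(0)
  if (!event$kind %in% c("meal_complex_CHO", "oral_glucose"))
    stop("invalid event: gastric emptying applies to oral events only")
  if (event$amount <= 0) stop("invalid event: amount must be > 0")
  if (event$t_start > state[["t"]]) return(0)
  eval_gastric_profile(gastric_profile(event, p), state[["t"]])
}

#' Systemic glucose appearance from the gut
#'
#' Saturating (Michaelis-type) absorption of gut glucose into the
#' extracellular space.  No gut losses: every mg emptied from the stomach
#' is eventually absorbed.
#'
#' @inheritParams gastric_emptying_flux
#' @return `G_in`, mg/dL/h of systemic glucose appearance.
#' @export
gut_absorption <- function(state, p) {
  stopifnot(state[["Ggut"]] >= 0)
  vg <- p$glucose_dist_volume * p$body_weight  # dL
  60 * gut_absorption_mass(state[["Ggut"]], p) / vg
}

# mg/min absorbed from the gut
gut_absorption_mass <- function(Ggut, p) {
  p$gut$absorption_vmax * Ggut / (p$gut$absorption_km + Ggut)
}

#' Peripheral plus insulin-dependent glucose utilization
#'
#' Sum of insulin-independent uptake (central nervous system, red cells)
#' and insulin-dependent uptake, linear in active insulin with slope
#' `c * Sp`, both modulated by a Michaelis factor in glycemia normalized
#' to 1 at the reference glycemia (100 mg/dL).
#'
#' @param G Glycemia, mg/dL.
#' @param I_eq Insulin driving utilization (the active pool), mIU/L.
#' @param p [patient_params()].
#' @return `G_out`, mg/kg/h.
#' @export
peripheral_utilization <- function(G, I_eq, p) {
  stopifnot(G >= 0, I_eq >= 0)
  mich <- G * (p$util_km + p$util_gref) / (p$util_gref * (p$util_km + G))
  (p$insulin_independent_util + 60 * p$c * p$Sp * I_eq) * mich
}

#' Net hepatic glucose balance
#'
#' Hepatic production minus uptake as a function of the effective insulin
#' `Sh * I` (piecewise-linear monotone table) and of glycemia (linear
#' suppression above the reference level), clamped to the table range.
#' Positive values are net production; negative values net uptake.
#'
#' @param G Glycemia, mg/dL.
#' @param I Plasma insulin, mIU/L.
#' @param p [patient_params()].
#' @return NHGB for the whole patient, mg/h.
#' @export
net_hepatic_glucose_balance <- function(G, I, p) {
  stopifnot(G >= 0, I >= 0)
  nhgb_specific(G, p$Sh * I, p) * p$body_weight
}

# mg/kg/h given effective insulin.  The insulin dimension is the
# piecewise-linear table (clamped at its endpoints); the glucose dimension
# is a linear suppression/counter-regulation term with its own configured
# bounds, so hepatic defense of hypoglycemia is not limited by the
# zero-insulin table endpoint.
nhgb_specific <- function(G, ieff, p) {
  tab <- p$nhgb_table
  base <- approx(tab$ieff, tab$nhgb, xout = ieff, rule = 2)$y
  val <- base - p$nhgb_glucose_slope * (G - p$util_gref)
  val <- min(max(val, p$nhgb_min), p$nhgb_max)
  # hypoglycemic counter-regulation: below the hypo threshold hepatic
  # output has a glucose-driven floor, itself attenuated by effective
  # insulin (counter-regulatory hepatic output is blunted under
  # hyperinsulinemia)
  if (G < p$nhgb_hypo_threshold) {
    hypo <- p$nhgb_hypo_slope * (p$nhgb_hypo_threshold - G) -
      p$nhgb_hypo_insulin_sup * ieff
    if (hypo > val) val <- min(hypo, p$nhgb_max)
  }
  val
}

#' Renal glucose excretion
#'
#' Zero below the renal threshold; proportional to the excess glycemia
#' above it (clearance times excess concentration).
#'
#' @param G Glycemia, mg/dL.
#' @param p [patient_params()].
#' @return `G_ren`, mg/h.
#' @export
renal_excretion <- function(G, p) {
  stopifnot(G >= 0)
  60 * p$renal_clearance * max(0, G - p$renal_threshold)
}

#' Plasma and active insulin kinetics
#'
#' First-order plasma elimination driven by the IV infusion, an active
#' pool that builds up from total plasma insulin (infusion plus any IV
#' bolus still distributing) and deactivates first-order, and the
#' two-compartment bolus masses.  The insulin driving the active pool
#' saturates at `active_insulin_sat` (receptor-level saturation), a cap
#' above any infusion-achievable plasma level that only limits the spike
#' of an IV bolus.
#'
#' @param state [patient_state()].
#' @param iv_infusion Insulin infusion reaching plasma, mIU/min.
#' @param bolus_input IV bolus administration rate entering the central
#'   bolus compartment, mIU/min.
#' @param p [patient_params()].
#' @return Named list with `dI`, `dIa`, `dB1`, `dB2` (per-minute rates)
#'   and `I_total`, the measurable plasma insulin mIU/L.
#' @export
insulin_kinetics <- function(state, iv_infusion, bolus_input, p) {
  stopifnot(iv_infusion >= 0, bolus_input >= 0)
  vi <- p$insulin_dist_volume * p$body_weight  # L
  v1 <- p$bolus_model$V1_per_kg * p$body_weight
  I <- state[["I"]]; Ia <- state[["Ia"]]
  B1 <- state[["B1"]]; B2 <- state[["B2"]]
  I_total <- I + B1 / v1
  kb <- p$active_insulin_rates[["build"]]
  kd <- p$active_insulin_rates[["decay"]]
  list(
    dI = iv_infusion / vi - p$insulin_elim_rate * I,
    dIa = kb * min(I_total, p$active_insulin_sat) - kd * Ia,
    dB1 = bolus_input - (p$bolus_model$k12 + p$bolus_model$k_el) * B1 +
      p$bolus_model$k21 * B2,
    dB2 = p$bolus_model$k12 * B1 - p$bolus_model$k21 * B2,
    I_total = I_total
  )
}

#' Plasma insulin contribution of an IV bolus (closed form)
#'
#' Bi-exponential impulse response of the two-compartment bolus model: the
#' entire dose enters the central compartment at `t_since = 0`.
#'
#' @param dose Bolus dose, IU.
#' @param t_since Time since administration, min (vectorized).
#' @param m [bolus_insulin_model()].
#' @return Central-compartment concentration contribution, mIU/L.
#' @export
iv_insulin_bolus <- function(dose, t_since, m) {
  stopifnot(dose > 0)
  s <- m$k12 + m$k_el + m$k21
  disc <- sqrt(s^2 - 4 * m$k_el * m$k21)
  l1 <- (-s + disc) / 2  # slow eigenvalue
  l2 <- (-s - disc) / 2  # fast eigenvalue
  x1 <- dose * 1000 *
    ((l1 + m$k21) * exp(l1 * t_since) - (l2 + m$k21) * exp(l2 * t_since)) /
    (l1 - l2)
  ifelse(t_since < 0, 0, x1 / m$V1)
}

#' Glycemia balance
#'
#' Assembles the rate of change of glycemia from its four physiological
#' fluxes plus any IV glucose:
#' `dG/dt = G_in + (NHGB - G_ren + 60 * iv_glucose) / V_g - G_out * weight / V_g`
#' with `V_g` the glucose distribution space in dL.
#'
#' @param state [patient_state()] (unused fields tolerated; present for
#'   signature symmetry with the other flux operations).
#' @param G_in Gut appearance, mg/dL/h.
#' @param NHGB Net hepatic glucose balance, mg/h.
#' @param G_out Peripheral utilization, mg/kg/h.
#' @param G_ren Renal excretion, mg/h.
#' @param iv_glucose IV glucose delivery, mg/min.
#' @param p [patient_params()].
#' @return `dG/dt`, mg/dL/h.
#' @export
glucose_balance <- function(state, G_in, NHGB, G_out, G_ren, iv_glucose, p) {
  vg <- p$glucose_dist_volume * p$body_weight
  G_in + (NHGB - G_ren + 60 * iv_glucose) / vg - G_out * p$body_weight / vg
}

#' Full state derivative of the virtual patient
#'
#' Composes the exported flux operations into the per-minute derivative of
#' the complete state vector.  This is the reference (pure R) right-hand
#' side; the compiled engine implements the same equations.
#'
#' @param state [patient_state()].
#' @param inputs Named list: `insulin_mIU_min` (pump insulin reaching
#'   plasma), `iv_glucose_mg_min` (dextrose pump plus any IV glucose
#'   bolus), `bolus_insulin_mIU_min` (IV insulin bolus administration),
#'   `ge_flux_mg_min` (gastric emptying).  Missing entries default to 0.
#' @param p [patient_params()].
#' @return Named numeric vector of derivatives (per minute) for
#'   `G, I, Ia, Ggut, B1, B2`.
#' @export
patient_derivs <- function(state, inputs, p) {
  getin <- function(nm) if (is.null(inputs[[nm]])) 0 else inputs[[nm]]
  ins <- getin("insulin_mIU_min")
  ivg <- getin("iv_glucose_mg_min")
  bol <- getin("bolus_insulin_mIU_min")
  ge  <- getin("ge_flux_mg_min")
  G <- max(state[["G"]], 0)
  ik <- insulin_kinetics(state, ins, bol, p)
  G_in  <- gut_absorption(state, p)
  G_out <- peripheral_utilization(G, state[["Ia"]], p)
  nhgb  <- net_hepatic_glucose_balance(G, ik$I_total, p)
  G_ren <- renal_excretion(G, p)
  dG_h  <- glucose_balance(state, G_in, nhgb, G_out, G_ren, ivg, p)
  c(G = dG_h / 60,
    I = ik$dI, Ia = ik$dIa,
    Ggut = ge - gut_absorption_mass(state[["Ggut"]], p),
    B1 = ik$dB1, B2 = ik$dB2)
}

#' Advance the patient one time step
#'
#' Classical fixed-step fourth-order Runge--Kutta step of the patient ODE
#' system with inputs held constant over the step.  Negative state values
#' produced by the step are clipped to zero (physiological floor) with a
#' warning.
#'
#' @param state [patient_state()].
#' @param inputs See [patient_derivs()].
#' @param dt Step size, min.
#' @param p [patient_params()].
#' @return The advanced [patient_state()].
#' @export
patient_step <- function(state, inputs, dt, p) {
  stopifnot(dt > 0)
  y <- unclass(state)[c("G", "I", "Ia", "Ggut", "B1", "B2")]
  if (any(!is.finite(y))) {
    bad <- names(y)[!is.finite(y)][1]
    stop("integration failure: non-finite state variable '", bad, "'")
  }
  f <- function(yv, tt) {
    s <- structure(c(yv, t = tt), class = "aiis_state")
    patient_derivs(s, inputs, p)
  }
  t0 <- state[["t"]]
  k1 <- f(y, t0)
  k2 <- f(y + dt / 2 * k1, t0 + dt / 2)
  k3 <- f(y + dt / 2 * k2, t0 + dt / 2)
  k4 <- f(y + dt * k3, t0 + dt)
  ynew <- y + dt / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
  if (any(!is.finite(ynew))) {
    bad <- names(ynew)[!is.finite(ynew)][1]
    stop("integration failure: non-finite state variable '", bad, "'")
  }
  if (any(ynew < 0)) {
    warning("state clipped at zero: ",
            paste(names(ynew)[ynew < 0], collapse = ", "))
    ynew <- pmax(ynew, 0)
  }
  structure(c(ynew, t = t0 + dt), class = "aiis_state")
}
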