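#' Controller slope for a basal anchor
#'
#' Solves the tanh insulin law for the slope that makes the controller
#' command a given basal rate at the reference glycemia with flat trend:
#' `(M/2) * (1 + tanh(S_slope * (G_ref - B))) = basal`.
#'
#' This is the scripted calibration behind the shipped `S_slope` default:
#' with `M = 200` mIU/min (12 IU/h) and `B = 153` mg/dL, anchoring the
#' keep-vein-open basal command of 1.0 IU/h at 103 mg/dL (just above the
#' reference glycemia, so readings inside the acceptance band leave the
#' insulin line at its KVO floor instead of chasing sensor noise) gives
#' `S_slope` of about 0.024 dL/mg.
#'
#' @param M Maximum infusion rate, mIU/min.
#' @param B Half-maximum glycemia, mg/dL.
#' @param basal Basal insulin command at the anchor glycemia, mIU/min.
#' @param G_ref Anchor glycemia at which the command equals `basal`,
#'   mg/dL.
#' @return `S_slope`, dL/mg.
#' @export
calibrate_controller_slope <- function(M = 200, B = 153, basal = 1000 / 60,
                                       G_ref = 103) {
  stopifnot(basal > 0, basal < M, G_ref != B)
  atanh(2 * basal / M - 1) / (G_ref - B)
}

#' Basal plasma insulin under a constant infusion
#'
#' Closed-form steady state of the linear plasma insulin kinetics:
#' `I_ss = R / (k_el * V_I)`.
#'
#' @param p [patient_params()].
#' @param rate_mIU_min Constant infusion rate, mIU/min.
#' @return Steady-state plasma insulin, mIU/L.
#' @export
basal_plasma_insulin <- function(p, rate_mIU_min = 1000 / 60) {
  rate_mIU_min / (p$insulin_elim_rate * p$insulin_dist_volume * p$body_weight)
}

#' NHGB value that balances the basal operating point
#'
#' The scripted calibration of the hepatic table: at the basal fixed point
#' (reference glycemia, keep-vein-open insulin delivery) the net hepatic
#' glucose balance must equal total glucose utilization.  Returns the
#' specific NHGB (mg/kg/h) required at the basal effective insulin, which
#' the shipped table interpolates exactly at its 10 mIU/L knot for the
#' default 70-kg, Sh = 0.5 patient.
#'
#' @param p [patient_params()].
#' @param rate_mIU_min Basal infusion, mIU/min.
#' @return List with `ieff` (mIU/L) and `nhgb` (mg/kg/h) at the basal
#'   point.
#' @export
nhgb_basal_value <- function(p = patient_params(), rate_mIU_min = 1000 / 60) {
  I <- basal_plasma_insulin(p, rate_mIU_min)
  # at steady state the active pool equals (build/decay) * I
  Ia <- I * p$active_insulin_rates[["build"]] / p$active_insulin_rates[["decay"]]
  list(ieff = p$Sh * I,
       nhgb = peripheral_utilization(p$util_gref, Ia, p))
}
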