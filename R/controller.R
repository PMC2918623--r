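#' Proportional-derivative insulin controller parameters
#'
#' The insulin law is a hyperbolic-tangent sigmoid of the projected
#' glycemia `G0 + DF`:
#' `IR' = (M/2) * (1 + tanh(S_slope * (G0 + DF - B)))`,
#' where `DF = K2 * A / sqrt(1 + K1 * A^2)` is the derivative-action
#' differential factor and `A = a0*G0 + a5*G5 + a10*G10` aggregates the
#' glycemia trend over the last three 5-minute readings (the coefficients
#' sum to zero, so constant glycemia gives pure proportional control).
#' Below the critical glycemia `G_crit` the emergency logic floors the
#' insulin line at the keep-vein-open minimum and enables the proportional
#' dextrose rescue `GR' = K_G * (G_crit - G0)`.
#'
#' Defaults are calibrated so that at the reference glycemia (100 mg/dL,
#' flat trend) the commanded rate is 1.0 IU/h and the maximum `M`
#' corresponds to 12 IU/h; see [calibrate_controller_slope()].
#'
#' @param M Maximum insulin infusion rate, mIU/min.
#' @param S_slope Slope of the tanh curve, dL/mg.
#' @param B Glycemia of half-maximum infusion, mg/dL.
#' @param ... Overrides for the remaining fields of
#'   `aiis_defaults()$controller` (`K1`, `K2`, `a0`, `a5`, `a10`,
#'   `IR_min`, `G_crit`, `K_G`, `G_ref`, `band_low`, `band_high`).
#' @return An object of class `aiis_controller`.
#' @export
controller_params <- function(M = 200, S_slope = 0.024, B = 153, ...) {
  p <- modifyList(aiis_defaults()$controller,
                  c(list(M = M, S_slope = S_slope, B = B), list(...)))
  stopifnot(
    "M must exceed IR_min and IR_min must be >= 0" =
      p$M > p$IR_min && p$IR_min >= 0,
    "S_slope must be > 0" = p$S_slope > 0,
    "B must be > 0" = p$B > 0,
    "G_crit must be below band_low" = p$G_crit < p$band_low,
    "K_G must be > 0" = p$K_G > 0,
    "band_low must be below band_high" = p$band_low < p$band_high
  )
  if (abs(p$a0 + p$a5 + p$a10) > 1e-8)
    stop("trend coefficients must sum to zero (a0 + a5 + a10 = 0), got ",
         p$a0 + p$a5 + p$a10)
  structure(p, class = "aiis_controller")
}

#' Rolling three-reading glycemia history
#'
#' @param G0,G5,G10 Last reading and the readings 5 and 10 minutes
#'   earlier, mg/dL (`NA` while warming up).
#' @export
glucose_history <- function(G0 = NA_real_, G5 = NA_real_, G10 = NA_real_) {
  structure(list(G0 = G0, G5 = G5, G10 = G10, last_t = -Inf),
            class = "aiis_history")
}

#' Differential parameter A
#'
#' Zero-sum linear aggregate of the last three readings measuring the
#' glycemia trend over the 10-minute window.  During warm-up (fewer than
#' three readings) `A = 0`, reducing the controller to pure proportional
#' action.
#'
#' @param h [glucose_history()].
#' @param p [controller_params()].
#' @return `A`, mg/dL.
#' @export
diff_parameter_A <- function(h, p) {
  if (anyNA(c(h$G0, h$G5, h$G10))) return(0)
  p$a0 * h$G0 + p$a5 * h$G5 + p$a10 * h$G10
}

#' Differential factor DF
#'
#' Odd, bounded transform of the trend estimate `A`:
#' `DF = K2 * A / (1 + K1 * A^2)`.  Near zero trend the gain is `K2`; the
#' magnitude peaks at `K2 / (2 sqrt(K1))` (5 mg/dL at the default K1 = 1,
#' K2 = 10) when `|A| = 1/sqrt(K1)` and then decays, so derivative action
#' responds fully to physiological per-minute trends of order 1 mg/dL/min
#' while suppressing large jumps between readings, which with a 5-minute
#' cadence are dominated by sensor noise.
#'
#' @param A Differential parameter, mg/dL (per-minute trend scale).
#' @param p [controller_params()].
#' @return `DF`, mg/dL.
#' @export
diff_factor_DF <- function(A, p) {
  p$K2 * A / (1 + p$K1 * A^2)
}

#' Tanh insulin infusion law
#'
#' @param G0 Last glycemia reading, mg/dL.
#' @param DF Differential factor, mg/dL.
#' @param p [controller_params()].
#' @return Raw commanded insulin rate `IR'`, mIU/min, in `(0, M)`.
#' @export
insulin_infusion_law <- function(G0, DF, p) {
  (p$M / 2) * (1 + tanh(p$S_slope * (G0 + DF - p$B)))
}

#' Proportional glucose rescue law
#'
#' @param G0 Last glycemia reading, mg/dL.
#' @param p [controller_params()].
#' @return Raw commanded dextrose rate `GR'`, mL/h; zero at or above
#'   `G_crit`, linear with gain `K_G` below it.
#' @export
glucose_infusion_law <- function(G0, p) {
  p$K_G * max(0, p$G_crit - G0)
}

#' Emergency switching logic
#'
#' Below the critical glycemia the insulin line is cut to its minimum and
#' the dextrose rescue is enabled; at or above it, normal insulin control
#' resumes and the dextrose line is off.
#'
#' @param G0 Last glycemia reading, mg/dL.
#' @param IR_prime Raw insulin command, mIU/min.
#' @param GR_prime Raw dextrose command, mL/h.
#' @param p [controller_params()].
#' @return List with `IR` (mIU/min), `GR` (mL/h), `emergency_active`.
#' @export
emergency_logic <- function(G0, IR_prime, GR_prime, p) {
  if (G0 < p$G_crit) {
    list(IR = p$IR_min, GR = GR_prime, emergency_active = TRUE)
  } else {
    list(IR = max(IR_prime, p$IR_min), GR = 0, emergency_active = FALSE)
  }
}

#' One controller execution on a new sensor reading
#'
#' Shifts the reading history, composes trend -> differential factor ->
#' insulin law and the rescue law, and applies the emergency logic.
#' Executed once per emitted 5-minute reading.
#'
#' @param reading List with `t` and `G_est` (see [emit_reading()]).
#' @param history [glucose_history()] carried between calls.
#' @param p [controller_params()].
#' @return List with `output` (fields `IR` mIU/min, `IR_prime` mIU/min,
#'   `GR`, `GR_prime` mL/h, `emergency_active`, `A`, `DF`) and the
#'   updated `history`.
#' @export
controller_step <- function(reading, history, p) {
  if (reading$t <= history$last_t)
    stop("sequencing error: reading timestamps must be strictly increasing")
  history <- glucose_history(G0 = reading$G_est, G5 = history$G0,
                             G10 = history$G5)
  history$last_t <- reading$t
  A <- diff_parameter_A(history, p)
  DF <- diff_factor_DF(A, p)
  IRp <- insulin_infusion_law(history$G0, DF, p)
  GRp <- glucose_infusion_law(history$G0, p)
  out <- emergency_logic(history$G0, IRp, GRp, p)
  out$IR_prime <- IRp; out$GR_prime <- GRp; out$A <- A; out$DF <- DF
  list(output = out, history = history)
}
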