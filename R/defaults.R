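#' Default simulation parameters
#'
#' Single versioned home of every numeric constant used by the simulator:
#' the virtual-patient physiology, the subcutaneous sensor, the
#' proportional-derivative controller, both infusion pumps and the engine
#' clocks.  Every value can be overridden through [load_config()] or by the
#' individual constructors ([patient_params()], [sensor_params()],
#' [controller_params()], [pump_spec()]).
#'
#' Units follow clinical convention: glycemia in mg/dL, insulin
#' concentrations in mIU/L (numerically identical to uIU/mL), insulin
#' infusion internally in mIU/min, pump rates in mL/h, time in minutes.
#'
#' Constants fall in three groups:
#'
#' * Printed device/algorithm constants: sensor gain `alpha` = 0.23 nA per
#'   mg/dL, time constant `tau` = 5.77 min, no transport lag, raw noise
#'   variance 100 nA^2, 40--400 mg/dL saturation; controller `K1` = 1
#'   (mg/dL)^-2 and `K2` = 10; reference glycemia 100 mg/dL with the
#'   90--120 mg/dL acceptance band and hypoglycemia threshold 60 mg/dL;
#'   pump limits 1.0--500 mL/h in 0.1 mL/h steps with a 1.0 mL/h
#'   keep-vein-open floor.
#' * Physiological constants of the compartmental patient model (glucose
#'   and insulin distribution volumes, elimination and active-pool rate
#'   constants, insulin-independent utilization, renal threshold and
#'   clearance, gastric-emptying and gut-absorption parameters, the net
#'   hepatic glucose balance table).  These are documented model choices in
#'   the range of published compartmental glucose models; see the methods
#'   vignette.
#' * Calibrated controller tuning (`M`, `S_slope`, `B`, the trend
#'   coefficients `a0/a5/a10`, rescue gain `K_G`), fixed by the scripted
#'   procedure in [calibrate_controller_slope()] / [nhgb_basal_value()] so
#'   that the closed loop holds 100 mg/dL while delivering 1.0 IU/h of
#'   insulin (about 20 uIU/mL plasma insulin) and saturates at 12 IU/h.
#'
#' @return A named nested list with blocks `patient`, `sensor`,
#'   `controller`, `pumps` (sub-blocks `insulin`, `glucose`) and `engine`.
#' @examples
#' d <- aiis_defaults()
#' d$sensor$tau
#' @export
aiis_defaults <- function() {
  list(
    patient = list(
      body_weight = 70,            # kg
      Sh = 0.5,                    # hepatic insulin sensitivity, 0-1
      Sp = 1.0,                    # peripheral insulin sensitivity, 0-1
      c = 0.045,                   # mg min^-1 mIU^-1 L (per kg) utilization slope
      renal_threshold = 180,       # mg/dL
      renal_clearance = 1.0,       # dL/min of plasma cleared above threshold
      glucose_dist_volume = 1.8,   # dL/kg
      insulin_dist_volume = 0.1065, # L/kg
      insulin_elim_rate = 0.12,    # min^-1, first-order plasma elimination
      active_insulin_rates = c(build = 0.25, decay = 0.25), # min^-1
      active_insulin_sat = 250,    # mIU/L, receptor-level saturation of the
                                   # insulin driving the active pool; above
                                   # any infusion-achievable plasma level, so
                                   # it only limits IV bolus spikes
      insulin_independent_util = 86, # mg/kg/h, CNS + red cells at 100 mg/dL
      util_km = 180,               # mg/dL, Michaelis constant of utilization
      util_gref = 100,             # mg/dL, glycemia at which the Michaelis
                                   # factor is normalized to 1
      # Net hepatic glucose balance vs effective insulin Sh*I (mg/kg/h).
      # Monotone decreasing; the 10 mIU/L knot is the basal calibration
      # point (see nhgb_basal_value()).
      nhgb_table = list(
        ieff = c(0, 5, 10, 15, 25, 40, 80),
        nhgb = c(180, 150, 134.128, 124, 60, -40, -130)
      ),
      nhgb_glucose_slope = 2.0,    # mg/kg/h decrease per mg/dL above 100
      nhgb_max = 300,              # mg/kg/h ceiling of hepatic output under
                                   # hypoglycemic counter-regulation
      nhgb_min = -130,             # mg/kg/h floor (maximal net uptake)
      nhgb_hypo_threshold = 85,    # mg/dL below which counter-regulation
                                   # overrides insulin suppression
      nhgb_hypo_slope = 16,        # mg/kg/h hepatic output per mg/dL below
                                   # the hypo threshold (override floor)
      nhgb_hypo_insulin_sup = 1.5, # mg/kg/h reduction of the hypoglycemia
                                   # floor per mIU/L effective insulin
      gut = list(
        emptying_vmax = 1300,      # mg/min, oral glucose
        emptying_ramp = 15,        # min, up/down ramp of the trapezoid
        meal_slowdown = 0.5,       # emptying factor for complex CHO meals
        absorption_vmax = 1200,    # mg/min, saturating gut absorption
        absorption_km = 15000      # mg, half-saturation gut glucose mass
      ),
      bolus_model = list(          # two-compartment IV insulin bolus
        k12 = 0.02,                # min^-1 central -> peripheral
        k21 = 0.05,                # min^-1 peripheral -> central
        k_el = 0.25,               # min^-1 central elimination
        V1_per_kg = 3.0 / 70       # L/kg central volume (3.0 L at 70 kg)
      )
    ),
    sensor = list(
      alpha = 0.23,                # nA per mg/dL
      tau = 5.77,                  # min
      T_D = 0,                     # min transport lag
      noise_variance = 100,        # nA^2 per raw 10-s sample
      sample_period = 10,          # s
      averaging_window = 5,        # min
      sat_low = 40,                # mg/dL
      sat_high = 400               # mg/dL
    ),
    controller = list(
      M = 200,                     # mIU/min maximum infusion (= 12 IU/h)
      S_slope = 0.024,             # dL/mg tanh slope
      B = 153,                     # mg/dL glycemia of half-maximum infusion
      K1 = 1,                      # (mg/dL)^-2
      K2 = 10,                     # dimensionless
      a0 = 0.3, a5 = -0.4, a10 = 0.1, # trend coefficients, sum 0:
                                   # three-point backward difference of the
                                   # per-minute glycemia trend over 10 min
      IR_min = 1000 / 60,          # mIU/min delivered at KVO (1 IU/h)
      G_crit = 60,                 # mg/dL rescue threshold
      K_G = 10,                    # (mL/h) per mg/dL rescue gain
      G_ref = 100,                 # mg/dL reference glycemia
      band_low = 90, band_high = 120 # mg/dL acceptable range
    ),
    pumps = list(
      insulin = list(rate_min = 1.0, rate_max = 500, rate_step = 0.1,
                     kvo_rate = 1.0, concentration = 1.0,    # IU/mL
                     drug = "insulin"),
      glucose = list(rate_min = 1.0, rate_max = 500, rate_step = 0.1,
                     kvo_rate = 1.0, concentration = 500.0,  # mg/mL (50% dextrose)
                     drug = "glucose")
    ),
    engine = list(
      dt = 1 / 12,                 # min; the 10-s sensor grid is every 2nd step
      duration = 1440,             # min
      challenge_time = 600         # min (hour 10:00)
    )
  )
}
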