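#' Infusion pump specification
#'
#' Clinical volumetric pump constraints: rates are quantized to
#' `rate_step` multiples and clamped to `[rate_min, rate_max]` while the
#' line is active; the insulin line never drops below the keep-vein-open
#' (KVO) rate, while the dextrose line is simply off between emergencies.
#'
#' @param rate_min Minimum active infusion rate, mL/h.
#' @param rate_max Maximum infusion rate, mL/h.
#' @param rate_step Rate resolution, mL/h.
#' @param kvo_rate Keep-vein-open rate, mL/h.
#' @param concentration Drug per mL of solution: IU/mL for insulin,
#'   mg/mL for dextrose.
#' @param drug `"insulin"` or `"glucose"`; selects the flux units of
#'   [delivered_dose()].
#' @return An object of class `aiis_pump`.
#' @export
pump_spec <- function(rate_min = 1.0, rate_max = 500, rate_step = 0.1,
                      kvo_rate = 1.0, concentration = 1.0,
                      drug = c("insulin", "glucose")) {
  drug <- match.arg(drug)
  stopifnot(
    "rates must satisfy 0 < rate_min <= kvo_rate <= rate_max" =
      rate_min > 0 && rate_min <= kvo_rate && kvo_rate <= rate_max,
    "rate_step must be > 0" = rate_step > 0,
    "concentration must be > 0" = concentration > 0
  )
  structure(list(rate_min = rate_min, rate_max = rate_max,
                 rate_step = rate_step, kvo_rate = kvo_rate,
                 concentration = concentration, drug = drug),
            class = "aiis_pump")
}

#' Quantize a commanded rate to pump resolution
#'
#' Rounds to the nearest `rate_step` multiple (ties round half-up for
#' bit-reproducibility) and clamps to the active range.  An inactive line
#' delivers 0 if `kvo` is `FALSE` (dextrose line between emergencies) or
#' the KVO rate if `kvo` is `TRUE` (insulin line, which must never stop).
#'
#' @param requested Commanded rate, mL/h (vectorized).
#' @param spec [pump_spec()].
#' @param active Is the line actively controlled?
#' @param kvo Should an inactive line fall back to KVO instead of 0?
#' @return Delivered rate, mL/h.
#' @export
quantize_rate <- function(requested, spec, active = TRUE, kvo = FALSE) {
  stopifnot(all(requested >= 0))
  if (!active) return(rep(if (kvo) spec$kvo_rate else 0, length(requested)))
  q <- floor(requested / spec$rate_step + 0.5 + 1e-9) * spec$rate_step
  pmin(pmax(q, spec$rate_min), spec$rate_max)
}

#' Convert a delivered pump rate into a drug/substrate flux
#'
#' @param rate Delivered rate, mL/h.
#' @param spec [pump_spec()].
#' @return Flux per minute: mIU/min for an insulin line
#'   (IU/mL * mL/h -> mIU/min), mg/min for a dextrose line.
#' @export
delivered_dose <- function(rate, spec) {
  if (spec$drug == "glucose") {
    rate * spec$concentration / 60           # mg/mL * mL/h -> mg/min
  } else {
    rate * spec$concentration * 1000 / 60    # IU/mL * mL/h -> mIU/min
  }
}
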