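#' Challenge scenario
#'
#' A timed list of challenge events over a simulation span.
#'
#' @param events List of [challenge_event()] objects, sorted by start time.
#' @param duration Simulated span, min.
#' @param name Optional scenario label.
#' @return An object of class `aiis_scenario`.
#' @export
scenario <- function(events = list(), duration = 1440, name = "custom") {
  stopifnot(duration > 0)
  if (length(events)) {
    starts <- vapply(events, function(e) e$t_start, numeric(1))
    if (is.unsorted(starts)) stop("events must be sorted by time")
    if (any(starts < 0 | starts > duration))
      stop("all events must fall within the simulation span")
  }
  structure(list(events = events, duration = duration, name = name),
            class = "aiis_scenario")
}

#' Build one of the four standard challenge scenarios
#'
#' Single-perturbation 24-hour scenarios with the challenge at hour 10:00
#' (minute 600):
#'
#' * `mild`: a standard meal with 50 g of complex carbohydrate (slow
#'   gastric emptying).
#' * `moderate`: 50 g of oral glucose (fast gastric emptying).
#' * `severe`: 10 g of glucose IV (20 mL of 50% dextrose) over 30 s.
#' * `negative`: 10 IU of regular insulin IV over 2 s.
#'
#' @param kind Challenge name, one of `"mild"`, `"moderate"`, `"severe"`,
#'   `"negative"`.
#' @param challenge_time Perturbation time, min.
#' @param duration Scenario span, min.
#' @return An [scenario()].
#' @export
build_scenario <- function(kind = c("mild", "moderate", "severe", "negative"),
                           challenge_time = 600, duration = 1440) {
  kind <- match.arg(kind)
  ev <- switch(kind,
    mild     = challenge_event("meal_complex_CHO", challenge_time, 50),
    moderate = challenge_event("oral_glucose", challenge_time, 50),
    severe   = challenge_event("iv_glucose_bolus", challenge_time, 10),
    negative = challenge_event("iv_insulin_bolus", challenge_time, 10)
  )
  scenario(list(ev), duration = duration, name = kind)
}
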