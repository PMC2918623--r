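#' Challenge response metrics
#'
#' Computes the stability metrics of a glycemia trace after a challenge:
#'
#' * overshoot: peak glycemia and total minutes above the overshoot
#'   threshold (140 mg/dL);
#' * undershoot: nadir glycemia and total minutes below the hypoglycemia
#'   threshold (60 mg/dL);
#' * `settling_time_Ts`: minutes from the challenge until glycemia enters
#'   the acceptance band (90--120 mg/dL) and remains inside it for the
#'   rest of the horizon (the stabilization, last-exit definition);
#' * `ts_first_below_high`: minutes until glycemia, having exceeded the
#'   upper band edge, falls back to it and never exceeds it again (the
#'   first-return definition quoted alongside figures); 0 if the band
#'   edge was never exceeded.
#'
#' Durations are accumulated over the sampled series with its own time
#' step, so the function is exactly reproducible by a brute-force scan of
#' the discretized trace.  Metrics are computed on true glycemia, not the
#' sensor estimate.
#'
#' @param series Data frame with columns `t` (min) and `G` (mg/dL) on a
#'   uniform time grid covering the challenge through the end of the run.
#' @param challenge_t Challenge time, min; metrics are computed on
#'   `t >= challenge_t`.
#' @param band_low,band_high Acceptance band, mg/dL.
#' @param over,under Overshoot / undershoot thresholds, mg/dL.
#' @return An object of class `aiis_metrics`: a named list with fields
#'   `overshoot_peak`, `overshoot_duration`, `undershoot_peak`,
#'   `undershoot_duration`, `settling_time_Ts`, `ts_first_below_high`,
#'   `had_overshoot`, `had_undershoot`, `g_max`, `g_min`.
#'   `settling_time_Ts` is `NA` if the trace never settles.
#' @export
compute_metrics <- function(series, challenge_t, band_low = 90,
                            band_high = 120, over = 140, under = 60) {
  stopifnot(all(c("t", "G") %in% names(series)))
  s <- series[series$t >= challenge_t, , drop = FALSE]
  if (nrow(s) < 2) stop("series must cover the challenge through the end")
  dt <- diff(s$t[1:2])
  g <- s$G
  g_max <- max(g); g_min <- min(g)
  had_over <- g_max > over
  had_under <- g_min < under
  in_band <- g >= band_low & g <= band_high
  # last index at which the trace is outside the band
  last_out <- if (all(in_band)) 0L else max(which(!in_band))
  ts <- if (last_out == length(g)) NA_real_ else s$t[last_out + 1L] - challenge_t
  above <- g > band_high
  last_above <- if (!any(above)) 0L else max(which(above))
  ts_first <- if (last_above == 0L) 0
              else if (last_above == length(g)) NA_real_
              else s$t[last_above + 1L] - challenge_t
  structure(list(
    overshoot_peak = if (had_over) g_max else NA_real_,
    overshoot_duration = sum(g > over) * dt,
    undershoot_peak = if (had_under) g_min else NA_real_,
    undershoot_duration = sum(g < under) * dt,
    settling_time_Ts = ts,
    ts_first_below_high = ts_first,
    had_overshoot = had_over,
    had_undershoot = had_under,
    g_max = g_max,
    g_min = g_min
  ), class = "aiis_metrics")
}

#' @export
print.aiis_metrics <- function(x, ...) {
  cat("Challenge metrics\n")
  cat(sprintf("  overshoot : peak %s mg/dL, duration %.1f min\n",
              if (x$had_overshoot) sprintf("%.1f", x$overshoot_peak) else "none",
              x$overshoot_duration))
  cat(sprintf("  undershoot: peak %s mg/dL, duration %.1f min\n",
              if (x$had_undershoot) sprintf("%.1f", x$undershoot_peak) else "none",
              x$undershoot_duration))
  cat(sprintf("  settling  : Ts %s min (stabilization), %s min (first return)\n",
              ifelse(is.na(x$settling_time_Ts), "undefined",
                     sprintf("%.1f", x$settling_time_Ts)),
              ifelse(is.na(x$ts_first_below_high), "undefined",
                     sprintf("%.1f", x$ts_first_below_high))))
  invisible(x)
}
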