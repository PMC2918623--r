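#' Subcutaneous glucose sensor parameters
#'
#' First-order lag model of the amperometric needle sensor: the current
#' `S(t)` follows `dS/dt = (alpha * G(t - T_D) - S) / tau`, is sampled
#' every 10 s with additive white Gaussian noise, and the 30 raw samples
#' of each 5-minute window are averaged, converted back to glucose through
#' the gain `alpha`, and clamped to the 40--400 mg/dL reporting range.
#'
#' @param alpha Sensitivity, nA per mg/dL.
#' @param tau Time constant, min.  With `T_D = 0` the signal reaches 63%
#'   of an equilibrium change `tau` minutes after a step in glycemia.
#' @param T_D Transport lag, min.
#' @param noise_variance Variance of the additive Gaussian noise on each
#'   raw current sample, nA^2 (mean 0).
#' @param ... Overrides for the remaining fields of
#'   `aiis_defaults()$sensor` (`sample_period`, `averaging_window`,
#'   `sat_low`, `sat_high`).
#' @return An object of class `aiis_sensor`.
#' @export
sensor_params <- function(alpha = 0.23, tau = 5.77, T_D = 0,
                          noise_variance = 100, ...) {
  p <- modifyList(aiis_defaults()$sensor,
                  c(list(alpha = alpha, tau = tau, T_D = T_D,
                         noise_variance = noise_variance), list(...)))
  stopifnot(
    "alpha must be > 0" = p$alpha > 0,
    "tau must be > 0" = p$tau > 0,
    "T_D must be >= 0" = p$T_D >= 0,
    "noise_variance must be >= 0" = p$noise_variance >= 0,
    "saturation limits must satisfy sat_low < sat_high" =
      p$sat_low < p$sat_high,
    "sample_period must divide the averaging window" =
      (p$averaging_window * 60) %% p$sample_period == 0
  )
  structure(p, class = "aiis_sensor")
}

#' Sensor current dynamics
#'
#' @param S Sensor current, nA.
#' @param G Glycemia already delayed by the transport lag, mg/dL.
#' @param p [sensor_params()].
#' @return `dS/dt`, nA/min.
#' @export
sensor_dynamics <- function(S, G, p) {
  if (p$tau <= 0) stop("tau must be > 0")
  (p$alpha * G - S) / p$tau
}

#' Draw one raw noisy sensor sample
#'
#' Adds white Gaussian noise (mean 0, variance `noise_variance`) to the
#' instantaneous sensor current.  Uses the calling R session's RNG stream;
#' the closed-loop engine pre-draws all samples from one seeded stream.
#'
#' @param S Sensor current, nA.
#' @param p [sensor_params()].
#' @return A noisy sample, nA.
#' @export
sample_raw <- function(S, p) {
  S + rnorm(length(S), 0, sqrt(p$noise_variance))
}

#' Emit a 5-minute averaged sensor reading
#'
#' Averages a full window of raw current samples, converts to glucose via
#' the gain `alpha` and clamps to the reporting range.
#'
#' @param buffer Numeric vector of raw samples (nA) covering one full
#'   averaging window.
#' @param t Timestamp of the reading (end of the window), min.
#' @param p [sensor_params()].
#' @return A list with `t` (min) and `G_est` (mg/dL).
#' @export
emit_reading <- function(buffer, t, p) {
  n_expected <- p$averaging_window * 60 / p$sample_period
  if (length(buffer) < n_expected)
    stop("partial averaging window: no reading emitted")
  g <- mean(buffer) / p$alpha
  list(t = t, G_est = min(max(g, p$sat_low), p$sat_high))
}

#' Open-loop sensor simulation on a known glucose trajectory
#'
#' Integrates the sensor lag exactly over each raw sampling interval
#' (exponential update, glucose held at the interval start), applies the
#' transport lag, adds per-sample noise and emits 5-minute averaged
#' readings.  Used for sensor characterization independently of the
#' closed loop.
#'
#' @param g_fun Function of time (min) returning true glycemia, mg/dL.
#' @param duration Simulated span, min.
#' @param p [sensor_params()].
#' @param noise Optional pre-drawn vector of noise values (nA), one per
#'   raw sample; `NULL` draws from the current RNG stream; `FALSE`
#'   disables noise.
#' @param S0 Initial current, nA; default is equilibrium with `g_fun(0)`.
#' @return A list with data frames `raw` (`t`, `S`, `sample`) and
#'   `readings` (`t`, `G_est`).
#' @export
simulate_sensor <- function(g_fun, duration, p = sensor_params(),
                            noise = NULL, S0 = NULL) {
  sp <- p$sample_period / 60                   # min
  n <- floor(duration / sp + 1e-9)
  if (is.null(S0)) S0 <- p$alpha * g_fun(0)
  eps <- if (isFALSE(noise)) rep(0, n)
         else if (is.null(noise)) rnorm(n, 0, sqrt(p$noise_variance))
         else rep_len(noise, n)
  decay <- exp(-sp / p$tau)
  S <- numeric(n); tgrid <- (1:n) * sp
  s_cur <- S0
  for (i in seq_len(n)) {
    # exact exponential update over the interval, glucose held at its
    # (lag-shifted) midpoint value
    g_del <- g_fun(max(tgrid[i] - sp / 2 - p$T_D, 0))
    s_eq <- p$alpha * g_del
    s_cur <- s_eq + (s_cur - s_eq) * decay
    S[i] <- s_cur
  }
  samples <- S + eps
  per_win <- p$averaging_window * 60 / p$sample_period
  n_read <- floor(n / per_win)
  readings <- data.frame(t = numeric(n_read), G_est = numeric(n_read))
  for (k in seq_len(n_read)) {
    idx <- ((k - 1) * per_win + 1):(k * per_win)
    r <- emit_reading(samples[idx], tgrid[k * per_win], p)
    readings$t[k] <- r$t; readings$G_est[k] <- r$G_est
  }
  list(raw = data.frame(t = tgrid, S = S, sample = samples),
       readings = readings)
}

#' Noise-free step response of the sensor
#'
#' Closed-form fractional response to a glycemia step at `t = 0`, with the
#' sensor initially at equilibrium: `1 - exp(-(t - T_D)/tau)` for
#' `t > T_D`, 0 before.
#'
#' @param t Time since the step, min (vectorized).
#' @param p [sensor_params()].
#' @return Fraction of the equilibrium signal change attained, in `[0, 1]`.
#' @export
sensor_step_response <- function(t, p = sensor_params()) {
  ifelse(t <= p$T_D, 0, 1 - exp(-(t - p$T_D) / p$tau))
}
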