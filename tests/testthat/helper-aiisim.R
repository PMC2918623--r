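# Shared fixtures: default parameter objects and cached challenge runs.
# Replicated closed-loop runs are expensive enough to share across tests;
# everything is generated in code under fixed seeds.

default_patient <- patient_params()
default_sensor <- sensor_params()
default_controller <- controller_params()
pumps2 <- default_pumps()

.run_cache <- new.env(parent = emptyenv())

# 11 seeded replicates of a standard challenge at given weight/Sh
challenge_runs <- function(kind, weight = 70, Sh = 0.5, n = 11) {
  key <- paste(kind, weight, Sh, n, sep = "_")
  if (is.null(.run_cache[[key]])) {
    pat <- if (weight == 70 && Sh == 0.5) default_patient
           else patient_params(body_weight = weight, Sh = Sh)
    .run_cache[[key]] <- lapply(seq_len(n), function(s)
      run_closed_loop(patient = pat, scn = build_scenario(kind), seed = s))
  }
  .run_cache[[key]]
}

challenge_metric <- function(runs, field) {
  vapply(runs, function(r) r$metrics[[field]], numeric(1))
}

# brute-force metrics oracle: literal scan of the discretized trace
metrics_oracle <- function(t, g, challenge_t, band_low = 90, band_high = 120,
                           over = 140, under = 60) {
  keep <- t >= challenge_t
  t <- t[keep]; g <- g[keep]
  dt <- t[2] - t[1]
  in_band <- g >= band_low & g <= band_high
  ts <- NA_real_
  for (i in seq_along(g)) {
    if (all(in_band[i:length(g)])) { ts <- t[i] - challenge_t; break }
  }
  above <- g > band_high
  tf <- if (!any(above)) 0 else {
    la <- max(which(above))
    if (la == length(g)) NA_real_ else t[la + 1] - challenge_t
  }
  list(g_max = max(g), g_min = min(g),
       overshoot_duration = sum(g > over) * dt,
       undershoot_duration = sum(g < under) * dt,
       settling_time_Ts = ts, ts_first_below_high = tf)
}
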