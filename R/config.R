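#' Load and validate a run configuration
#'
#' Reads a YAML or JSON configuration with any subset of the blocks
#' `patient`, `sensor`, `controller`, `pumps` (sub-blocks `insulin`,
#' `glucose`), `scenario` (`kind`, `challenge_time`, `duration`),
#' `engine` (`dt`), and the scalars `seed` and `output_dir`.  Missing
#' values fall back to the documented defaults ([aiis_defaults()]); every
#' block is validated through its constructor before any simulation can
#' start.  Unknown keys are rejected by name.
#'
#' @param path Path to a `.yaml`/`.yml`/`.json` file.  An empty file (or
#'   empty list) yields the full default configuration.
#' @return An object of class `aiis_config`: list with validated
#'   `patient`, `sensor`, `controller`, `pumps`, `scenario`, `engine`,
#'   `seed`, `output_dir`.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::fromJSON(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  if (is.null(raw)) raw <- list()
  validate_config(raw)
}

#' Validate a configuration list
#'
#' @param raw Named list as produced by parsing a config file.
#' @return A validated `aiis_config`; errors name the offending key and
#'   constraint.
#' @export
validate_config <- function(raw) {
  known <- c("patient", "sensor", "controller", "pumps", "scenario",
             "engine", "seed", "output_dir")
  unknown <- setdiff(names(raw), known)
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  d <- aiis_defaults()
  check_keys <- function(block, allowed, where) {
    bad <- setdiff(names(block), allowed)
    if (length(bad))
      stop("unknown key(s) in '", where, "': ", paste(bad, collapse = ", "))
    block
  }
  pat_raw <- check_keys(raw$patient %||% list(),
                        names(d$patient), "patient")
  patient <- validate_patient(merge_defaults(d$patient, pat_raw))
  sen_raw <- check_keys(raw$sensor %||% list(), names(d$sensor), "sensor")
  sensor <- do.call(sensor_params, merge_defaults(d$sensor, sen_raw))
  con_raw <- check_keys(raw$controller %||% list(),
                        names(d$controller), "controller")
  controller <- do.call(controller_params, merge_defaults(d$controller, con_raw))
  pmp_raw <- check_keys(raw$pumps %||% list(), c("insulin", "glucose"),
                        "pumps")
  pumps <- list(
    insulin = do.call(pump_spec, merge_defaults(
      d$pumps$insulin,
      check_keys(pmp_raw$insulin %||% list(), names(d$pumps$insulin),
                 "pumps$insulin"))),
    glucose = do.call(pump_spec, merge_defaults(
      d$pumps$glucose,
      check_keys(pmp_raw$glucose %||% list(), names(d$pumps$glucose),
                 "pumps$glucose"))))
  scn_raw <- check_keys(raw$scenario %||% list(),
                        c("kind", "challenge_time", "duration"), "scenario")
  scn <- build_scenario(scn_raw$kind %||% "mild",
                        challenge_time = scn_raw$challenge_time %||%
                          d$engine$challenge_time,
                        duration = scn_raw$duration %||% d$engine$duration)
  eng_raw <- check_keys(raw$engine %||% list(),
                        names(d$engine), "engine")
  engine <- merge_defaults(d$engine, eng_raw)
  structure(list(patient = patient, sensor = sensor,
                 controller = controller, pumps = pumps, scenario = scn,
                 engine = engine,
                 seed = as.integer(raw$seed %||% 1L),
                 output_dir = raw$output_dir %||% "."),
            class = "aiis_config")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# element-wise merge of a (possibly nested) override list into defaults
merge_defaults <- function(defaults, override) {
  if (!length(override)) return(defaults)
  modifyList(defaults, override)
}

#' Serialize a configuration back to YAML
#'
#' `load_config(dump_config(cfg, f))` reproduces `cfg`: loading, dumping
#' and re-loading is idempotent.
#'
#' @param cfg An `aiis_config`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
dump_config <- function(cfg, path) {
  plain <- list(
    patient = unclass(cfg$patient),
    sensor = unclass(cfg$sensor),
    controller = unclass(cfg$controller),
    pumps = lapply(cfg$pumps, function(p) unclass(p)),
    scenario = list(kind = cfg$scenario$name,
                    challenge_time = if (length(cfg$scenario$events))
                      cfg$scenario$events[[1]]$t_start else 600,
                    duration = cfg$scenario$duration),
    engine = cfg$engine,
    seed = cfg$seed,
    output_dir = cfg$output_dir)
  plain$patient$active_insulin_rates <-
    as.list(plain$patient$active_insulin_rates)
  yaml::write_yaml(plain, path, precision = 15)
  invisible(path)
}

#' Write the standard output files of a run
#'
#' Writes `series.csv` (full time series), `trace.csv` (controller
#' trace), `metrics.csv` (one row mirroring the challenge-table layout:
#' overshoot peak/duration, undershoot peak/duration, both settling-time
#' definitions) and `config.json` (full parameter snapshot).  Numeric
#' columns are written with 17 significant digits so reading them back
#' reproduces the values bit-exactly.
#'
#' @param result An `aiis_result` from [run_closed_loop()].
#' @param dir Output directory (created if needed).
#' @return Character vector of the written paths, invisibly.
#' @export
write_outputs <- function(result, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- file.path(dir, c("series.csv", "trace.csv", "metrics.csv",
                            "config.json"))
  write_csv_exact(result$series, paths[1])
  write_csv_exact(result$trace, paths[2])
  m <- result$metrics
  metrics_df <- data.frame(
    scenario = result$scenario, seed = result$seed,
    challenge_t = result$challenge_t,
    overshoot_peak = m$g_max, overshoot_duration = m$overshoot_duration,
    undershoot_peak = m$g_min,
    undershoot_duration = m$undershoot_duration,
    settling_time_Ts = m$settling_time_Ts,
    ts_first_below_high = m$ts_first_below_high,
    had_overshoot = m$had_overshoot, had_undershoot = m$had_undershoot)
  write_csv_exact(metrics_df, paths[3])
  jsonlite::write_json(result$config, paths[4], auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(paths)
}

# CSV with full-precision numerics (RFC 4180 via write.csv)
write_csv_exact <- function(df, path) {
  out <- df
  for (j in seq_along(out))
    if (is.double(out[[j]])) out[[j]] <- sprintf("%.17g", out[[j]])
  write.csv(out, path, row.names = FALSE, quote = FALSE)
}
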