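# End-to-end orchestration: simulate -> extract crossings -> classify ->
# summarize logger episodes -> wind hypotheses -> fit models, with a config
# file, per-stage logging, and a manifest of content-hashed artifacts.

log_msg <- function(...) message(format(Sys.time(), "%H:%M:%S "), ...)

#' Validate a pipeline run configuration
#'
#' A run config is a YAML file (or equivalent list) with top-level keys
#' `seed`, `out_dir`, `scenario` (forwarded to [sim_config()]) and optional
#' `params` (module tuning: `airspeed`, `step_km`, `owd_method`, `zenith`).
#' Unknown keys are rejected; referenced input paths must exist.
#'
#' @param config path to a YAML file, or a list.
#' @return normalized config list.
#' @export
validate_run_config <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config)) stop("config file not found: ", config)
    config <- yaml::read_yaml(config)
  }
  allowed <- c("seed", "out_dir", "scenario", "params", "inputs")
  unknown <- setdiff(names(config), allowed)
  if (length(unknown)) stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  if (is.null(config$seed)) config$seed <- 1L
  if (is.null(config$out_dir)) stop("config needs an out_dir")
  for (key in names(config$inputs)) {
    if (!file.exists(config$inputs[[key]]))
      stop("input path for '", key, "' does not exist: ", config$inputs[[key]])
  }
  defaults <- list(airspeed = 10, step_km = 1, owd_method = "longest",
                   zenith = 90.833, n_trapping = 95)
  config$params <- modifyList(defaults, if (is.null(config$params)) list() else config$params)
  config
}

#' Run the full sea-crossing pipeline
#'
#' Simulates a study data set under the configured scenario (or reads the
#' configured input files), writes the interchange files, extracts water
#' crossings with day/night outcomes, summarizes logger episodes by period,
#' evaluates the wind hypotheses on the first track, fits the statistical
#' layer, and writes a manifest listing every artifact with its MD5 hash.
#' Deterministic under a fixed seed.
#'
#' @param config YAML path or list; see [validate_run_config()].
#' @return the manifest, invisibly (list with `artifacts`, `config`).
#' @export
run_pipeline <- function(config) {
  config <- validate_run_config(config)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  artifacts <- character()
  keep <- function(path) { artifacts <<- c(artifacts, path); path }

  scen <- if (is.null(config$scenario)) list() else config$scenario
  scen$seed <- config$seed
  cfg <- do.call(sim_config, scen)
  coast <- do.call(generate_coastline, cfg$coastline_spec)

  log_msg("stage simulate: ", cfg$n_individuals, " individual(s)")
  gps <- generate_gps_dataset(cfg, coast)
  write_gps_csv(gps$fixes, keep(file.path(config$out_dir, "gps_fixes.csv")))
  write_coastline_geojson(coast, keep(file.path(config$out_dir, "coastline.geojson")))

  night0 <- as.POSIXct("2020-09-05 20:00:00", tz = "UTC")
  plan <- data.frame(start = c(night0, night0 + 10 * 3600),
                     end = c(night0 + 10 * 3600, night0 + 20 * 3600),
                     mode = c("flapping", "flap-glide"),
                     altitude_m = c(cfg$altitude_night_m, cfg$altitude_day_m))
  stream <- generate_sensor_stream(cfg, plan)
  write_sensor_csv(stream, keep(file.path(config$out_dir, "sensor_stream.csv")))

  trapping <- generate_trapping_records(cfg, n = config$params$n_trapping)
  write_trapping_csv(trapping, keep(file.path(config$out_dir, "trapping.csv")))

  log_msg("stage crossings")
  crossings <- extract_crossings(gps$fixes, coast,
                                 fix_hours_utc = cfg$fix_hours_utc,
                                 step_km = config$params$step_km,
                                 owd_method = config$params$owd_method)
  write_crossing_csv(crossings, keep(file.path(config$out_dir, "crossings.csv")))

  log_msg("stage mdl")
  episodes <- segment_flight_episodes(stream)
  period_summary <- summarize_periods(episodes, stream)
  utils::write.csv(period_summary,
                   keep(file.path(config$out_dir, "period_summary.csv")),
                   row.names = FALSE)

  log_msg("stage wind")
  first <- gps$fixes[gps$fixes$individual == gps$fixes$individual[1] &
                       gps$fixes$track == gps$fixes$track[1], ]
  bbox <- c(min(first$lon) - 5, max(first$lon) + 5,
            min(first$lat) - 2, max(first$lat) + 2)
  wtimes <- seq(trunc(min(first$t), "days"), max(first$t) + 86400, by = 6 * 3600)
  field <- generate_wind_field(cfg$wind_spec, bbox, wtimes, seed = config$seed)
  write_wind_csv(field, keep(file.path(config$out_dir, "wind_field.csv")))
  profile <- wind_profit_profile(first, field, airspeed = cfg$airspeed)
  hyp <- evaluate_hypotheses(profile, nocturnal_level = nearest_level(cfg$altitude_night_m),
                             airspeed = cfg$airspeed)
  jsonlite::write_json(hyp$summary,
                       keep(file.path(config$out_dir, "wind_hypotheses.json")),
                       dataframe = "rows", auto_unbox = TRUE, digits = NA)

  log_msg("stage stats")
  models <- list()
  if (nrow(crossings) >= 4 && length(unique(crossings$individual)) >= 2 &&
      length(unique(crossings$diurnal)) == 2)
    models$diurnal_glmm <- fit_diurnal_glmm(crossings)
  models$bodymass_ols <- fit_bodymass_ols(trapping)
  if (nrow(crossings) >= 2)
    models$groundspeed_t <- one_sample_t(mean(crossings$v_g_ms),
                                         sd(crossings$v_g_ms),
                                         nrow(crossings), mu0 = cfg$airspeed)
  model_json <- lapply(models, function(m)
    if (inherits(m, "nx_model_result"))
      list(model = m$model, coefficients = m$coefficients, ranef = m$ranef,
           converged = m$converged, flags = m$flags) else m)
  jsonlite::write_json(model_json, keep(file.path(config$out_dir, "models.json")),
                       dataframe = "rows", auto_unbox = TRUE, digits = NA,
                       force = TRUE)

  manifest <- list(
    config = config[setdiff(names(config), "out_dir")],
    artifacts = data.frame(path = basename(artifacts),
                           md5 = unname(tools::md5sum(artifacts))))
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       dataframe = "rows", auto_unbox = TRUE, digits = NA)
  log_msg("done: ", length(artifacts), " artifact(s)")
  invisible(manifest)
}
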