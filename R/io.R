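# Plain-text interchange: GPS fixes, sensor streams, wind fields and
# trapping records as CSV (timestamps ISO-8601 UTC; unit suffixes in column
# names), coastlines as GeoJSON.

fmt_utc <- function(t) format(t, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")
parse_utc <- function(x) as.POSIXct(x, format = "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")

#' Write and read GPS fix tables
#'
#' Columns: `id`, `timestamp_iso8601_utc`, `lat`, `lon` (plus any extras on
#' write). Reading restores `individual`, `t` (`POSIXct` UTC), `lat`, `lon`.
#'
#' @param fixes data frame `individual`, `t`, `lat`, `lon`.
#' @param path CSV file.
#' @return `path` invisibly; the fix data frame for the reader.
#' @export
write_gps_csv <- function(fixes, path) {
  out <- data.frame(id = fixes$individual,
                    timestamp_iso8601_utc = fmt_utc(fixes$t),
                    lat = fixes$lat, lon = fixes$lon)
  extra <- setdiff(names(fixes), c("individual", "t", "lat", "lon"))
  for (cl in extra) out[[cl]] <- fixes[[cl]]
  write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_gps_csv
#' @export
read_gps_csv <- function(path) {
  x <- read.csv(path, stringsAsFactors = FALSE)
  out <- data.frame(individual = x$id, t = parse_utc(x$timestamp_iso8601_utc),
                    lat = x$lat, lon = x$lon)
  for (cl in setdiff(names(x), c("id", "timestamp_iso8601_utc", "lat", "lon")))
    out[[cl]] <- x[[cl]]
  out
}

#' Write and read multisensor streams
#'
#' Columns: `id`, `timestamp_iso8601_utc`, `pressure_hpa`, `n_active`,
#' `n_samples`.
#'
#' @param stream data frame `t`, `pressure_hpa`, `n_active`, `n_samples`.
#' @param id individual id stored with the stream.
#' @param path CSV file.
#' @export
write_sensor_csv <- function(stream, path, id = "bird01") {
  write.csv(data.frame(id = id, timestamp_iso8601_utc = fmt_utc(stream$t),
                       pressure_hpa = stream$pressure_hpa,
                       n_active = stream$n_active,
                       n_samples = stream$n_samples),
            path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_sensor_csv
#' @export
read_sensor_csv <- function(path) {
  x <- read.csv(path, stringsAsFactors = FALSE)
  data.frame(individual = x$id, t = parse_utc(x$timestamp_iso8601_utc),
             pressure_hpa = x$pressure_hpa, n_active = x$n_active,
             n_samples = x$n_samples)
}

#' Write and read wind fields as long-format CSV
#'
#' Columns: `timestamp_iso8601_utc`, `level`, `lat`, `lon`, `u_ms`, `v_ms`.
#' The long CSV is the package's gridded-wind interchange format (dims
#' time x level x lat x lon, wind components in m s^-1).
#'
#' @param field wind field data frame (`time`, `level`, `lat`, `lon`, `u`,
#'   `v`).
#' @param path CSV file.
#' @export
write_wind_csv <- function(field, path) {
  write.csv(data.frame(timestamp_iso8601_utc = fmt_utc(field$time),
                       level = field$level, lat = field$lat, lon = field$lon,
                       u_ms = field$u, v_ms = field$v),
            path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_wind_csv
#' @export
read_wind_csv <- function(path) {
  x <- read.csv(path, stringsAsFactors = FALSE, colClasses = c(level = "character"))
  out <- data.frame(time = parse_utc(x$timestamp_iso8601_utc),
                    level = x$level, lat = x$lat, lon = x$lon,
                    u = x$u_ms, v = x$v_ms)
  structure(out, class = c("nx_windfield", "data.frame"))
}

#' Write and read trapping records
#'
#' Columns: `date`, `hour_local`, `mass_g`.
#'
#' @param records data frame from [generate_trapping_records()].
#' @param path CSV file.
#' @export
write_trapping_csv <- function(records, path) {
  write.csv(records, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_trapping_csv
#' @export
read_trapping_csv <- function(path) {
  x <- read.csv(path, stringsAsFactors = FALSE)
  x$date <- as.Date(x$date)
  x
}

#' Write a crossing table as CSV
#'
#' One row per crossing with `owd_km`, `v_g_ms`, `completed_km`,
#' `remaining_km`, ISO-8601 `t_init`/`t_arr` and the `diurnal` outcome.
#'
#' @param crossings from [extract_crossings()].
#' @param path CSV file.
#' @export
write_crossing_csv <- function(crossings, path) {
  out <- crossings
  out$t_init <- fmt_utc(out$t_init)
  out$t_arr <- fmt_utc(out$t_arr)
  write.csv(out, path, row.names = FALSE)
  invisible(path)
}
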