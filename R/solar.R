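# Solar position after the NOAA solar-calculator algorithm (low-accuracy
# ephemeris of Meeus). Declination and the equation of time evaluated at a
# fractional Julian day; event times refined by fixed-point iteration.

.deg2rad <- pi / 180

solar_decl_eqtime <- function(jd) {
  jc <- (jd - 2451545) / 36525
  L0 <- (280.46646 + jc * (36000.76983 + jc * 0.0003032)) %% 360
  M <- 357.52911 + jc * (35999.05029 - 0.0001537 * jc)
  ecc <- 0.016708634 - jc * (0.000042037 + 0.0000001267 * jc)
  C <- sin(M * .deg2rad) * (1.914602 - jc * (0.004817 + 0.000014 * jc)) +
    sin(2 * M * .deg2rad) * (0.019993 - 0.000101 * jc) +
    sin(3 * M * .deg2rad) * 0.000289
  omega <- 125.04 - 1934.136 * jc
  lambda <- L0 + C - 0.00569 - 0.00478 * sin(omega * .deg2rad)
  e0 <- 23 + (26 + (21.448 - jc * (46.815 + jc * (0.00059 - jc * 0.001813))) / 60) / 60
  eps <- e0 + 0.00256 * cos(omega * .deg2rad)
  decl <- asin(sin(eps * .deg2rad) * sin(lambda * .deg2rad)) / .deg2rad
  y <- tan(eps / 2 * .deg2rad)^2
  eqtime <- 4 / .deg2rad *
    (y * sin(2 * L0 * .deg2rad) - 2 * ecc * sin(M * .deg2rad) +
       4 * ecc * y * sin(M * .deg2rad) * cos(2 * L0 * .deg2rad) -
       0.5 * y^2 * sin(4 * L0 * .deg2rad) -
       1.25 * ecc^2 * sin(2 * M * .deg2rad))
  list(decl = decl, eqtime = eqtime)
}

julian_day_0h <- function(date) {
  # JD at 00:00 UTC of a Date
  as.numeric(date) + 2440587.5
}

#' Sunrise and sunset at a position and date
#'
#' Solar events from standard solar geometry (NOAA algorithm), accurate to
#' well under two minutes for latitudes below the polar circles. Daylight is
#' delimited at the conventional refraction-corrected zenith of 90.833
#' degrees (sun centre 50 arc-minutes below the horizon), not civil
#' twilight.
#'
#' @param position `c(lon, lat)` degrees.
#' @param date a `Date` (or string coercible to one); the UTC calendar day.
#' @param zenith zenith angle defining the horizon, degrees.
#' @return list with `sunrise_utc` and `sunset_utc` (`POSIXct`, UTC; `NA`
#'   under polar day or night), `polar` (`"day"`, `"night"` or `NA`), and
#'   the inputs.
#' @export
#' @examples
#' sun_events(c(16.21, 57.34), as.Date("2020-09-05"))
sun_events <- function(position, date, zenith = 90.833) {
  position <- drop(as_lonlat(position))
  date <- as.Date(date)
  lon <- position[1]; lat <- position[2]
  jd0 <- julian_day_0h(date)

  event_minutes <- function(rise) {
    t_frac <- 0.5 - lon / 360  # approximate solar noon, fraction of day UTC
    for (i in 1:3) {
      sp <- solar_decl_eqtime(jd0 + t_frac)
      cos_ha <- cos(zenith * .deg2rad) /
        (cos(lat * .deg2rad) * cos(sp$decl * .deg2rad)) -
        tan(lat * .deg2rad) * tan(sp$decl * .deg2rad)
      if (cos_ha > 1) return(structure(NA_real_, polar = "night"))
      if (cos_ha < -1) return(structure(NA_real_, polar = "day"))
      ha <- acos(cos_ha) / .deg2rad
      minutes <- 720 - 4 * (lon + if (rise) ha else -ha) - sp$eqtime
      t_frac <- minutes / 1440
    }
    minutes
  }

  rise <- event_minutes(TRUE)
  set <- event_minutes(FALSE)
  polar <- attr(rise, "polar")
  midnight <- as.POSIXct(paste(date, "00:00:00"), tz = "UTC")
  to_time <- function(m) if (is.na(m)) as.POSIXct(NA) else midnight + as.numeric(m) * 60
  list(position = position, date = date,
       sunrise_utc = to_time(rise), sunset_utc = to_time(set),
       polar = if (is.null(polar)) NA_character_ else polar,
       zenith = zenith)
}

#' Classify an arrival time as diurnal or nocturnal
#'
#' An arrival is diurnal when it falls between sunrise and sunset at the
#' arrival position on the arrival's UTC calendar day; the boundary instants
#' themselves count as daylight.
#'
#' @param t_arr arrival time, `POSIXct` UTC.
#' @param position arrival position `c(lon, lat)`.
#' @param zenith horizon convention passed to [sun_events()].
#' @return logical: `TRUE` for a daylight arrival. Polar day returns `TRUE`,
#'   polar night `FALSE`.
#' @export
classify_arrival <- function(t_arr, position, zenith = 90.833) {
  stopifnot(inherits(t_arr, "POSIXct"))
  ev <- sun_events(position, as.Date(t_arr, tz = "UTC"), zenith = zenith)
  if (!is.na(ev$polar)) return(ev$polar == "day")
  t_arr >= ev$sunrise_utc && t_arr <= ev$sunset_utc
}
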