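# Multisensor-logger processing: accelerometer activity index, flight
# episode segmentation, crossing-period assignment (N1/D/N2), vertical
# speed, and identification of sea-crossing episodes between positional
# anchors.

#' Flight-activity index of an accelerometer interval
#'
#' Fraction of burst samples in the interval classified as active (flapping)
#' flight: `n_active / n_samples`. Logger generations use 60 or 120 samples
#' per interval; other totals are accepted with a warning.
#'
#' @param n_active number of active samples (vectorised).
#' @param n_samples total samples in the interval.
#' @return active fraction in \[0, 1\].
#' @export
#' @examples
#' activity_index(90, 120)  # 0.75
#' activity_index(45, 60)   # 0.75
activity_index <- function(n_active, n_samples) {
  if (any(n_active < 0) || any(n_active > n_samples))
    stop("need 0 <= n_active <= n_samples")
  if (!all(n_samples %in% c(60L, 120L)))
    warning("n_samples outside the usual logger totals (60, 120)")
  n_active / n_samples
}

#' Classify an acceleration burst as active flight
#'
#' A burst (5 or 10 vertical-acceleration samples at 100 ms) counts as
#' active flapping when its peak-to-peak amplitude exceeds a threshold.
#'
#' @param burst numeric vector of vertical accelerations, m s^-2.
#' @param threshold peak-to-peak amplitude threshold, m s^-2.
#' @return logical.
#' @export
burst_is_active <- function(burst, threshold = 2) {
  stopifnot(length(burst) >= 2, is.finite(threshold))
  diff(range(burst)) > threshold
}

#' Vertical speed from an altitude series
#'
#' Central finite differences of altitude over time; one-sided differences
#' at the endpoints. Unbiased for smooth trajectories at logger sampling
#' rates.
#'
#' @param altitude_m altitude series, m.
#' @param t sample times (`POSIXct` or numeric seconds).
#' @return vertical speed, m s^-1 (same length as input).
#' @export
vertical_speed <- function(altitude_m, t) {
  n <- length(altitude_m)
  stopifnot(n >= 2, length(t) == n)
  tt <- as.numeric(t)
  vs <- numeric(n)
  vs[1] <- (altitude_m[2] - altitude_m[1]) / (tt[2] - tt[1])
  vs[n] <- (altitude_m[n] - altitude_m[n - 1]) / (tt[n] - tt[n - 1])
  if (n > 2) {
    i <- 2:(n - 1)
    vs[i] <- (altitude_m[i + 1] - altitude_m[i - 1]) / (tt[i + 1] - tt[i - 1])
  }
  vs
}

#' Segment flight episodes from an activity series
#'
#' A flight episode is a maximal run of intervals whose smoothed activity
#' index stays at or above `threshold` for at least `min_duration_min`
#' minutes; single-interval dropouts inside a run are bridged. Smoothing is
#' a centred rolling mean over `smooth_k` intervals.
#'
#' @param activity data frame `t` (`POSIXct`, regular), `n_active`,
#'   `n_samples`.
#' @param threshold smoothed-index threshold for "in flight".
#' @param min_duration_min minimum episode duration, minutes.
#' @param smooth_k rolling-mean window (odd).
#' @param bridge_gaps maximum number of consecutive sub-threshold intervals
#'   bridged inside an episode.
#' @return data frame `start`, `end`, `duration_h`, `n_intervals`,
#'   `mean_activity`; zero rows if nothing qualifies.
#' @export
segment_flight_episodes <- function(activity, threshold = 0.5,
                                    min_duration_min = 30, smooth_k = 3,
                                    bridge_gaps = 1) {
  stopifnot(all(c("t", "n_active", "n_samples") %in% names(activity)))
  idx <- activity$n_active / activity$n_samples
  n <- length(idx)
  dt_s <- if (n > 1) median(diff(as.numeric(activity$t))) else Inf
  k <- max(1L, as.integer(smooth_k))
  half <- k %/% 2
  sm <- vapply(seq_len(n), function(i)
    mean(idx[max(1, i - half):min(n, i + half)]), numeric(1))
  flying <- sm >= threshold

  if (any(flying) && bridge_gaps > 0) {
    r <- rle(flying)
    ends <- cumsum(r$lengths)
    for (j in seq_along(r$lengths)) {
      if (!r$values[j] && r$lengths[j] <= bridge_gaps &&
          j > 1 && j < length(r$lengths))
        flying[(ends[j] - r$lengths[j] + 1):ends[j]] <- TRUE
    }
  }

  r <- rle(flying)
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1
  out <- NULL
  for (j in seq_along(r$lengths)) {
    if (!r$values[j]) next
    dur_s <- (r$lengths[j] - 1) * dt_s
    if (dur_s < min_duration_min * 60) next
    i0 <- starts[j]; i1 <- ends[j]
    out <- rbind(out, data.frame(
      start = activity$t[i0], end = activity$t[i1],
      duration_h = dur_s / 3600, n_intervals = i1 - i0 + 1L,
      mean_activity = mean(idx[i0:i1])))
  }
  if (is.null(out))
    out <- data.frame(start = as.POSIXct(character(), tz = "UTC"),
                      end = as.POSIXct(character(), tz = "UTC"),
                      duration_h = numeric(), n_intervals = integer(),
                      mean_activity = numeric())
  out
}

#' Assign crossing periods to timestamps
#'
#' UTC hours 21:00-03:00 are night and 06:00-16:00 day (hour labels 21-23
#' and 0-3 vs 6-16); other hours are unassigned. Night samples before the
#' episode's first day block are the first night (N1); night samples after
#' it are the second night (N2).
#'
#' @param times `POSIXct` UTC timestamps of one episode, sorted.
#' @return factor with levels `N1`, `D`, `N2`, `unassigned`, one per
#'   timestamp (every sample is assigned exactly one label).
#' @export
#' @examples
#' t0 <- as.POSIXct("2020-09-05 22:00", tz = "UTC")
#' assign_periods(t0 + c(0, 12, 19, 26) * 3600)
assign_periods <- function(times) {
  stopifnot(inherits(times, "POSIXct"), !is.unsorted(as.numeric(times)))
  hr <- as.integer(format(times, "%H", tz = "UTC"))
  base <- ifelse(hr %in% c(21:23, 0:3), "night",
                 ifelse(hr %in% 6:16, "D", "unassigned"))
  lab <- base
  first_day <- match("D", base)
  if (is.na(first_day)) {
    lab[base == "night"] <- "N1"
  } else {
    night <- base == "night"
    lab[night & seq_along(base) < first_day] <- "N1"
    lab[night & seq_along(base) > first_day] <- "N2"
  }
  factor(lab, levels = c("N1", "D", "N2", "unassigned"))
}

#' Per-period summaries of a flight episode
#'
#' Means of barometric altitude, vertical speed, and activity index within
#' the N1/D/N2 periods of each episode.
#'
#' @param episodes episode table from [segment_flight_episodes()].
#' @param stream sensor data frame `t`, `pressure_hpa`, `n_active`,
#'   `n_samples` (as written by [generate_sensor_stream()]).
#' @param individual id recorded in the output.
#' @param const [isa_constants()].
#' @return tidy data frame `individual`, `episode`, `period`,
#'   `mean_altitude_m`, `mean_vspeed_ms`, `mean_activity`, `n`.
#' @export
summarize_periods <- function(episodes, stream, individual = "bird01",
                              const = isa_constants()) {
  out <- NULL
  for (e in seq_len(nrow(episodes))) {
    seg <- stream[stream$t >= episodes$start[e] & stream$t <= episodes$end[e], ]
    if (nrow(seg) < 2) next
    alt <- pressure_to_altitude(seg$pressure_hpa, const)
    vs <- vertical_speed(alt, seg$t)
    per <- assign_periods(seg$t)
    for (p in c("N1", "D", "N2")) {
      sel <- per == p
      if (!any(sel)) next
      out <- rbind(out, data.frame(
        individual = individual, episode = e, period = p,
        mean_altitude_m = mean(alt[sel]),
        mean_vspeed_ms = mean(vs[sel]),
        mean_activity = mean(seg$n_active[sel] / seg$n_samples[sel]),
        n = sum(sel)))
    }
  }
  if (is.null(out))
    out <- data.frame(individual = character(), episode = integer(),
                      period = character(), mean_altitude_m = numeric(),
                      mean_vspeed_ms = numeric(), mean_activity = numeric(),
                      n = integer())
  out$period <- factor(out$period, levels = c("N1", "D", "N2"))
  out
}

#' Flag flight episodes as sea crossings
#'
#' Two independent criteria, either of which flags an episode:
#' \itemize{
#'   \item \emph{route}: positions interpolated between the bracketing
#'   anchors (known locations, e.g. geolocation fixes) at an assumed fixed
#'   ground speed place part of the episode over water;
#'   \item \emph{skimming}: the episode contains at least `skim_hours` of
#'   daylight flight below `skim_alt_m` barometric altitude — prolonged
#'   surface-skimming is only possible over open water.
#' }
#'
#' @param episodes episode table.
#' @param anchors data frame `t`, `lon`, `lat` of known positions, or `NULL`
#'   if unavailable (route criterion then returns `NA`).
#' @param land polygon set.
#' @param stream sensor stream (needed for the skimming criterion; `NULL`
#'   skips it).
#' @param groundspeed assumed fixed ground speed for the interpolation,
#'   m s^-1.
#' @param skim_alt_m,skim_hours skimming thresholds.
#' @param const [isa_constants()].
#' @return episode table with logical columns `route_over_water`,
#'   `skimming`, `is_sea_crossing`.
#' @export
identify_sea_crossing <- function(episodes, anchors, land, stream = NULL,
                                  groundspeed = 10, skim_alt_m = 10,
                                  skim_hours = 2, const = isa_constants()) {
  n <- nrow(episodes)
  route <- rep(NA, n); skim <- rep(NA, n)

  pos_at <- function(time) {
    # along the anchor-to-anchor great circle at fixed ground speed, capped
    tt <- as.numeric(anchors$t); q <- as.numeric(time)
    if (q <= tt[1]) return(c(anchors$lon[1], anchors$lat[1]))
    if (q >= tt[length(tt)])
      return(c(anchors$lon[nrow(anchors)], anchors$lat[nrow(anchors)]))
    i <- max(which(tt <= q))
    a <- c(anchors$lon[i], anchors$lat[i])
    b <- c(anchors$lon[i + 1], anchors$lat[i + 1])
    d <- min(groundspeed * (q - tt[i]) / 1000, gc_distance(a, b))
    if (d <= 0) a else gc_point_along(a, b, d)
  }

  for (e in seq_len(n)) {
    if (!is.null(anchors) &&
        as.numeric(anchors$t[1]) <= as.numeric(episodes$start[e]) &&
        as.numeric(anchors$t[nrow(anchors)]) >= as.numeric(episodes$end[e])) {
      probe <- seq(episodes$start[e], episodes$end[e], length.out = 25)
      pts <- t(vapply(probe, pos_at, numeric(2)))
      route[e] <- any(!point_on_land(land, pts[, 1], pts[, 2]))
    }
    if (!is.null(stream)) {
      seg <- stream[stream$t >= episodes$start[e] & stream$t <= episodes$end[e], ]
      if (nrow(seg) > 1) {
        alt <- pressure_to_altitude(seg$pressure_hpa, const)
        ref <- if (!is.null(anchors)) pos_at(episodes$start[e]) else NULL
        daylight <- if (is.null(ref)) rep(TRUE, nrow(seg)) else
          vapply(seg$t, classify_arrival, logical(1), position = ref)
        dt_h <- median(diff(as.numeric(seg$t))) / 3600
        skim[e] <- sum(alt < skim_alt_m & daylight) * dt_h >= skim_hours
      }
    }
  }
  episodes$route_over_water <- route
  episodes$skimming <- skim
  episodes$is_sea_crossing <- (!is.na(route) & route) | (!is.na(skim) & skim)
  episodes
}
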