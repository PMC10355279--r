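# Wind support along reconstructed tracks: gridded-wind sampling, the wind
# triangle with heading compensation at fixed airspeed, harmonic-mean ground
# speeds, and the two altitude-use hypotheses (H1: best level each hour;
# H2: fixed nocturnal level).

WIND_LEVELS <- c("surface", "1000", "925", "850", "700")

# Approximate altitudes of the analysis levels, m above sea level.
LEVEL_ALTITUDES_M <- c(surface = 10, `1000` = 100, `925` = 750,
                       `850` = 1500, `700` = 3000)

#' Map an altitude to the nearest analysis pressure level
#'
#' @param altitude_m altitude, m.
#' @return level name (`"surface"`, `"1000"`, `"925"`, `"850"`, `"700"`).
#' @export
nearest_level <- function(altitude_m) {
  names(LEVEL_ALTITUDES_M)[which.min(abs(LEVEL_ALTITUDES_M - altitude_m))]
}

#' Filter GPS altitude fixes for the nocturnal-level estimate
#'
#' GPS processing can yield negative altitudes, or altitudes locked to the
#' nearest 250-m interval when no clear solution is found in time; both are
#' excluded before averaging.
#'
#' @param altitude_m GPS altitude vector, m.
#' @return the retained altitudes.
#' @export
filter_gps_altitudes <- function(altitude_m) {
  keep <- altitude_m >= 0 & altitude_m %% 250 != 0
  altitude_m[keep & !is.na(keep)]
}

#' Sample a gridded wind field
#'
#' Multilinear interpolation in longitude, latitude and time at a fixed
#' pressure level.
#'
#' @param field wind field from [generate_wind_field()] or
#'   [read_wind_csv()].
#' @param time query time (`POSIXct`).
#' @param position `c(lon, lat)`.
#' @param level level name.
#' @return list `u`, `v` (m s^-1).
#' @export
sample_wind <- function(field, time, position, level) {
  stopifnot(level %in% WIND_LEVELS)
  lv <- field[field$level == level, , drop = FALSE]
  if (nrow(lv) == 0) stop("level ", level, " not present in field")
  lons <- sort(unique(lv$lon)); lats <- sort(unique(lv$lat))
  times <- sort(unique(as.numeric(lv$time)))
  q <- as.numeric(time); lon <- position[1]; lat <- position[2]
  if (lon < lons[1] || lon > lons[length(lons)] ||
      lat < lats[1] || lat > lats[length(lats)] ||
      q < times[1] || q > times[length(times)])
    stop("query outside wind grid")

  brack <- function(grid, x) {
    i <- findInterval(x, grid, rightmost.closed = TRUE)
    i <- min(max(i, 1), length(grid) - 1)
    if (length(grid) == 1) return(list(i = 1, j = 1, w = 0))
    list(i = i, j = i + 1, w = (x - grid[i]) / (grid[i + 1] - grid[i]))
  }
  bx <- brack(lons, lon); by <- brack(lats, lat); bt <- brack(times, q)

  val <- function(comp) {
    node <- function(ti, xi, yi) {
      row <- lv[abs(as.numeric(lv$time) - times[ti]) < 1e-6 &
                  lv$lon == lons[xi] & lv$lat == lats[yi], comp]
      row[1]
    }
    bilin <- function(ti) {
      (1 - bx$w) * (1 - by$w) * node(ti, bx$i, by$i) +
        bx$w * (1 - by$w) * node(ti, bx$j, by$i) +
        (1 - bx$w) * by$w * node(ti, bx$i, by$j) +
        bx$w * by$w * node(ti, bx$j, by$j)
    }
    (1 - bt$w) * bilin(bt$i) + bt$w * bilin(bt$j)
  }
  list(u = val("u"), v = val("v"))
}

#' Ground speed under heading compensation (wind triangle)
#'
#' The bird flies at fixed airspeed and offsets its heading so that the
#' crosswind component is cancelled and the resultant motion stays along the
#' preferred track direction. With along-track wind w_par and cross-track
#' wind w_perp, the achievable ground speed is
#' `w_par + sqrt(airspeed^2 - w_perp^2)`; when `|w_perp|` exceeds the
#' airspeed the preferred direction cannot be held and the hour is flagged
#' infeasible. Wind profit is ground speed minus airspeed.
#'
#' @param u,v wind components, m s^-1 (east, north).
#' @param track_direction_deg preferred direction, degrees clockwise from
#'   north.
#' @param airspeed fixed airspeed, m s^-1.
#' @return list `groundspeed`, `wind_profit`, `heading_deg`, `feasible`,
#'   `w_par`, `w_perp`. Infeasible: `groundspeed` and `heading_deg` are
#'   `NA`.
#' @export
#' @examples
#' ground_speed_with_heading_compensation(0, 6, 0, 10)$groundspeed   # 16
#' ground_speed_with_heading_compensation(6, 0, 0, 10)$groundspeed   # 8
ground_speed_with_heading_compensation <- function(u, v, track_direction_deg,
                                                   airspeed = 10) {
  if (airspeed <= 0) stop("airspeed must be positive")
  th <- track_direction_deg * pi / 180
  along <- c(sin(th), cos(th))        # unit vector of the preferred track
  cross <- c(cos(th), -sin(th))       # unit vector 90 deg clockwise of it
  w_par <- u * along[1] + v * along[2]
  w_perp <- u * cross[1] + v * cross[2]
  if (abs(w_perp) > airspeed)
    return(list(groundspeed = NA_real_, wind_profit = NA_real_,
                heading_deg = NA_real_, feasible = FALSE,
                w_par = w_par, w_perp = w_perp))
  gs <- w_par + sqrt(airspeed^2 - w_perp^2)
  # airspeed vector must contribute -w_perp across-track
  offset <- asin(-w_perp / airspeed) * 180 / pi
  list(groundspeed = gs, wind_profit = gs - airspeed,
       heading_deg = (track_direction_deg + offset) %% 360,
       feasible = TRUE, w_par = w_par, w_perp = w_perp)
}

#' Harmonic mean of ground speeds
#'
#' `n / sum(1 / v)`: the correct travel-time average for fixed-distance
#' flight. Non-positive or missing speeds (infeasible hours) are excluded;
#' their count is attached as attribute `n_excluded`.
#'
#' @param speeds numeric vector, m s^-1.
#' @return harmonic mean with attribute `n_excluded`; `NA` when no valid
#'   speed remains.
#' @export
#' @examples
#' harmonic_mean_groundspeed(c(10, 20))  # 13.333
harmonic_mean_groundspeed <- function(speeds) {
  bad <- is.na(speeds) | speeds <= 0
  v <- speeds[!bad]
  hm <- if (length(v) == 0) NA_real_ else length(v) / sum(1 / v)
  structure(hm, n_excluded = sum(bad))
}

#' Hourly wind-profit profile along a track
#'
#' Samples the wind field at linearly interpolated hourly positions along
#' the reconstructed track and computes the heading-compensated ground speed
#' and wind profit at every analysis level. The preferred direction each
#' hour is the local great-circle bearing of the track.
#'
#' @param track data frame `t`, `lon`, `lat`.
#' @param field wind field.
#' @param airspeed fixed airspeed, m s^-1.
#' @param levels levels to evaluate.
#' @param t_start,t_end evaluation window (defaults to the track span,
#'   truncated to whole hours).
#' @return data frame of class `nx_windprofile`: `time`, `level`, `lon`,
#'   `lat`, `bearing_deg`, `u`, `v`, `groundspeed`, `wind_profit`,
#'   `feasible`.
#' @export
wind_profit_profile <- function(track, field, airspeed = 10,
                                levels = WIND_LEVELS,
                                t_start = NULL, t_end = NULL) {
  track <- as_track(track)
  if (is.null(t_start)) t_start <- track$t[1]
  if (is.null(t_end)) t_end <- track$t[nrow(track)]
  hours <- seq(as.POSIXct(ceiling(as.numeric(t_start) / 3600) * 3600,
                          origin = "1970-01-01", tz = "UTC"),
               t_end, by = 3600)
  if (length(hours) == 0) stop("window shorter than one hour")
  out <- NULL
  for (h in seq_along(hours)) {
    tm <- hours[h]
    p <- interpolate_on_track(track, time = tm)
    # local bearing: towards the position a short time ahead (or behind at
    # the track end)
    ahead <- min(as.numeric(tm) + 300, as.numeric(track$t[nrow(track)]))
    q <- interpolate_on_track(track, time = as.POSIXct(ahead, origin = "1970-01-01", tz = "UTC"))
    brg <- if (isTRUE(all.equal(unname(p), unname(q)))) {
      behind <- max(as.numeric(tm) - 300, as.numeric(track$t[1]))
      gc_bearing(interpolate_on_track(track,
        time = as.POSIXct(behind, origin = "1970-01-01", tz = "UTC")), p)
    } else gc_bearing(p, q)
    for (lv in levels) {
      w <- sample_wind(field, tm, p, lv)
      hc <- ground_speed_with_heading_compensation(w$u, w$v, brg, airspeed)
      out <- rbind(out, data.frame(
        time = tm, level = lv, lon = p[1], lat = p[2], bearing_deg = brg,
        u = w$u, v = w$v, groundspeed = hc$groundspeed,
        wind_profit = hc$wind_profit, feasible = hc$feasible))
    }
  }
  rownames(out) <- NULL
  class(out) <- c("nx_windprofile", "data.frame")
  out
}

#' Evaluate the altitude-use hypotheses on a wind-profit profile
#'
#' H1 (flexible altitude): each hour the bird uses the level with the
#' highest achievable ground speed; the track summary is the harmonic mean
#' of those per-hour maxima. H2 (fixed altitude): ground speeds at the
#' supplied nocturnal level. A surface-level summary is always included for
#' the surface-vs-altitude contrast.
#'
#' @param profile from [wind_profit_profile()].
#' @param nocturnal_level level name for H2 (e.g. from [nearest_level()] of
#'   the filtered mean GPS altitude).
#' @param airspeed airspeed used for the profile, m s^-1.
#' @return list with `summary` (data frame: hypothesis, harmonic-mean ground
#'   speed, mean wind profit, hours used/excluded) and `h1_levels` (the
#'   per-hour level chosen under H1).
#' @export
evaluate_hypotheses <- function(profile, nocturnal_level = "850",
                                airspeed = 10) {
  stopifnot(nocturnal_level %in% WIND_LEVELS)
  hours <- unique(profile$time)
  h1 <- h2 <- surf <- numeric(0)
  h1_lv <- character(0)
  for (tm in hours) {
    rows <- profile[profile$time == tm, ]
    feas <- rows[rows$feasible, ]
    if (nrow(feas) > 0) {
      b <- which.max(feas$groundspeed)
      h1 <- c(h1, feas$groundspeed[b]); h1_lv <- c(h1_lv, feas$level[b])
    } else { h1 <- c(h1, NA); h1_lv <- c(h1_lv, NA) }
    g2 <- rows$groundspeed[rows$level == nocturnal_level]
    h2 <- c(h2, if (length(g2)) g2 else NA)
    gs <- rows$groundspeed[rows$level == "surface"]
    surf <- c(surf, if (length(gs)) gs else NA)
  }
  mk <- function(name, v) {
    hm <- harmonic_mean_groundspeed(v)
    data.frame(hypothesis = name, harmonic_mean_groundspeed = as.numeric(hm),
               mean_wind_profit = mean(v - airspeed, na.rm = TRUE),
               n_hours = sum(!is.na(v) & v > 0),
               n_excluded = attr(hm, "n_excluded"))
  }
  list(summary = rbind(mk("surface", surf), mk("H1", h1), mk("H2", h2)),
       h1_levels = data.frame(time = hours, level = h1_lv))
}
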