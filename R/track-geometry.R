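# Track reconstruction between nightly GPS fixes: great-circle legs,
# time/fraction interpolation, shoreline intersection on densified
# geodesics, open-water distance, and crossing-time reconstruction.

as_track <- function(track) {
  stopifnot(is.data.frame(track), all(c("t", "lon", "lat") %in% names(track)))
  stopifnot(inherits(track$t, "POSIXct"))
  if (is.unsorted(as.numeric(track$t), strictly = TRUE))
    stop("track timestamps must be strictly increasing")
  as_lonlat(track)
  track
}

track_leg_lengths <- function(track) {
  n <- nrow(track)
  if (n < 2) return(numeric(0))
  gc_distance(cbind(track$lon[-n], track$lat[-n]),
              cbind(track$lon[-1], track$lat[-1]))
}

#' Interpolate a position on a great-circle track
#'
#' Positions between fixes lie on the great circle joining the bracketing
#' fixes. With `time`, the along-leg distance is proportional to elapsed
#' time within that leg (constant speed per leg); with `fraction`, it is the
#' given fraction of the total along-track length.
#'
#' @param track data frame with `t` (`POSIXct`, strictly increasing), `lon`,
#'   `lat`.
#' @param time query time within the track's span (`POSIXct`).
#' @param fraction alternative query: fraction of total track length in
#'   \[0, 1\].
#' @return named numeric `c(lon, lat)`.
#' @export
interpolate_on_track <- function(track, time = NULL, fraction = NULL) {
  track <- as_track(track)
  legs <- track_leg_lengths(track)
  if (!is.null(time)) {
    tt <- as.numeric(track$t); q <- as.numeric(time)
    if (q < tt[1] || q > tt[length(tt)]) stop("query time outside track span")
    i <- max(which(tt <= q)); i <- min(i, length(tt) - 1)
    f_leg <- (q - tt[i]) / (tt[i + 1] - tt[i])
    d <- legs[i] * f_leg
  } else {
    stopifnot(!is.null(fraction), fraction >= 0, fraction <= 1)
    cum <- c(0, cumsum(legs))
    target <- fraction * cum[length(cum)]
    i <- max(which(cum <= target + 1e-12)); i <- min(i, length(legs))
    d <- target - cum[i]
  }
  p1 <- c(track$lon[i], track$lat[i]); p2 <- c(track$lon[i + 1], track$lat[i + 1])
  if (d <= 0 || legs[i] == 0) return(c(lon = p1[1], lat = p1[2]))
  if (d >= legs[i]) return(c(lon = p2[1], lat = p2[2]))
  p <- gc_point_along(p1, p2, d)
  c(lon = p[1], lat = p[2])
}

# Densify a track at roughly step_km spacing along each leg. Legs crossing
# the antimeridian are split first so longitudes never wrap within a piece.
densify_track <- function(track, step_km = 1) {
  track <- as_track(track)
  pts <- NULL; along <- NULL; leg_idx <- NULL
  cum <- 0
  for (i in seq_len(nrow(track) - 1)) {
    p1 <- c(track$lon[i], track$lat[i]); p2 <- c(track$lon[i + 1], track$lat[i + 1])
    for (piece in split_antimeridian(p1, p2)) {
      a <- piece[[1]]; b <- piece[[2]]
      d <- gc_distance(a, b)
      n_seg <- max(1L, ceiling(d / step_km))
      f <- seq(0, 1, length.out = n_seg + 1)
      seg <- if (d == 0) matrix(rep(a, 2), ncol = 2, byrow = TRUE) else
        rbind(a, if (n_seg > 1)
          geosphere::gcIntermediate(as_lonlat(a), as_lonlat(b), n = n_seg - 1)
          else NULL, b)
      seg_along <- cum + f * d
      if (!is.null(pts)) { seg <- seg[-1, , drop = FALSE]; seg_along <- seg_along[-1] }
      pts <- rbind(pts, seg)
      along <- c(along, seg_along)
      leg_idx <- c(leg_idx, rep(i, nrow(seg)))
      cum <- cum + d
    }
  }
  data.frame(lon = pts[, 1], lat = pts[, 2], along_km = along, leg = leg_idx)
}

#' Intersect a track with land polygons
#'
#' Densifies the great-circle track (default 1 km step), classifies each
#' vertex as land or water, and refines every land/water transition by
#' bisection along the geodesic to metre-level accuracy. Returns the ordered
#' shoreline transitions and the land/water spans between them.
#'
#' @param track data frame `t`, `lon`, `lat` (fix order = travel order).
#' @param land polygon set ([generate_coastline()] /
#'   [read_coastline_geojson()]).
#' @param step_km densification step, km.
#' @return list with `transitions` (data frame: `lon`, `lat`, `along_km`,
#'   `leg`, `type` = `"land_to_water"`/`"water_to_land"`) and `spans` (data
#'   frame: `start_km`, `end_km`, `length_km`, `water`, `bounded` — spans
#'   touching a track end are unbounded). A track entirely over land yields
#'   zero water spans; entirely over water yields one unbounded water span.
#' @export
intersect_shoreline <- function(track, land, step_km = 1) {
  dens <- densify_track(track, step_km = step_km)
  on_land <- point_on_land(land, dens$lon, dens$lat)

  refine <- function(i) {
    # bisect between densified vertices i and i+1 (state changes across them)
    a <- c(dens$lon[i], dens$lat[i]); b <- c(dens$lon[i + 1], dens$lat[i + 1])
    ka <- dens$along_km[i]; kb <- dens$along_km[i + 1]
    state_a <- on_land[i]
    while (gc_distance(a, b) > 1e-4) {  # 0.1 m
      m <- gc_midpoint(a, b)
      km <- (ka + kb) / 2
      if (point_on_land(land, m[1], m[2]) == state_a) { a <- m; ka <- km }
      else { b <- m; kb <- km }
    }
    c(lon = unname((a[1] + b[1]) / 2), lat = unname((a[2] + b[2]) / 2),
      along_km = (ka + kb) / 2)
  }

  change <- which(diff(on_land) != 0)
  transitions <- data.frame(lon = numeric(), lat = numeric(),
                            along_km = numeric(), leg = integer(),
                            type = character())
  for (i in change) {
    r <- refine(i)
    transitions <- rbind(transitions, data.frame(
      lon = r[["lon"]], lat = r[["lat"]], along_km = r[["along_km"]],
      leg = dens$leg[i],
      type = if (on_land[i]) "land_to_water" else "water_to_land"))
  }

  total <- dens$along_km[nrow(dens)]
  cuts <- c(0, transitions$along_km, total)
  n_span <- length(cuts) - 1
  # state of span j is the state at its interior; first span state = state of
  # first vertex
  states <- logical(n_span)
  states[1] <- on_land[1]
  if (n_span > 1) for (j in 2:n_span) states[j] <- !states[j - 1]
  spans <- data.frame(start_km = cuts[-length(cuts)], end_km = cuts[-1])
  spans$length_km <- spans$end_km - spans$start_km
  spans$water <- !states
  spans$bounded <- !(seq_len(n_span) == 1 | seq_len(n_span) == n_span)
  spans <- spans[spans$length_km > 1e-9, , drop = FALSE]
  rownames(spans) <- NULL
  list(transitions = transitions, spans = spans)
}

#' Open-water distance of a crossing
#'
#' The along-track length of the longest contiguous water span (the maximum
#' distance of water crossing). `method = "sum"` instead totals all water
#' spans, for archipelago-style accounting.
#'
#' @param spans span table from [intersect_shoreline()], or the list it
#'   returns.
#' @param method `"longest"` (default) or `"sum"`.
#' @return distance in km.
#' @export
#' @examples
#' spans <- data.frame(start_km = c(0, 150, 155), end_km = c(150, 155, 215),
#'                     length_km = c(150, 5, 60), water = c(TRUE, FALSE, TRUE))
#' open_water_distance(spans)         # 150
#' open_water_distance(spans, "sum")  # 210
open_water_distance <- function(spans, method = c("longest", "sum")) {
  method <- match.arg(method)
  if (is.list(spans) && !is.data.frame(spans)) spans <- spans$spans
  w <- spans[spans$water, , drop = FALSE]
  if (nrow(w) == 0) stop("track has no water span")
  switch(method, longest = max(w$length_km), sum = sum(w$length_km))
}

#' Ground speed between two fixes
#'
#' Great-circle separation divided by elapsed time; for the nightly fix pair
#' taken two hours apart this is the crossing ground speed \eqn{V_g}.
#'
#' @param p1,p2 single-row data frames (or lists) with `t`, `lon`, `lat`;
#'   `p2` later than `p1`.
#' @return speed, m s^-1.
#' @export
#' @examples
#' p1 <- list(t = as.POSIXct("2020-09-05 21:00", tz = "UTC"), lon = 16, lat = 56)
#' p2 <- list(t = as.POSIXct("2020-09-05 23:00", tz = "UTC"), lon = 16, lat = 57.0588)
#' ground_speed(p1, p2)  # about 16.35
ground_speed <- function(p1, p2) {
  dt <- as.numeric(p2$t) - as.numeric(p1$t)
  if (dt <= 0) stop("p2 must be later than p1")
  gc_distance(c(p1$lon, p1$lat), c(p2$lon, p2$lat)) * 1000 / dt
}

#' Reconstruct crossing initiation and arrival times
#'
#' Initiation: the bird is assumed to hold ground speed `v_g`, so it crossed
#' the departure shoreline `completed_km` before the first nightly fix:
#' `t_init = t(p1) - completed_km / v_g`. Arrival at the far shoreline:
#' `t_arr = t(p2) + remaining_km / v_g`. Distances are signed along-track, so
#' a fix beyond the shoreline (negative remaining distance) still yields the
#' correct time under uniform motion.
#'
#' @param t_p1,t_p2 times of the nightly fixes (`POSIXct`).
#' @param v_g ground speed, m s^-1 (> 0).
#' @param completed_km along-track distance from the departure shoreline
#'   p_A to the first fix, km.
#' @param remaining_km along-track distance from the second fix to the
#'   arrival shoreline p_B, km.
#' @return list `t_init`, `t_arr`.
#' @export
reconstruct_crossing_times <- function(t_p1, t_p2, v_g, completed_km,
                                       remaining_km) {
  if (!is.finite(v_g) || v_g <= 0) stop("v_g must be positive")
  list(t_init = t_p1 - completed_km * 1000 / v_g,
       t_arr = t_p2 + remaining_km * 1000 / v_g)
}

#' Extract water crossings from nightly GPS fixes
#'
#' End-to-end geometry stage: per individual, reconstructs the great-circle
#' track through the fixes, intersects it with the land polygons, takes the
#' longest bounded water span as the crossing, identifies the nightly fix
#' pair (the configured UTC hours) spanning or nearest the crossing,
#' computes ground speed, reconstructs initiation and arrival times, and
#' classifies the arrival as diurnal or nocturnal.
#'
#' @param fixes data frame `individual`, `t` (`POSIXct` UTC), `lon`, `lat`,
#'   optional `source_hour`.
#' @param land polygon set.
#' @param fix_hours_utc the two nightly sampling hours used for the ground
#'   speed estimate.
#' @param step_km densification step for the intersection.
#' @param owd_method passed to [open_water_distance()].
#' @return data frame, one row per individual with a crossing: `individual`,
#'   `owd_km`, `v_g_ms`, `completed_km`, `remaining_km`, `t_init`, `t_arr`,
#'   `diurnal`, `season`, `bracketed` (both fixes strictly inside the water
#'   span), plus p_A/p_B coordinates. Individuals whose track never leaves
#'   land, or without a usable nightly fix pair, are dropped with a warning.
#' @export
extract_crossings <- function(fixes, land, fix_hours_utc = c(21, 23),
                              step_km = 1, owd_method = "longest") {
  stopifnot(all(c("individual", "t", "lon", "lat") %in% names(fixes)))
  # one track per individual, or per (individual, track) when a track column
  # distinguishes repeated crossings by the same bird
  key <- if ("track" %in% names(fixes))
    paste(fixes$individual, fixes$track, sep = "\r") else fixes$individual
  out <- NULL
  for (id in unique(key)) {
    trk <- fixes[key == id, , drop = FALSE]
    trk <- trk[order(trk$t), , drop = FALSE]
    if (nrow(trk) < 2) next
    inter <- intersect_shoreline(trk, land, step_km = step_km)
    water <- inter$spans[inter$spans$water & inter$spans$bounded, , drop = FALSE]
    if (nrow(water) == 0) {
      warning("individual ", trk$individual[1], ": no bounded water span; skipped")
      next
    }
    cross <- water[which.max(water$length_km), ]
    owd <- open_water_distance(water, method = owd_method)

    # along-track km of each fix
    legs <- track_leg_lengths(trk)
    fix_km <- c(0, cumsum(legs))
    hr <- as.integer(format(trk$t, "%H", tz = "UTC"))
    is_night_fix <- hr %in% fix_hours_utc
    pair <- NULL
    cand <- which(is_night_fix[-nrow(trk)] & is_night_fix[-1] &
                    diff(as.numeric(trk$t)) <= 4 * 3600)
    if (length(cand) > 0) {
      # prefer the pair whose leg overlaps the crossing span most
      ov <- vapply(cand, function(i)
        max(0, min(fix_km[i + 1], cross$end_km) - max(fix_km[i], cross$start_km)),
        numeric(1))
      # fall back to the pair nearest the crossing if none overlaps
      if (all(ov == 0)) {
        mid <- (cross$start_km + cross$end_km) / 2
        pair <- cand[which.min(abs((fix_km[cand] + fix_km[cand + 1]) / 2 - mid))]
      } else pair <- cand[which.max(ov)]
    }
    if (is.null(pair)) {
      warning("individual ", trk$individual[1], ": no nightly fix pair; skipped")
      next
    }
    p1 <- trk[pair, ]; p2 <- trk[pair + 1, ]
    v_g <- ground_speed(p1, p2)
    completed <- fix_km[pair] - cross$start_km
    remaining <- cross$end_km - fix_km[pair + 1]
    times <- reconstruct_crossing_times(p1$t, p2$t, v_g, completed, remaining)
    tr <- inter$transitions
    pA <- tr[which.min(abs(tr$along_km - cross$start_km)), ]
    pB <- tr[which.min(abs(tr$along_km - cross$end_km)), ]
    diurnal <- classify_arrival(times$t_arr, c(pB$lon, pB$lat))
    month <- as.integer(format(times$t_arr, "%m", tz = "UTC"))
    out <- rbind(out, data.frame(
      individual = trk$individual[1], owd_km = owd, v_g_ms = v_g,
      completed_km = completed, remaining_km = remaining,
      t_init = times$t_init, t_arr = times$t_arr, diurnal = diurnal,
      season = if (month >= 7) "autumn" else "spring",
      bracketed = completed >= 0 && remaining >= 0,
      p_A_lon = pA$lon, p_A_lat = pA$lat, p_B_lon = pB$lon, p_B_lat = pB$lat))
  }
  if (is.null(out))
    return(data.frame(individual = character(), owd_km = numeric(),
                      v_g_ms = numeric(), completed_km = numeric(),
                      remaining_km = numeric(), diurnal = logical()))
  rownames(out) <- NULL
  out
}
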