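#' @importFrom stats rnorm runif rbinom coef approx median sd setNames
#' @importFrom utils read.csv write.csv modifyList
NULL

# Mean Earth radius (IUGG), km. All great-circle arithmetic in the package
# uses this sphere; ellipsoidal refinement is unnecessary at the accuracy of
# nightly GPS fixes.
R_EARTH_KM <- 6371.0088
R_EARTH_M <- R_EARTH_KM * 1000

KM_PER_DEG_LAT <- R_EARTH_M * pi / 180 / 1000  # 111.19493 km per degree of meridian arc

as_lonlat <- function(p) {
  if (is.data.frame(p)) p <- cbind(p$lon, p$lat)
  if (is.null(dim(p))) p <- matrix(p, ncol = 2)
  stopifnot(ncol(p) == 2)
  if (any(p[, 2] < -90 | p[, 2] > 90, na.rm = TRUE))
    stop("latitude out of [-90, 90]")
  if (any(p[, 1] < -180 | p[, 1] > 180, na.rm = TRUE))
    stop("longitude out of [-180, 180]")
  p
}

#' Great-circle distance between positions
#'
#' Haversine distance on a sphere of radius 6371.0088 km, the radius used
#' throughout the package for track reconstruction.
#'
#' @param a,b positions as `c(lon, lat)` vectors, two-column matrices, or
#'   data frames with `lon`/`lat` columns (degrees, WGS84; lon-lat order).
#' @return distance(s) in kilometres.
#' @export
#' @examples
#' gc_distance(c(0, 0), c(1, 0))  # one degree of longitude at the equator
gc_distance <- function(a, b) {
  geosphere::distHaversine(as_lonlat(a), as_lonlat(b), r = R_EARTH_M) / 1000
}

#' Initial great-circle bearing from one position to another
#'
#' @inheritParams gc_distance
#' @return bearing in degrees clockwise from true north, in [0, 360).
#' @export
gc_bearing <- function(a, b) {
  (geosphere::bearing(as_lonlat(a), as_lonlat(b)) + 360) %% 360
}

#' Point a given distance along the great circle from `a` towards `b`
#'
#' @inheritParams gc_distance
#' @param distance_km distance from `a` along the geodesic, km.
#' @return `c(lon, lat)` position (matrix row for vector input).
#' @export
gc_point_along <- function(a, b, distance_km) {
  a <- as_lonlat(a); b <- as_lonlat(b)
  p <- geosphere::destPoint(a, geosphere::bearing(a, b), distance_km * 1000,
                            r = R_EARTH_M)
  colnames(p) <- c("lon", "lat")
  if (nrow(p) == 1) drop(p) else p
}

# Great-circle midpoint, used by the bisection refinement of shoreline
# transitions.
gc_midpoint <- function(a, b) {
  m <- geosphere::midPoint(as_lonlat(a), as_lonlat(b))
  drop(m)
}

# Split a leg at the antimeridian if it crosses it the short way round.
# Returns a list of (p1, p2) pairs whose longitudes never wrap.
split_antimeridian <- function(p1, p2) {
  if (abs(p1[1] - p2[1]) <= 180) return(list(list(p1, p2)))
  edge <- if (p1[1] > 0) 180 else -180
  lat_cross <- geosphere::gcLat(as_lonlat(p1), as_lonlat(p2), lon = edge)[1]
  list(list(p1, c(edge, lat_cross)), list(c(-edge, lat_cross), p2))
}
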