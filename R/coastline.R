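# Analytic toy coastlines: land bands in latitude separated by water gaps of
# exact meridional width, centred on a reference meridian. Because meridian
# arc length on the sphere is exactly proportional to latitude difference,
# the along-track water widths of a south-to-north crossing are known in
# closed form, which gives the intersection machinery exact ground truth.

#' Generate a toy coastline
#'
#' Builds a set of land polygons (lon-lat degrees, WGS84) around a reference
#' meridian. Named geometries:
#' \describe{
#'   \item{`strait`}{two land masses separated by one water gap (one width).}
#'   \item{`two-gaps`}{two gaps with one island between (two widths).}
#'   \item{`archipelago`}{three or more gaps with islands between.}
#' }
#' The minimum great-circle separation of consecutive land masses along the
#' reference meridian equals the requested width.
#'
#' @param spec geometry name, one of `"strait"`, `"two-gaps"`,
#'   `"archipelago"`.
#' @param widths_km water-gap widths from south to north, km; `strait` takes
#'   one, `two-gaps` two, `archipelago` three or more.
#' @param lon0 reference meridian, degrees east.
#' @param lat_south latitude of the first (southern) shoreline, degrees.
#' @param extent_deg east-west extent of the land polygons, degrees.
#' @param land_depth_km north-south depth of the outer land masses, km.
#' @param island_depth_km north-south depth of islands between gaps, km.
#' @return object of class `nx_coastline`: list of closed polygon matrices
#'   (`lon`, `lat`) with the gap bookkeeping in attributes.
#' @export
#' @examples
#' coast <- generate_coastline("strait", widths_km = 200)
#' attr(coast, "gaps")
generate_coastline <- function(spec = c("strait", "two-gaps", "archipelago"),
                               widths_km, lon0 = 16, lat_south = 54,
                               extent_deg = 10, land_depth_km = 300,
                               island_depth_km = 20) {
  spec <- match.arg(spec)
  n_expected <- switch(spec, strait = 1L, `two-gaps` = 2L, archipelago = NA_integer_)
  if (!is.na(n_expected) && length(widths_km) != n_expected)
    stop(sprintf("'%s' expects %d width(s)", spec, n_expected))
  if (spec == "archipelago" && length(widths_km) < 3)
    stop("'archipelago' expects at least three widths")
  if (any(!is.finite(widths_km)) || any(widths_km <= 0))
    stop("widths must be positive")

  deg <- function(km) km / KM_PER_DEG_LAT
  band <- function(lat_lo, lat_hi) {
    lon_w <- lon0 - extent_deg / 2
    lon_e <- lon0 + extent_deg / 2
    cbind(lon = c(lon_w, lon_e, lon_e, lon_w, lon_w),
          lat = c(lat_lo, lat_lo, lat_hi, lat_hi, lat_lo))
  }

  polys <- list(band(lat_south - deg(land_depth_km), lat_south))
  gaps <- data.frame(start_lat = numeric(), end_lat = numeric(),
                     width_km = numeric())
  cursor <- lat_south
  for (i in seq_along(widths_km)) {
    gap_deg <- deg(widths_km[i])
    gaps <- rbind(gaps, data.frame(start_lat = cursor,
                                   end_lat = cursor + gap_deg,
                                   width_km = widths_km[i]))
    cursor <- cursor + gap_deg
    depth <- if (i < length(widths_km)) deg(island_depth_km) else deg(land_depth_km)
    polys <- c(polys, list(band(cursor, cursor + depth)))
    cursor <- cursor + depth
  }

  structure(polys, class = "nx_coastline", spec = spec, lon0 = lon0,
            lat_south = lat_south, gaps = gaps)
}

#' Test whether positions fall on land
#'
#' Even-odd (ray-casting) point-in-polygon test against a polygon set in the
#' lon-lat plane. Positions exactly on a polygon edge are treated as land.
#'
#' @param coast polygons from [generate_coastline()] or
#'   [read_coastline_geojson()].
#' @param lon,lat position vectors, degrees.
#' @return logical vector.
#' @export
point_on_land <- function(coast, lon, lat) {
  stopifnot(length(lon) == length(lat))
  inside <- logical(length(lon))
  for (poly in coast) {
    px <- poly[, 1]; py <- poly[, 2]
    n <- length(px)
    # ring is closed: vertex n equals vertex 1
    for (k in seq_len(n - 1)) {
      x1 <- px[k]; y1 <- py[k]; x2 <- px[k + 1]; y2 <- py[k + 1]
      crosses <- ((y1 > lat) != (y2 > lat)) &
        (lon < (x2 - x1) * (lat - y1) / (y2 - y1) + x1)
      inside <- xor(inside, crosses & !is.na(crosses))
      on_edge <- (pmin(y1, y2) <= lat & lat <= pmax(y1, y2) &
                    pmin(x1, x2) <= lon & lon <= pmax(x1, x2) &
                    abs((x2 - x1) * (lat - y1) - (y2 - y1) * (lon - x1)) < 1e-12)
      inside <- inside | on_edge
    }
  }
  inside
}

#' Write a coastline polygon set as GeoJSON
#'
#' One `Feature` per land mass with `Polygon` geometry, coordinates in
#' lon-lat order (RFC 7946).
#'
#' @param coast polygon set.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_coastline_geojson <- function(coast, path) {
  features <- lapply(seq_along(coast), function(i) {
    ring <- lapply(seq_len(nrow(coast[[i]])), function(k)
      c(coast[[i]][k, 1], coast[[i]][k, 2]))
    list(type = "Feature",
         properties = list(id = i),
         geometry = list(type = "Polygon", coordinates = list(ring)))
  })
  gj <- list(type = "FeatureCollection", features = features)
  jsonlite::write_json(gj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read land polygons from GeoJSON
#'
#' Accepts `Polygon` and `MultiPolygon` features (outer rings only; holes
#' are not supported by the toy geometries this package works with).
#'
#' @param path GeoJSON file.
#' @return list of polygon matrices of class `nx_coastline`.
#' @export
read_coastline_geojson <- function(path) {
  gj <- jsonlite::read_json(path, simplifyVector = FALSE)
  polys <- list()
  ring_to_matrix <- function(ring) {
    m <- do.call(rbind, lapply(ring, function(pt) as.numeric(unlist(pt)[1:2])))
    colnames(m) <- c("lon", "lat")
    m
  }
  for (f in gj$features) {
    g <- f$geometry
    if (g$type == "Polygon") {
      polys <- c(polys, list(ring_to_matrix(g$coordinates[[1]])))
    } else if (g$type == "MultiPolygon") {
      for (pg in g$coordinates) polys <- c(polys, list(ring_to_matrix(pg[[1]])))
    } else {
      stop("unsupported geometry type: ", g$type)
    }
  }
  structure(polys, class = "nx_coastline")
}
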