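# Cylindrical equal-area projection of geographic ranges.

# Authalic (equal-area sphere) radius in km
AUTHALIC_RADIUS_KM <- 6371.0072

#' Project longitude/latitude coordinates with the cylindrical equal-area map
#'
#' Lambert cylindrical equal-area with standard parallel 0:
#' `x = R * lon_rad`, `y = R * sin(lat_rad)`.  The map preserves areas
#' exactly, so polygon areas computed in the projected plane equal spherical
#' areas (up to the straight-segment rendering of the boundary between
#' vertices); this avoids the systematic inflation of high-latitude ranges
#' that plain degree coordinates produce.
#'
#' @param lonlat two-column matrix of longitude/latitude in decimal degrees.
#' @param radius sphere radius; defaults to the authalic Earth radius in km,
#'   so projected areas are km^2.
#' @return two-column matrix of planar coordinates (km).
#' @export
cea_project <- function(lonlat, radius = AUTHALIC_RADIUS_KM) {
  lonlat <- as.matrix(lonlat)
  if (any(lonlat[, 1] < -180 - 1e-9 | lonlat[, 1] > 180 + 1e-9))
    stop("longitude outside [-180, 180]")
  if (any(lonlat[, 2] < -90 - 1e-9 | lonlat[, 2] > 90 + 1e-9))
    stop("latitude outside [-90, 90]")
  cbind(radius * lonlat[, 1] * pi / 180,
        radius * sin(lonlat[, 2] * pi / 180))
}

#' Project a geographic range set to equal-area planar coordinates
#'
#' @param ranges a `range_set` with `projection == "lonlat"`.
#' @param radius sphere radius (km); see [cea_project()].
#' @return The range set with planar coordinates (`projection == "cea"`);
#'   subsequent areas and overlaps are in km^2.
#' @export
project_equal_area <- function(ranges, radius = AUTHALIC_RADIUS_KM) {
  stopifnot(inherits(ranges, "range_set"))
  if (ranges$projection != "lonlat")
    stop("ranges are already projected (projection '", ranges$projection, "')")
  ranges$geoms <- lapply(ranges$geoms, function(mp) {
    lapply(mp, function(poly) {
      list(outer = cea_project(poly$outer, radius),
           holes = lapply(poly$holes, cea_project, radius = radius))
    })
  })
  ranges$projection <- "cea"
  ranges
}
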