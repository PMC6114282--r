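#' Geodesy configuration
#'
#' All distances in this package are great-circle distances on a sphere.
#' The default radius (6378137 m) matches the default of
#' [geosphere::distCosine()], so distances agree in convention with
#' analyses that used that function.
#'
#' @param earth_radius_m Sphere radius in meters. Must be positive.
#' @return A list of class `geodesy_config`.
#' @export
geodesy_config <- function(earth_radius_m = 6378137) {
  stopifnot(is.numeric(earth_radius_m), length(earth_radius_m) == 1,
            earth_radius_m > 0)
  structure(list(earth_radius_m = earth_radius_m), class = "geodesy_config")
}

#' Great-circle distance in kilometers
#'
#' Spherical-law-of-cosines distance between points given as
#' longitude/latitude in decimal degrees (WGS84 convention, longitude in
#' (-180, 180]). Vectorised over rows.
#'
#' @param p1,p2 Numeric vectors `c(lon, lat)` or two-column matrices.
#' @param geodesy A [geodesy_config()].
#' @return Distance(s) in km; `NaN` inputs raise an error rather than
#'   propagating silently.
#' @export
great_circle_km <- function(p1, p2, geodesy = geodesy_config()) {
  p1 <- rbind(p1); p2 <- rbind(p2)
  if (anyNA(p1) || anyNA(p2)) stop("great_circle_km: NA/NaN coordinate")
  check_lonlat(p1); check_lonlat(p2)
  geosphere::distCosine(p1, p2, r = geodesy$earth_radius_m) / 1000
}

check_lonlat <- function(m) {
  if (any(m[, 1] <= -180 | m[, 1] > 180))
    stop("longitude out of (-180, 180]")
  if (any(m[, 2] < -90 | m[, 2] > 90))
    stop("latitude out of [-90, 90]")
  invisible(m)
}

#' Azimuthal-equidistant projection about a center
#'
#' Projects lon/lat to planar km so that great-circle distance and
#' initial bearing from the center are preserved exactly (spherical
#' forward/inverse formulas, consistent in both directions); used for
#' track simulation, kernel densities and the environmental grid, where
#' the region of interest surrounds a single colony.
#'
#' @param lonlat Two-column matrix (lon, lat) in degrees.
#' @param center `c(lon, lat)` of the projection center.
#' @param geodesy A [geodesy_config()].
#' @return Two-column matrix (x, y) in km; x east, y north.
#' @export
aeqd_project <- function(lonlat, center, geodesy = geodesy_config()) {
  lonlat <- rbind(lonlat)
  rad <- pi / 180
  l1 <- center[1] * rad; f1 <- center[2] * rad
  l2 <- lonlat[, 1] * rad; f2 <- lonlat[, 2] * rad
  cosd <- sin(f1) * sin(f2) + cos(f1) * cos(f2) * cos(l2 - l1)
  d <- geodesy$earth_radius_m / 1000 * acos(pmin(1, pmax(-1, cosd)))
  b <- atan2(sin(l2 - l1) * cos(f2),
             cos(f1) * sin(f2) - sin(f1) * cos(f2) * cos(l2 - l1))
  b[d == 0] <- 0
  cbind(x = d * sin(b), y = d * cos(b))
}

#' Inverse azimuthal-equidistant projection
#'
#' @param xy Two-column matrix (x, y) in km.
#' @inheritParams aeqd_project
#' @return Two-column matrix (lon, lat) in degrees.
#' @export
aeqd_unproject <- function(xy, center, geodesy = geodesy_config()) {
  xy <- rbind(xy)
  rad <- pi / 180
  l1 <- center[1] * rad; f1 <- center[2] * rad
  delta <- sqrt(xy[, 1]^2 + xy[, 2]^2) * 1000 / geodesy$earth_radius_m
  theta <- atan2(xy[, 1], xy[, 2])
  f2 <- asin(sin(f1) * cos(delta) + cos(f1) * sin(delta) * cos(theta))
  l2 <- l1 + atan2(sin(theta) * sin(delta) * cos(f1),
                   cos(delta) - sin(f1) * sin(f2))
  lon <- (l2 / rad + 180) %% 360 - 180
  lon[lon == -180] <- 180  # convention: lon in (-180, 180]
  cbind(lon = lon, lat = f2 / rad)
}
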