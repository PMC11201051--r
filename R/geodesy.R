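#' Great-circle distance between points (haversine)
#'
#' Distance on a sphere of radius [earth_radius_km]. Inputs are recycled;
#' coordinates are decimal degrees (WGS84 lon/lat).
#'
#' @param lon1,lat1,lon2,lat2 Coordinates in decimal degrees.
#' @return Distance(s) in kilometres.
#' @examples
#' haversine_km(0, 0, 0, 1)  # one degree of latitude, ~111.19 km
#' @export
haversine_km <- function(lon1, lat1, lon2, lat2) {
  p1 <- deg2rad(lat1); p2 <- deg2rad(lat2)
  dphi <- p2 - p1
  dlam <- deg2rad(lon2 - lon1)
  a <- sin(dphi / 2)^2 + cos(p1) * cos(p2) * sin(dlam / 2)^2
  a <- pmin(1, pmax(0, a))
  2 * earth_radius_km * asin(sqrt(a))
}

#' Initial bearing of the great circle from one point to another
#'
#' @inheritParams haversine_km
#' @return Bearing in degrees clockwise from north, in \[0, 360).
#' @export
initial_bearing <- function(lon1, lat1, lon2, lat2) {
  p1 <- deg2rad(lat1); p2 <- deg2rad(lat2)
  dlam <- deg2rad(lon2 - lon1)
  y <- sin(dlam) * cos(p2)
  x <- cos(p1) * sin(p2) - sin(p1) * cos(p2) * cos(dlam)
  (atan2(y, x) * 180 / pi) %% 360
}

#' Spherical area of one raster cell
#'
#' Area of the cell in row `row` of a lat/lon grid, using the spherical
#' quadrangle formula A = R^2 * dlam * (sin(phi_top) - sin(phi_bottom)).
#' All cells in a row share the same area; area shrinks towards the poles.
#'
#' @param header A grid header (see [env_grid()]) or any list with
#'   `nrows`, `yllcorner`, `cellsize`.
#' @param row Row index (1 = northernmost row), may be a vector.
#' @return Cell area(s) in km^2.
#' @export
cell_area_km2 <- function(header, row) {
  stopifnot(all(row >= 1), all(row <= header$nrows))
  lat_bottom <- header$yllcorner + (header$nrows - row) * header$cellsize
  lat_top <- lat_bottom + header$cellsize
  dlam <- deg2rad(header$cellsize)
  earth_radius_km^2 * dlam * (sin(deg2rad(lat_top)) - sin(deg2rad(lat_bottom)))
}
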