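# Spherical geometry kernels. All distances in km on a sphere of radius
# 6371 km; coordinates in decimal degrees, longitude in [-180, 180).

#' Great-circle distance between points
#'
#' Haversine distance on a sphere of radius 6371 km. Vectorized over all
#' arguments.
#'
#' @param lat1,lon1,lat2,lon2 Coordinates in decimal degrees.
#' @return Distance(s) in km.
#' @examples
#' great_circle_km(0, 0, 1, 0)    # one degree of latitude, ~111.195 km
#' @export
great_circle_km <- function(lat1, lon1, lat2, lon2) {
  p1 <- lat1 * pi / 180
  p2 <- lat2 * pi / 180
  dphi <- (lat2 - lat1) * pi / 180
  dlam <- (lon2 - lon1) * pi / 180
  a <- sin(dphi / 2)^2 + cos(p1) * cos(p2) * sin(dlam / 2)^2
  a <- pmin(pmax(a, 0), 1)
  2 * EARTH_RADIUS_KM * asin(sqrt(a))
}

#' Initial great-circle bearing from point 1 to point 2, degrees clockwise
#' from north.
#' @inheritParams great_circle_km
#' @return Bearing(s) in [0, 360).
#' @export
gc_bearing <- function(lat1, lon1, lat2, lon2) {
  p1 <- lat1 * pi / 180; p2 <- lat2 * pi / 180
  dl <- (lon2 - lon1) * pi / 180
  th <- atan2(sin(dl) * cos(p2),
              cos(p1) * sin(p2) - sin(p1) * cos(p2) * cos(dl))
  (th * 180 / pi) %% 360
}

#' Destination point along a great circle
#'
#' @inheritParams great_circle_km
#' @param bearing Initial bearing, degrees clockwise from north.
#' @param dist_km Distance travelled, km.
#' @return list(lat, lon) in degrees, lon wrapped to [-180, 180).
#' @export
gc_destination <- function(lat1, lon1, bearing, dist_km) {
  d <- dist_km / EARTH_RADIUS_KM
  p1 <- lat1 * pi / 180
  l1 <- lon1 * pi / 180
  th <- bearing * pi / 180
  p2 <- asin(sin(p1) * cos(d) + cos(p1) * sin(d) * cos(th))
  l2 <- l1 + atan2(sin(th) * sin(d) * cos(p1), cos(d) - sin(p1) * sin(p2))
  list(lat = p2 * 180 / pi, lon = wrap_lon(l2 * 180 / pi))
}

#' Spherical linear interpolation between two points
#'
#' Interpolates along the great circle from point 1 (frac = 0) to point 2
#' (frac = 1); dateline-safe since it works in Cartesian coordinates.
#'
#' @inheritParams great_circle_km
#' @param frac Interpolation fraction(s) in [0, 1].
#' @return list(lat, lon) in degrees.
#' @export
gc_interpolate <- function(lat1, lon1, lat2, lon2, frac) {
  n <- max(length(lat1), length(lat2), length(frac))
  v1 <- ll_to_xyz(rep_len(lat1, n), rep_len(lon1, n))
  v2 <- ll_to_xyz(rep_len(lat2, n), rep_len(lon2, n))
  frac <- rep_len(frac, n)
  dot <- pmin(pmax(rowSums(v1 * v2), -1), 1)
  om <- acos(dot)
  small <- om < 1e-12
  a <- ifelse(small, 1 - frac, sin((1 - frac) * om) / ifelse(small, 1, sin(om)))
  b <- ifelse(small, frac, sin(frac * om) / ifelse(small, 1, sin(om)))
  v <- v1 * a + v2 * b
  xyz_to_ll(v)
}

#' East/north displacement between successive points
#'
#' Local equirectangular components evaluated at the latitude midpoint, in
#' km; used to express step velocities as east/north vectors.
#' @inheritParams great_circle_km
#' @return list(east_km, north_km)
#' @export
displacement_en <- function(lat1, lon1, lat2, lon2) {
  midlat <- (lat1 + lat2) / 2 * pi / 180
  dlam <- (wrap_lon(lon2 - lon1)) * pi / 180
  list(east_km = EARTH_RADIUS_KM * cos(midlat) * dlam,
       north_km = EARTH_RADIUS_KM * (lat2 - lat1) * pi / 180)
}

#' Wrap longitudes into [-180, 180)
#' @param lon Longitude(s), degrees.
#' @export
wrap_lon <- function(lon) ((lon + 180) %% 360) - 180

# Cumulative unwrap so that successive longitudes never jump by more than
# 180 degrees (needed before running means across the dateline).
unwrap_lon <- function(lon) {
  if (length(lon) < 2) return(lon)
  d <- diff(lon)
  d <- d - 360 * round(d / 360)
  cumsum(c(lon[1], d))
}

ll_to_xyz <- function(lat, lon) {
  p <- lat * pi / 180
  l <- lon * pi / 180
  cbind(cos(p) * cos(l), cos(p) * sin(l), sin(p))
}

xyz_to_ll <- function(v) {
  nrm <- sqrt(rowSums(v^2))
  v <- v / nrm
  list(lat = asin(pmin(pmax(v[, 3], -1), 1)) * 180 / pi,
       lon = wrap_lon(atan2(v[, 2], v[, 1]) * 180 / pi))
}
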