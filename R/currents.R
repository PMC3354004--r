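# Surface currents: geostrophic velocities from SSH slopes with an
# equatorial beta-plane treatment, a two-parameter Ekman layer from wind
# stress, bilinear sampling, and removal of currents from track velocities.

#' Geostrophic surface currents from sea-surface height
#'
#' Outside the equatorial band: u = -(g/f) dEta/dy, v = (g/f) dEta/dx with
#' f = 2 Omega sin(lat), central finite differences. Inside the band the
#' f-plane form is singular, so a beta-plane solution built from second
#' meridional derivatives (u = -(g/beta) d2Eta/dy2, v = (g/beta) d2Eta/dxdy,
#' beta = 2 Omega cos(lat)/R) replaces it, blended with Gaussian weights
#' w = exp(-(lat/L)^2) so the field is continuous through the band edges and
#' finite on the equator.
#'
#' @param ssh list(lat, lon, z) with z in metres on a regular grid
#'   (spacing <= 1 degree).
#' @param band_deg Half-width of the equatorial band, degrees (default 4).
#' @param blend_scale_deg Gaussian e-folding scale L of the blend (default
#'   `band_deg / 2`, making the beta weight ~2% at the band edge).
#' @param cap_kmd Optional magnitude cap (km/d) applied inside the band as a
#'   guard against residual amplification (default 150).
#' @return list of class `"current_field"`: `lat`, `lon`, `u`, `v` (km/d,
#'   matrices \[lat, lon\]), `provenance = "derived_geostrophic"`.
#' @export
geostrophic_from_ssh <- function(ssh, band_deg = 4,
                                 blend_scale_deg = band_deg / 2,
                                 cap_kmd = 150) {
  lat <- ssh$lat; lon <- ssh$lon; z <- ssh$z
  if (length(lat) < 3 || length(lon) < 3)
    stop("SSH grid too coarse for second derivatives (need >= 3 points per axis)")
  dlat <- diff(lat); dlon <- diff(lon)
  if (max(dlat) > 1 + 1e-9 || max(dlon) > 1 + 1e-9)
    stop("SSH grid spacing must be <= 1 degree")
  stopifnot(band_deg >= 0)
  dy <- mean(dlat) * pi / 180 * EARTH_RADIUS_KM * 1000   # metres
  dx_row <- mean(dlon) * pi / 180 * EARTH_RADIUS_KM * 1000 * cos(lat * pi / 180)
  detadY <- central_diff(z, 1) / dy
  detadX <- central_diff(z, 2) / dx_row
  f <- 2 * OMEGA_EARTH * sin(lat * pi / 180)
  f_min <- 2 * OMEGA_EARTH * sin(0.5 * pi / 180)
  f_safe <- ifelse(f == 0, f_min, sign(f) * pmax(abs(f), f_min))
  uf <- -GRAVITY_MS2 * detadY / f_safe
  vf <- GRAVITY_MS2 * detadX / f_safe
  beta <- 2 * OMEGA_EARTH * cos(lat * pi / 180) / (EARTH_RADIUS_KM * 1000)
  d2y <- central_diff(central_diff(z, 1), 1) / dy^2
  d2xy <- central_diff(central_diff(z, 2) / dx_row, 1) / dy
  ub <- -GRAVITY_MS2 * d2y / beta
  vb <- GRAVITY_MS2 * d2xy / beta
  w <- exp(-(lat / blend_scale_deg)^2)
  w[abs(lat) >= band_deg] <- 0
  u <- (1 - w) * uf + w * ub
  v <- (1 - w) * vf + w * vb
  u <- u * MS_TO_KMD; v <- v * MS_TO_KMD
  if (!is.null(cap_kmd)) {
    inband <- abs(lat) < band_deg
    u[inband, ] <- pmin(pmax(u[inband, , drop = FALSE], -cap_kmd), cap_kmd)
    v[inband, ] <- pmin(pmax(v[inband, , drop = FALSE], -cap_kmd), cap_kmd)
  }
  structure(list(lat = lat, lon = lon, u = u, v = v,
                 provenance = "derived_geostrophic"),
            class = "current_field")
}

# central difference along rows (margin 1 = lat) or columns (2 = lon),
# one-sided at the edges, per grid step
central_diff <- function(z, margin) {
  if (margin == 2) return(t(central_diff(t(z), 1)))
  n <- nrow(z)
  out <- z
  out[2:(n - 1), ] <- (z[3:n, ] - z[1:(n - 2), ]) / 2
  out[1, ] <- z[2, ] - z[1, ]
  out[n, ] <- z[n, ] - z[n - 1, ]
  out
}

#' Ekman surface currents from wind stress
#'
#' Slab-layer parameterization (r + i f) h u = tau / rho: the surface flow is
#' proportional to the stress, rotated clockwise of the wind in the northern
#' hemisphere and counterclockwise in the southern, with the linear friction
#' r keeping the solution finite on the equator.
#'
#' @param wind list(lat, lon, tau_x, tau_y) in N/m^2.
#' @param rho Seawater density, kg/m^3 (default 1025).
#' @param layer_m Slab depth h, m (default 32.5).
#' @param friction_ms Rayleigh friction r, m/s (default 2.15e-4).
#' @return `"current_field"` in km/d with provenance `"derived_ekman"`.
#' @export
ekman_from_wind <- function(wind, rho = 1025, layer_m = 32.5,
                            friction_ms = 2.15e-4) {
  lat <- wind$lat
  f <- 2 * OMEGA_EARTH * sin(lat * pi / 180)
  den <- rho * layer_m * (friction_ms^2 + f^2)
  u <- (friction_ms * wind$tau_x + f * wind$tau_y) / den
  v <- (friction_ms * wind$tau_y - f * wind$tau_x) / den
  structure(list(lat = lat, lon = wind$lon,
                 u = u * MS_TO_KMD, v = v * MS_TO_KMD,
                 provenance = "derived_ekman"),
            class = "current_field")
}

#' Sum current fields on a common grid
#' @param ... `"current_field"` objects sharing lat/lon grids.
#' @return `"current_field"` with provenance `"total"`.
#' @export
add_currents <- function(...) {
  fields <- list(...)
  out <- fields[[1]]
  for (f in fields[-1]) {
    stopifnot(identical(f$lat, out$lat), identical(f$lon, out$lon))
    out$u <- out$u + f$u
    out$v <- out$v + f$v
  }
  out$provenance <- "total"
  out
}

#' Sample a current field at positions
#'
#' Bilinear interpolation in space (exact at grid nodes). Positions outside
#' the grid hull yield `NA` components (flagged missing, never zero).
#'
#' @param field A `"current_field"`.
#' @param lat,lon Query positions, degrees (vectorized).
#' @return `data.frame(u_kmd, v_kmd)` with one row per query.
#' @export
sample_current <- function(field, lat, lon) {
  data.frame(u_kmd = bilinear(field$lat, field$lon, field$u, lat, lon),
             v_kmd = bilinear(field$lat, field$lon, field$v, lat, lon))
}

bilinear <- function(glat, glon, z, lat, lon) {
  i <- findInterval(lat, glat)
  j <- findInterval(lon, glon)
  out <- rep(NA_real_, length(lat))
  ok <- i >= 1 & lat <= glat[length(glat)] & j >= 1 & lon <= glon[length(glon)]
  i <- pmax(i, 1L); j <- pmax(j, 1L)
  i2 <- pmin(i + 1, length(glat)); j2 <- pmin(j + 1, length(glon))
  ty <- ifelse(i2 > i, (lat - glat[i]) / (glat[i2] - glat[i]), 0)
  tx <- ifelse(j2 > j, (lon - glon[j]) / (glon[j2] - glon[j]), 0)
  v <- (1 - ty) * (1 - tx) * z[cbind(i, j)] + (1 - ty) * tx * z[cbind(i, j2)] +
        ty * (1 - tx) * z[cbind(i2, j)] + ty * tx * z[cbind(i2, j2)]
  out[ok] <- v[ok]
  out
}

#' Remove ocean currents from a track
#'
#' Ground velocity per step (east/north displacement over the knot interval)
#' minus the current sampled at the step midpoint gives the swimming
#' velocity; its norm is the swimming speed. Steps whose midpoint falls
#' outside the current field keep `NA` swimming components.
#'
#' @param track A `"regular_track"` (after [mask_gaps()]).
#' @param field A `"current_field"` (km/d).
#' @return `data.frame` of class `"swim_series"`: `id, mid_time, mid_lat,
#'   mid_lon, u_ground, v_ground, u_cur, v_cur, u_swim, v_swim, speed_kmd,
#'   ground_speed_kmd, segment`. `speed_kmd` is the swimming speed so the
#'   result can be passed to the modality functions directly.
#' @export
correct_track <- function(track, field) {
  interval_h <- attr(track, "interval_h")
  if (is.null(interval_h)) interval_h <- 6
  res <- list()
  for (animal in unique(track$id)) {
    tr <- track[track$id == animal & track$valid, , drop = FALSE]
    if (nrow(tr) < 2) next
    i <- seq_len(nrow(tr) - 1)
    same <- tr$segment[i] == tr$segment[i + 1] &
      abs(diff(as.numeric(tr$time)) - interval_h * 3600) < 1
    i <- i[same]
    if (!length(i)) next
    d <- displacement_en(tr$lat[i], tr$lon[i], tr$lat[i + 1], tr$lon[i + 1])
    dt_d <- interval_h / 24
    ug <- d$east_km / dt_d
    vg <- d$north_km / dt_d
    mid_lat <- (tr$lat[i] + tr$lat[i + 1]) / 2
    mid_lon <- wrap_lon(tr$lon[i] + wrap_lon(tr$lon[i + 1] - tr$lon[i]) / 2)
    cur <- sample_current(field, mid_lat, mid_lon)
    us <- ug - cur$u_kmd
    vs <- vg - cur$v_kmd
    res[[animal]] <- data.frame(
      id = animal, mid_time = tr$time[i] + interval_h * 1800,
      mid_lat = mid_lat, mid_lon = mid_lon,
      u_ground = ug, v_ground = vg,
      u_cur = cur$u_kmd, v_cur = cur$v_kmd,
      u_swim = us, v_swim = vs,
      speed_kmd = sqrt(us^2 + vs^2),
      ground_speed_kmd = sqrt(ug^2 + vg^2),
      segment = tr$segment[i], stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  attr(out, "interval_h") <- interval_h
  class(out) <- c("swim_series", "data.frame")
  out
}
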