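# Synthetic ocean fields: sea-surface height, wind stress, 8-day chlorophyll
# composites on a fine grid, and a 1-degree temperature/nitrate profile
# climatology with a latitude-controlled thermocline and nutricline.
# All gridded objects are lists with explicit ascending lat/lon coordinate
# vectors and matrices indexed [lat, lon].

#' Synthetic ocean field parameters
#'
#' @param lat_range,lon_range Domain, degrees.
#' @param res_deg SSH / wind grid spacing (default 1).
#' @param chl_res_deg Chlorophyll composite spacing (default 0.05).
#' @param n_windows Number of 8-day chlorophyll windows (default 16).
#' @param start_time First window start, UTC.
#' @param ssh One of `"gyre"` (smooth anticyclonic bump), `"slope"` (constant
#'   meridional slope `ssh_alpha`), `"flat"`.
#' @param ssh_amp Gyre SSH amplitude, m (default 0.4).
#' @param ssh_alpha Meridional slope for `ssh = "slope"`, m per m northward.
#' @param wind_amp Zonal wind-stress amplitude, N/m^2 (default 0.05).
#' @param chl_foraging_mean,chl_gyre_mean Target mean chlorophyll (mg/m^3) in
#'   the high-latitude "foraging" box and the subtropical "gyre" box
#'   (defaults 0.67 and 0.18, the contrast scale seen between productive
#'   foraging grounds and oligotrophic gyres).
#' @param foraging_lat,gyre_lat Latitude bands (deg) defining the two boxes.
#' @param chl_sdlog Lognormal spread of chlorophyll (default 0.5).
#' @param cloud_frac Fraction of chlorophyll cells masked as cloud (default 0.1).
#' @param therm_shallow,therm_deep,therm_mid_lat,therm_width Thermocline
#'   target-depth shape: depth (m) is `shallow + (deep - shallow) *
#'   exp(-((|lat| - mid_lat)/width)^2)` — deepest in the subtropical gyres,
#'   shallow at the equator and poleward.
#' @param nutricline_frac Nutricline target depth as a fraction of the
#'   thermocline target (default 0.8).
#' @return list of class `"ocean_params"`.
#' @export
ocean_params <- function(lat_range = c(0, 60), lon_range = c(-60, -20),
                         res_deg = 1, chl_res_deg = 0.05, n_windows = 16,
                         start_time = as.POSIXct("2005-01-01", tz = "UTC"),
                         ssh = c("gyre", "slope", "flat"), ssh_amp = 0.4,
                         ssh_alpha = 1e-7, wind_amp = 0.05,
                         chl_foraging_mean = 0.67, chl_gyre_mean = 0.18,
                         foraging_lat = c(40, 60), gyre_lat = c(10, 35),
                         chl_sdlog = 0.5, cloud_frac = 0.1,
                         therm_shallow = 40, therm_deep = 120,
                         therm_mid_lat = 30, therm_width = 15,
                         nutricline_frac = 0.8) {
  ssh <- match.arg(ssh)
  structure(as.list(environment()), class = "ocean_params")
}

# standard depth levels (m) for the profile climatology
STANDARD_DEPTHS <- c(0, 10, 20, 30, 50, 75, 100, 125, 150, 200, 250, 300, 400, 500)

#' Generate synthetic ocean fields
#'
#' Produces SSH and wind-stress grids, a stack of 8-day chlorophyll
#' composites with a latitudinal productivity gradient and lognormal noise,
#' and a 1-degree annual climatology of temperature and nitrate profiles.
#' Temperature profiles place their sharpest gradient in the layer whose
#' midpoint is nearest the latitude-dependent target depth (the stored
#' `target_thermocline` is that snapped midpoint, so analysis recovers it
#' exactly); nitrate increases linearly with depth and crosses 2 umol exactly
#' at `target_nutricline`.
#'
#' @param params An [ocean_params()] list.
#' @param seed Optional integer seed (chlorophyll noise and cloud mask).
#' @return list of class `"synthetic_ocean"` with elements `ssh`, `wind`
#'   (`tau_x`, `tau_y`), `chl` (lat, lon, windows, values\[lat, lon, window\]),
#'   `clim` (lat, lon, depths, temp\[lat, lon, depth\], nitrate\[...\],
#'   `target_thermocline`, `target_nutricline`), and `params`.
#' @export
synth_ocean <- function(params = ocean_params(), seed = NULL) {
  p <- params
  lat <- seq(p$lat_range[1], p$lat_range[2], by = p$res_deg)
  lon <- seq(p$lon_range[1], p$lon_range[2], by = p$res_deg)
  nlat <- length(lat); nlon <- length(lon)

  ssh_z <- switch(p$ssh,
    flat = matrix(0, nlat, nlon),
    slope = matrix(p$ssh_alpha * (lat * pi / 180 * EARTH_RADIUS_KM * 1000),
                   nlat, nlon),
    gyre = {
      lat0 <- mean(p$lat_range); lon0 <- mean(p$lon_range)
      sy <- diff(p$lat_range) / 4; sx <- diff(p$lon_range) / 4
      outer(lat, lon, function(la, lo)
        p$ssh_amp * exp(-((la - lat0) / sy)^2 - ((lo - lon0) / sx)^2))
    })
  ssh <- list(lat = lat, lon = lon, z = ssh_z)

  # zonal trade-wind / westerly pattern, meridional stress zero
  tau_x <- matrix(-p$wind_amp * cos(pi * lat / 30), nlat, nlon)
  wind <- list(lat = lat, lon = lon, tau_x = tau_x,
               tau_y = matrix(0, nlat, nlon))

  # chlorophyll mean surface: gyre floor, foraging-box plateau, smooth ramp
  clat <- seq(p$lat_range[1], p$lat_range[2], by = p$chl_res_deg)
  clon <- seq(p$lon_range[1], p$lon_range[2], by = p$chl_res_deg)
  mu <- chl_mean_profile(clat, p)
  windows <- p$start_time + (seq_len(p$n_windows) - 1) * 8 * 86400
  vals <- with_seed(seed, {
    v <- array(rlnorm(length(clat) * length(clon) * p$n_windows,
                      meanlog = log(mu) - p$chl_sdlog^2 / 2,
                      sdlog = p$chl_sdlog),
               dim = c(length(clat), length(clon), p$n_windows))
    if (p$cloud_frac > 0)
      v[runif(length(v)) < p$cloud_frac] <- NA_real_
    v
  })
  chl <- list(lat = clat, lon = clon, windows = windows, values = vals,
              window_days = 8)

  clim <- make_climatology(lat, lon, p)

  structure(list(ssh = ssh, wind = wind, chl = chl, clim = clim, params = p),
            class = "synthetic_ocean")
}

# latitudinal mean chlorophyll: plateau values inside the named boxes,
# linear ramps between, gyre level as the background
chl_mean_profile <- function(lat, p) {
  mu <- rep(p$chl_gyre_mean, length(lat))
  f <- p$foraging_lat; g <- p$gyre_lat
  mu[lat >= f[1] & lat <= f[2]] <- p$chl_foraging_mean
  ramp <- lat > g[2] & lat < f[1]
  mu[ramp] <- p$chl_gyre_mean + (p$chl_foraging_mean - p$chl_gyre_mean) *
    (lat[ramp] - g[2]) / (f[1] - g[2])
  low <- lat < g[1]  # modest equatorial enhancement
  mu[low] <- p$chl_gyre_mean + (0.3 - p$chl_gyre_mean) *
    (g[1] - lat[low]) / max(g[1], 1)
  mu
}

#' Latitude-dependent thermocline target depth
#' @param lat Latitude(s), degrees.
#' @param p An [ocean_params()] list.
#' @return Target depth(s), m (not yet snapped to layer midpoints).
#' @export
thermocline_target <- function(lat, p) {
  p$therm_shallow + (p$therm_deep - p$therm_shallow) *
    exp(-((abs(lat) - p$therm_mid_lat) / p$therm_width)^2)
}

make_climatology <- function(lat, lon, p) {
  z <- STANDARD_DEPTHS
  nz <- length(z)
  mids <- (z[-nz] + z[-1]) / 2
  tgt_raw <- thermocline_target(lat, p)
  layer <- vapply(tgt_raw, function(d) which.min(abs(mids - d)), 1L)
  tgt <- mids[layer]                      # snapped: analysis recovers exactly
  ntgt <- p$nutricline_frac * tgt
  nlat <- length(lat); nlon <- length(lon)
  temp <- array(NA_real_, c(nlat, nlon, nz))
  nitr <- array(NA_real_, c(nlat, nlon, nz))
  g_base <- 0.01; g_strong <- 0.12        # degC per m
  for (i in seq_len(nlat)) {
    grad <- rep(g_base, nz - 1)
    grad[layer[i]] <- g_strong
    prof <- (28 - 0.2 * abs(lat[i])) - cumsum(c(0, grad * diff(z)))
    nprof <- 2 * z / ntgt[i]             # linear, crosses 2 umol at ntgt
    for (j in seq_len(nlon)) {
      temp[i, j, ] <- prof
      nitr[i, j, ] <- nprof
    }
  }
  list(lat = lat, lon = lon, depths = z, temp = temp, nitrate = nitr,
       target_thermocline = matrix(tgt, nlat, nlon),
       target_nutricline = matrix(ntgt, nlat, nlon))
}

#' Synthetic 6-h dive summaries
#'
#' Each 6-h step of a (true) track yields one dive-summary record whose mean
#' depth is a link function of the local climatological thermocline depth
#' (nearest 1-degree cell) plus Gaussian noise, floored at 0.5 m.
#'
#' @param track A true track from [simulate_true_track()].
#' @param ocean A [synth_ocean()] object.
#' @param noise_sd Depth noise SD, m (default 8).
#' @param seed Optional integer seed.
#' @param id Animal identifier.
#' @param link Link from thermocline depth to mean dive depth (default
#'   identity).
#' @return `data.frame`: `id, bin_start, bin_end, mean_depth_m`.
#' @export
synth_dive_summaries <- function(track, ocean, noise_sd = 8, seed = NULL,
                                 id = "sim", link = identity) {
  cl <- ocean$clim
  ii <- nearest_index(track$lat, cl$lat)
  jj <- nearest_index(track$lon, cl$lon)
  if (anyNA(ii) || anyNA(jj)) stop("track positions fall outside the climatology grid")
  therm <- cl$target_thermocline[cbind(ii, jj)]
  with_seed(seed, {
    depth <- link(therm) + rnorm(length(therm), 0, noise_sd)
    data.frame(id = id,
               bin_start = track$time,
               bin_end = track$time + 6 * 3600,
               mean_depth_m = pmax(depth, 0.5),
               stringsAsFactors = FALSE)
  })
}

nearest_index <- function(x, grid) {
  step <- grid[2] - grid[1]
  i <- round((x - grid[1]) / step) + 1
  i[i < 1 | i > length(grid)] <- NA_integer_
  as.integer(i)
}
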