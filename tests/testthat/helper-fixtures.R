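# Small in-code fixtures shared across tests.

# fixes for one animal at given hour offsets
mk_fixes <- function(lat, lon, hours, lc = "3", id = "t1",
                     t0 = as.POSIXct("2005-01-01", tz = "UTC")) {
  as_fixes(id = id, time = t0 + hours * 3600, lat = lat, lon = lon, lc = lc)
}

# regular eastward equatorial track: fixes every `dt_h` hours moving
# `speed_kmd`, exactly interpolable
mk_equatorial_fixes <- function(n, speed_kmd = 24, dt_h = 6, lc = "3",
                                id = "t1") {
  step_km <- speed_kmd * dt_h / 24
  dlon <- step_km / 111.19492664455873   # km per degree at the equator
  mk_fixes(lat = rep(0, n), lon = (seq_len(n) - 1) * dlon,
           hours = (seq_len(n) - 1) * dt_h, lc = lc, id = id)
}

# single-cell-profile climatology over a small grid
mk_clim <- function(lat = 0:4, lon = 0:4,
                    depths = c(0, 50, 100, 150),
                    temp = c(25, 24, 15, 14),
                    nitrate = c(0.5, 1, 3, 5)) {
  nlat <- length(lat); nlon <- length(lon); nz <- length(depths)
  list(lat = lat, lon = lon, depths = depths,
       temp = array(rep(temp, each = nlat * nlon), c(nlat, nlon, nz)),
       nitrate = array(rep(nitrate, each = nlat * nlon), c(nlat, nlon, nz)))
}

# constant current field over a grid (km/d)
mk_field <- function(u = 10, v = 0, lat = seq(-40, 60, 2),
                     lon = seq(-130, 40, 5)) {
  structure(list(lat = lat, lon = lon,
                 u = matrix(u, length(lat), length(lon)),
                 v = matrix(v, length(lat), length(lon)),
                 provenance = "external"),
            class = "current_field")
}

# chlorophyll stack with controllable values
mk_chl <- function(vals, lat = seq(0, 1, 0.05), lon = seq(0, 1, 0.05),
                   n_win = 2, t0 = as.POSIXct("2005-01-01", tz = "UTC")) {
  v <- array(vals, c(length(lat), length(lon), n_win))
  list(lat = lat, lon = lon, windows = t0 + (seq_len(n_win) - 1) * 8 * 86400,
       values = v, window_days = 8)
}
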