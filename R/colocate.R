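# Environmental co-location: thermocline and nutricline depths from profile
# climatologies, chlorophyll sampling along tracks with a bounded cloud-gap
# search, and dive depth vs latitude summaries.

#' Thermocline depth of a profile
#'
#' The depth of the maximum vertical temperature gradient: gradients are
#' computed between consecutive standard levels and the midpoint depth of the
#' steepest pair is returned; ties break toward the shallower pair. An
#' isothermal profile returns `NA` (flagged undefined).
#'
#' @param temp Temperatures, degC, one per depth level (>= 3 levels).
#' @param depths Strictly increasing depths, m.
#' @return Thermocline depth, m, or `NA` if undefined.
#' @examples
#' thermocline_depth(c(25, 24, 15, 14), c(0, 50, 100, 150))  # 75
#' @export
thermocline_depth <- function(temp, depths) {
  if (length(temp) < 3) stop("profile needs at least 3 depth levels")
  if (any(!is.finite(temp))) stop("temperatures must be finite")
  if (any(diff(depths) <= 0)) stop("depths must be strictly increasing")
  grad <- abs(diff(temp) / diff(depths))
  if (max(grad) == 0) return(NA_real_)
  i <- which.max(grad)  # first maximum = shallower pair
  (depths[i] + depths[i + 1]) / 2
}

#' Nutricline depth of a profile
#'
#' Shallowest depth at which nitrate crosses `threshold_umol`, by linear
#' interpolation between the bracketing levels. If surface nitrate already
#' meets the threshold the nutricline is 0 m; if the threshold is never
#' reached the result is `NA` (flagged undefined).
#'
#' @param nitrate Nitrate concentrations, umol, one per depth level.
#' @param depths Strictly increasing depths, m.
#' @param threshold_umol Isocline threshold (default 2).
#' @return Nutricline depth, m, or `NA`.
#' @examples
#' nutricline_depth(c(0.5, 1, 3), c(0, 50, 100))  # 75
#' @export
nutricline_depth <- function(nitrate, depths, threshold_umol = 2) {
  stopifnot(threshold_umol > 0)
  if (any(!is.finite(nitrate))) stop("nitrate values must be finite")
  if (any(diff(depths) <= 0)) stop("depths must be strictly increasing")
  if (nitrate[1] >= threshold_umol) return(0)
  above <- which(nitrate >= threshold_umol)
  if (!length(above)) return(NA_real_)
  j <- above[1]
  depths[j - 1] + (depths[j] - depths[j - 1]) *
    (threshold_umol - nitrate[j - 1]) / (nitrate[j] - nitrate[j - 1])
}

# apply a profile functional over every cell of a climatology
profile_grid <- function(clim, fun, ...) {
  nlat <- length(clim$lat); nlon <- length(clim$lon)
  out <- matrix(NA_real_, nlat, nlon)
  for (i in seq_len(nlat)) for (j in seq_len(nlon))
    out[i, j] <- fun(i, j, ...)
  out
}

#' Thermocline depth over a climatology grid
#' @param clim Climatology list (lat, lon, depths, temp\[lat, lon, depth\]).
#' @return Matrix \[lat, lon\] of thermocline depths, m.
#' @export
thermocline_grid <- function(clim) {
  profile_grid(clim, function(i, j)
    thermocline_depth(clim$temp[i, j, ], clim$depths))
}

#' Nutricline depth over a climatology grid
#' @inheritParams thermocline_grid
#' @param threshold_umol Nitrate isocline threshold, umol (default 2).
#' @return Matrix \[lat, lon\] of nutricline depths, m.
#' @export
nutricline_grid <- function(clim, threshold_umol = 2) {
  profile_grid(clim, function(i, j)
    nutricline_depth(clim$nitrate[i, j, ], clim$depths, threshold_umol))
}

#' Sample chlorophyll composites along positions
#'
#' For each position/time, picks the 8-day window containing the timestamp
#' and the nearest grid cell; if that cell is cloud-masked the search square
#' expands ring by ring (Chebyshev rings, up to `max_rings`), returning the
#' mean of the valid cells in the first non-empty ring. Positions outside the
#' grid or times outside coverage yield `NA`.
#'
#' @param chl Chlorophyll stack: list(lat, lon, windows, values, window_days).
#' @param lat,lon Positions, degrees (vectorized).
#' @param time Timestamps (`POSIXct`).
#' @param max_rings Maximum search rings around a cloudy cell (default 3).
#' @return Numeric vector of chlorophyll values, mg/m^3 (`NA` = missing).
#' @export
sample_chl <- function(chl, lat, lon, time, max_rings = 3) {
  wi <- findInterval(as.numeric(time),
                     as.numeric(chl$windows))
  n_win <- length(chl$windows)
  wend <- as.numeric(chl$windows[n_win]) + chl$window_days * 86400
  wi[as.numeric(time) >= wend] <- 0L   # past coverage
  ii <- nearest_index(lat, chl$lat)
  jj <- nearest_index(lon, chl$lon)
  nlat <- length(chl$lat); nlon <- length(chl$lon)
  out <- rep(NA_real_, length(lat))
  for (k in seq_along(out)) {
    if (is.na(ii[k]) || is.na(jj[k]) || wi[k] < 1) next
    v <- chl$values[ii[k], jj[k], wi[k]]
    r <- 0
    while (is.na(v) && r < max_rings) {
      r <- r + 1
      is <- max(1, ii[k] - r):min(nlat, ii[k] + r)
      js <- max(1, jj[k] - r):min(nlon, jj[k] + r)
      ring <- chl$values[is, js, wi[k]]
      # keep only the ring itself (drop the interior already searched)
      di <- abs(outer(is - ii[k], rep(0, length(js)), "+"))
      dj <- abs(outer(rep(0, length(is)), js - jj[k], "+"))
      on_ring <- pmax(di, dj) == r
      vals <- ring[on_ring & !is.na(ring)]
      if (length(vals)) v <- mean(vals)
    }
    out[k] <- v
  }
  out
}

#' Summary statistics of chlorophyll samples
#'
#' @param values Chlorophyll samples (mg/m^3); `NA`s (missing/cloud) are
#'   excluded. At least one non-missing value is required.
#' @return list: `mean`, `sd` (`NA` when n = 1), `min`, `max`, `n`.
#' @export
chl_summary <- function(values) {
  v <- values[!is.na(values)]
  if (!length(v)) stop("all chlorophyll samples are missing")
  list(mean = mean(v), sd = if (length(v) > 1) sd(v) else NA_real_,
       min = min(v), max = max(v), n = length(v))
}

#' Dive depth and thermocline/nutricline structure by latitude band
#'
#' Joins 6-h dive summaries to track positions (by animal and bin start
#' time), assigns each record to a 1-degree latitude bin centered on
#' half-integers, and reports per bin the mean and SD of dive depth together
#' with the mean thermocline and nutricline depth over the climatology cells
#' the track visited in that bin.
#'
#' @param dives `data.frame(id, bin_start, bin_end, mean_depth_m)`.
#' @param track A track `data.frame` with `id`/`time`/`lat`/`lon` columns
#'   (a true track or a `"regular_track"`).
#' @param clim Climatology list (see [synth_ocean()]).
#' @param bin_deg Latitude bin width, degrees (default 1).
#' @param threshold_umol Nutricline threshold, umol (default 2).
#' @return `data.frame`: `bin_center_lat, mean_depth, sd_depth, n,
#'   mean_thermocline, mean_nutricline` (SD is `NA` when n = 1). Unjoinable
#'   dive records are dropped with a message.
#' @export
bin_dive_depths <- function(dives, track, clim, bin_deg = 1,
                            threshold_umol = 2) {
  key_d <- paste(dives$id, as.numeric(dives$bin_start))
  tid <- if ("id" %in% names(track)) track$id else "sim"
  key_t <- paste(tid, as.numeric(track$time))
  m <- match(key_d, key_t)
  dropped <- sum(is.na(m))
  if (dropped > 0)
    message(dropped, " dive record(s) could not be joined to track positions")
  ok <- !is.na(m)
  d <- dives[ok, , drop = FALSE]
  lat <- track$lat[m[ok]]
  lon <- track$lon[m[ok]]
  bin <- floor(lat / bin_deg) * bin_deg + bin_deg / 2
  tg <- thermocline_grid(clim)
  ng <- nutricline_grid(clim, threshold_umol)
  ii <- nearest_index(lat, clim$lat)
  jj <- nearest_index(lon, clim$lon)
  out <- lapply(sort(unique(bin)), function(b) {
    sel <- bin == b
    cells <- unique(cbind(ii[sel], jj[sel]))
    cells <- cells[!is.na(cells[, 1]) & !is.na(cells[, 2]), , drop = FALSE]
    data.frame(bin_center_lat = b,
               mean_depth = mean(d$mean_depth_m[sel]),
               sd_depth = if (sum(sel) > 1) sd(d$mean_depth_m[sel]) else NA_real_,
               n = sum(sel),
               mean_thermocline = if (nrow(cells)) mean(tg[cells], na.rm = TRUE) else NA_real_,
               mean_nutricline = if (nrow(cells)) mean(ng[cells], na.rm = TRUE) else NA_real_)
  })
  do.call(rbind, out)
}
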