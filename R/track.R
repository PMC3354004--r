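# Track processing: Argos speed filtering, smoothing + 6-h regularization,
# gap masking, and per-step travel speeds by first differencing.

ARGOS_CLASSES <- c("3", "2", "1", "0", "A", "B", "Z")

#' Assemble an Argos fix table
#'
#' Validates and orders a table of raw Argos fixes. Exact duplicate
#' timestamps within an animal are dropped (first record kept); times must
#' then be strictly increasing per animal.
#'
#' @param id Animal identifier(s).
#' @param time Fix times, `POSIXct` (UTC) or anything coercible by
#'   [as.POSIXct()].
#' @param lat,lon Coordinates in decimal degrees; lon is wrapped to
#'   \[-180, 180).
#' @param lc Argos location class, one of `3,2,1,0,A,B,Z`.
#' @return A `data.frame` of class `"argos_fixes"` with columns
#'   `id, time, lat, lon, lc`, ordered by animal and time.
#' @export
as_fixes <- function(id, time, lat, lon, lc) {
  time <- as.POSIXct(time, tz = "UTC")
  lc <- as.character(lc)
  if (!all(lc %in% ARGOS_CLASSES))
    stop("'lc' must be one of ", paste(ARGOS_CLASSES, collapse = ", "))
  if (any(abs(lat) > 90)) stop("latitude out of range [-90, 90]")
  fx <- data.frame(id = as.character(id), time = time,
                   lat = as.numeric(lat), lon = wrap_lon(as.numeric(lon)),
                   lc = lc, stringsAsFactors = FALSE)
  fx <- fx[order(fx$id, fx$time), , drop = FALSE]
  dup <- duplicated(fx[c("id", "time")])
  if (any(dup)) fx <- fx[!dup, , drop = FALSE]
  rownames(fx) <- NULL
  class(fx) <- c("argos_fixes", "data.frame")
  fx
}

#' Speed and location-class filter for Argos fixes
#'
#' Drops the requested location classes, then makes a single forward pass per
#' animal keeping the first fix and every subsequent fix whose implied
#' great-circle speed from the last *kept* fix does not exceed `max_speed_kmh`
#' (apparent speeds above it are considered biologically unlikely).
#' The result is a subsequence of the input and the filter is idempotent.
#'
#' @param fixes An `argos_fixes` table (see [as_fixes()]).
#' @param max_speed_kmh Speed threshold in km/h (default 10).
#' @param drop_classes Location classes removed before the speed pass
#'   (default `"Z"`; use `character(0)` to analyse all classes).
#' @return Filtered `argos_fixes`.
#' @export
filter_fixes <- function(fixes, max_speed_kmh = 10, drop_classes = "Z") {
  stopifnot(max_speed_kmh > 0)
  if (nrow(fixes) == 0) return(fixes)
  fixes <- fixes[!(fixes$lc %in% drop_classes), , drop = FALSE]
  keep <- logical(nrow(fixes))
  for (animal in unique(fixes$id)) {
    sel <- which(fixes$id == animal)
    tt <- as.numeric(fixes$time[sel])
    if (any(diff(tt) <= 0)) stop("fix times must be strictly increasing within an animal")
    if (length(sel) == 0) next
    last <- 1L
    keep[sel[1]] <- TRUE
    for (i in seq_along(sel)[-1]) {
      dt_h <- (tt[i] - tt[last]) / 3600
      dkm <- great_circle_km(fixes$lat[sel[last]], fixes$lon[sel[last]],
                             fixes$lat[sel[i]], fixes$lon[sel[i]])
      if (dkm / dt_h <= max_speed_kmh) {
        keep[sel[i]] <- TRUE
        last <- i
      }
    }
  }
  out <- fixes[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Smooth and regularize a track to fixed time intervals
#'
#' Fixes are first smoothed by a centered running mean over
#' `smooth_window` fixes (latitudes and unwrapped longitudes; the window
#' shrinks at the track ends), then interpolated along great circles at exact
#' `interval_h`-hour knots counted from each animal's first retained fix.
#' Knots beyond the last fix are not extrapolated; a knot coinciding exactly
#' with a fix time takes that (smoothed) position.
#'
#' @param fixes An `argos_fixes` table with at least 2 fixes per animal.
#' @param interval_h Knot spacing in hours (default 6).
#' @param smooth_window Centered running-mean window in fixes; 1 disables
#'   smoothing (default 3).
#' @return A `data.frame` of class `"regular_track"` with columns
#'   `id, time, lat, lon, valid, segment` (all positions valid until
#'   [mask_gaps()] is applied), and attribute `interval_h`.
#' @export
regularize <- function(fixes, interval_h = 6, smooth_window = 3) {
  stopifnot(interval_h > 0, smooth_window >= 1)
  out <- list()
  for (animal in unique(fixes$id)) {
    fx <- fixes[fixes$id == animal, , drop = FALSE]
    if (nrow(fx) < 2) stop("regularize needs at least 2 fixes per animal")
    lat <- run_mean(fx$lat, smooth_window)
    lon_u <- run_mean(unwrap_lon(fx$lon), smooth_window)
    # a window-mean position corresponds to the window-mean time: with
    # irregular fix times, anchoring it to the middle fix's timestamp would
    # displace fast-moving sections and bias speeds
    tt <- run_mean(as.numeric(fx$time), smooth_window)
    raw_t <- as.numeric(fx$time)
    if (raw_t[length(raw_t)] - raw_t[1] < interval_h * 3600)
      stop("fixes must span at least one interval")
    knots <- seq(raw_t[1], raw_t[length(raw_t)], by = interval_h * 3600)
    knots <- knots[knots >= tt[1] & knots <= tt[length(tt)]]
    idx <- findInterval(knots, tt, rightmost.closed = TRUE)
    frac <- (knots - tt[idx]) / (tt[pmin(idx + 1, length(tt))] - tt[idx])
    frac[!is.finite(frac)] <- 0
    at_knot <- knots == tt[idx]
    frac[at_knot] <- 0
    i2 <- pmin(idx + 1, length(tt))
    p <- gc_interpolate(lat[idx], wrap_lon(lon_u[idx]), lat[i2], wrap_lon(lon_u[i2]), frac)
    out[[animal]] <- data.frame(
      id = animal, time = as.POSIXct(knots, tz = "UTC", origin = "1970-01-01"),
      lat = p$lat, lon = p$lon, valid = TRUE, segment = 1L,
      stringsAsFactors = FALSE)
  }
  tr <- do.call(rbind, out)
  rownames(tr) <- NULL
  attr(tr, "interval_h") <- interval_h
  class(tr) <- c("regular_track", "data.frame")
  tr
}

# centered running mean with shrinking window at the ends
run_mean <- function(x, window) {
  if (window <= 1) return(x)
  h <- (window - 1) %/% 2
  n <- length(x)
  vapply(seq_len(n), function(i) mean(x[max(1, i - h):min(n, i + h)]), 0)
}

#' Mask regularized positions across transmission gaps
#'
#' Positions whose bracketing raw fixes are separated by more than
#' `max_gap_days` are marked invalid (such sections would underestimate
#' travel rate); the segment counter increments across each invalidated run.
#'
#' @param track A `"regular_track"` from [regularize()].
#' @param fixes The (filtered) fixes the track was built from.
#' @param max_gap_days Longest tolerated gap in days (default 3).
#' @return The track with `valid` and `segment` updated; invalid positions
#'   carry `segment = NA`.
#' @export
mask_gaps <- function(track, fixes, max_gap_days = 3) {
  stopifnot(max_gap_days > 0)
  for (animal in unique(track$id)) {
    sel <- which(track$id == animal)
    tt <- as.numeric(fixes$time[fixes$id == animal])
    kt <- as.numeric(track$time[sel])
    idx <- findInterval(kt, tt, rightmost.closed = TRUE)
    gap <- tt[pmin(idx + 1, length(tt))] - tt[idx]
    at_fix <- kt %in% tt
    bad <- !at_fix & gap > max_gap_days * 86400
    track$valid[sel] <- !bad
    seg <- cumsum(c(TRUE, diff(!bad) == 1)) # new segment when valid resumes
    seg[bad] <- NA_integer_
    # renumber segments consecutively within the animal
    track$segment[sel] <- as.integer(factor(seg))
  }
  track
}

#' Travel speeds by first differencing a regularized track
#'
#' One speed per consecutive pair of valid positions within the same segment:
#' great-circle distance divided by the knot interval, in km/d. No speed
#' spans a segment boundary.
#'
#' @param track A `"regular_track"`, typically after [mask_gaps()].
#' @return A `data.frame` of class `"speed_series"` with columns `id,
#'   mid_time, speed_kmd, mid_lat, mid_lon, segment`. Empty (0-row) if no
#'   valid pair exists.
#' @export
compute_speeds <- function(track) {
  interval_h <- attr(track, "interval_h")
  if (is.null(interval_h)) interval_h <- 6
  res <- list()
  for (animal in unique(track$id)) {
    tr <- track[track$id == animal & track$valid, , drop = FALSE]
    if (nrow(tr) < 2) next
    i <- seq_len(nrow(tr) - 1)
    same <- tr$segment[i] == tr$segment[i + 1] &
      abs(diff(as.numeric(tr$time)) - interval_h * 3600) < 1
    if (!any(same)) next
    i <- i[same]
    d <- great_circle_km(tr$lat[i], tr$lon[i], tr$lat[i + 1], tr$lon[i + 1])
    res[[animal]] <- data.frame(
      id = animal,
      mid_time = tr$time[i] + interval_h * 1800,
      speed_kmd = d / (interval_h / 24),
      mid_lat = (tr$lat[i] + tr$lat[i + 1]) / 2,
      mid_lon = wrap_lon(tr$lon[i] + wrap_lon(tr$lon[i + 1] - tr$lon[i]) / 2),
      segment = tr$segment[i],
      stringsAsFactors = FALSE)
  }
  out <- if (length(res)) do.call(rbind, res) else
    data.frame(id = character(), mid_time = as.POSIXct(character(), tz = "UTC"),
               speed_kmd = numeric(), mid_lat = numeric(), mid_lon = numeric(),
               segment = integer(), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "interval_h") <- interval_h
  class(out) <- c("speed_series", "data.frame")
  out
}

#' Run the standard fix-to-speed chain
#'
#' Convenience wrapper: [filter_fixes()] then [regularize()], [mask_gaps()]
#' and [compute_speeds()].
#'
#' @inheritParams filter_fixes
#' @inheritParams regularize
#' @inheritParams mask_gaps
#' @return list with elements `fixes` (filtered), `track`, `speeds`.
#' @export
process_track <- function(fixes, max_speed_kmh = 10, drop_classes = "Z",
                          interval_h = 6, smooth_window = 3, max_gap_days = 3) {
  kept <- filter_fixes(fixes, max_speed_kmh, drop_classes)
  track <- regularize(kept, interval_h, smooth_window)
  track <- mask_gaps(track, kept, max_gap_days)
  list(fixes = kept, track = track, speeds = compute_speeds(track))
}
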