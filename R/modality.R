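# Travel-speed modality: histogram, mode finding, modal transiting speed,
# and classification of putative foraging (slow-speed) locations.

#' Histogram of travel speeds
#'
#' Half-open uniform bins `[k w, (k+1) w)` with the first edge at 0, so a
#' speed exactly on an edge falls in the upper bin. Counts conserve the
#' sample size.
#'
#' @param speeds A `"speed_series"` (see [compute_speeds()]) or a numeric
#'   vector of speeds in km/d.
#' @param bin_width Bin width in km/d (default 5).
#' @return list of class `"speed_histogram"`: `bin_edges`, `bin_centers`,
#'   `counts`, `n`, `bin_width`.
#' @export
speed_histogram <- function(speeds, bin_width = 5) {
  stopifnot(bin_width > 0)
  v <- if (is.data.frame(speeds)) speeds$speed_kmd else as.numeric(speeds)
  if (any(v < 0)) stop("negative speeds: upstream processing error")
  if (length(v) == 0) {
    h <- list(bin_edges = numeric(0), bin_centers = numeric(0),
              counts = integer(0), n = 0L, bin_width = bin_width)
    class(h) <- "speed_histogram"
    return(h)
  }
  nb <- floor(max(v) / bin_width) + 1L
  idx <- pmin(floor(v / bin_width) + 1L, nb)
  counts <- tabulate(idx, nbins = nb)
  h <- list(bin_edges = seq(0, nb * bin_width, by = bin_width),
            bin_centers = (seq_len(nb) - 0.5) * bin_width,
            counts = as.integer(counts), n = length(v), bin_width = bin_width)
  class(h) <- "speed_histogram"
  h
}

#' Locate histogram modes
#'
#' Returns the centers of bins that are local count maxima and exceed both
#' adjacent troughs by at least `min_prominence` times the maximum count.
#' Counts outside the histogram are treated as zero, so a monotone histogram
#' has a single terminal mode. Plateau maxima are represented by their middle
#' bin.
#'
#' @param hist A `"speed_histogram"`.
#' @param min_prominence Fraction of the maximum count a peak must rise above
#'   its neighbouring troughs (default 0.05).
#' @return Mode locations in km/d, ascending.
#' @export
find_modes <- function(hist, min_prominence = 0.05) {
  counts <- hist$counts
  nb <- length(counts)
  if (nb == 0) return(numeric(0))
  r <- rle(counts)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  vals <- c(0, r$values, 0)  # pad with empty bins
  peak_runs <- which(r$values > vals[seq_along(r$values)] &
                     r$values > vals[seq_along(r$values) + 2])
  if (!length(peak_runs)) return(numeric(0))
  peaks <- (starts[peak_runs] + ends[peak_runs]) %/% 2
  thr <- min_prominence * max(counts)
  keep <- vapply(seq_along(peaks), function(i) {
    p <- peaks[i]
    lt <- if (i == 1) 0 else min(counts[peaks[i - 1]:p])      # edge counts as 0
    rt <- if (i == length(peaks)) 0 else min(counts[p:peaks[i + 1]])
    (counts[p] - lt) >= thr && (counts[p] - rt) >= thr
  }, TRUE)
  sort(hist$bin_centers[peaks[keep]])
}

#' Modal transiting speed
#'
#' The histogram mass is partitioned at the minimum-count bin between
#' adjacent modes; the mode whose partition holds the largest mass is taken
#' as the modal transiting speed (pelagic foragers are presumed to spend most
#' of their time transiting). Equal masses break toward the faster mode. A
#' single-mode histogram returns that mode with mass 1.
#'
#' @param hist A `"speed_histogram"`.
#' @param modes Mode locations from [find_modes()] (km/d).
#' @return list: `modal_speed` (km/d), `band_masses` (fraction of the sample
#'   in each mode's partition, named by mode), `cut_points` (partition
#'   boundaries, km/d).
#' @export
modal_transiting_speed <- function(hist, modes) {
  if (length(modes) < 1) stop("at least one mode is required")
  counts <- hist$counts
  centers <- hist$bin_centers
  mode_bins <- vapply(modes, function(m) which.min(abs(centers - m)), 1L)
  cuts <- integer(0)
  if (length(modes) > 1) {
    for (i in seq_len(length(modes) - 1)) {
      rng <- mode_bins[i]:mode_bins[i + 1]
      cuts <- c(cuts, rng[which.min(counts[rng])])
    }
  }
  bounds <- c(0L, cuts, length(counts))
  masses <- vapply(seq_along(modes), function(i)
    sum(counts[(bounds[i] + 1):bounds[i + 1]]) / hist$n, 0)
  best <- which(masses == max(masses))
  best <- best[length(best)]  # tie toward the faster mode
  list(modal_speed = modes[best],
       band_masses = setNames(masses, paste0("mode_", modes)),
       cut_points = hist$bin_edges[cuts + 1])
}

#' Classify foraging-speed locations
#'
#' Relative speed is expressed as percent of the modal transiting speed;
#' steps at or below `fraction` of it are flagged as foraging
#' (area-restricted-search) locations. The threshold is inclusive.
#'
#' @param speeds A `"speed_series"` or numeric vector (km/d).
#' @param modal_speed Modal transiting speed, km/d (> 0).
#' @param fraction Foraging threshold as a fraction of the modal speed,
#'   in (0, 1) (default 0.4).
#' @return list: `foraging` (logical mask), `relative_pct` (percent of modal
#'   speed), `threshold_kmd`.
#' @export
classify_foraging <- function(speeds, modal_speed, fraction = 0.4) {
  stopifnot(modal_speed > 0, fraction > 0, fraction < 1)
  v <- if (is.data.frame(speeds)) speeds$speed_kmd else as.numeric(speeds)
  thr <- fraction * modal_speed
  list(foraging = v <= thr,
       relative_pct = 100 * v / modal_speed,
       threshold_kmd = thr)
}

#' Full modality analysis of a speed series
#'
#' Dip test on the raw (unbinned) speeds, histogram, mode identification,
#' modal transiting speed and foraging threshold in one call.
#'
#' @inheritParams speed_histogram
#' @inheritParams find_modes
#' @inheritParams dip_test
#' @param fraction Foraging threshold fraction (default 0.4).
#' @return list of class `"modality_result"`: `dip`, `p_value`, `n_boot`,
#'   `modes`, `modal_transiting_speed`, `foraging_threshold`, `band_masses`,
#'   `histogram`, `n`.
#' @export
analyze_modality <- function(speeds, bin_width = 5, n_boot = 2000, seed = NULL,
                             min_prominence = 0.05, fraction = 0.4) {
  v <- if (is.data.frame(speeds)) speeds$speed_kmd else as.numeric(speeds)
  ht <- dip_test(v, n_boot = n_boot, seed = seed)
  hist <- speed_histogram(v, bin_width)
  modes <- find_modes(hist, min_prominence)
  mts <- modal_transiting_speed(hist, if (length(modes)) modes else
    hist$bin_centers[which.max(hist$counts)])
  out <- list(dip = unname(ht$statistic), p_value = ht$p.value,
              n_boot = n_boot, modes = modes,
              modal_transiting_speed = mts$modal_speed,
              foraging_threshold = fraction * mts$modal_speed,
              band_masses = mts$band_masses,
              histogram = hist, n = length(v))
  class(out) <- "modality_result"
  out
}

#' @export
print.modality_result <- function(x, ...) {
  cat("Travel-speed modality analysis\n")
  cat(sprintf("  n = %d steps; dip = %.4f, bootstrap p = %.4g (%d resamples)\n",
              x$n, x$dip, x$p_value, x$n_boot))
  cat(sprintf("  modes at %s km/d\n",
              if (length(x$modes)) paste(x$modes, collapse = ", ") else "none prominent"))
  cat(sprintf("  modal transiting speed %.1f km/d; foraging threshold %.1f km/d\n",
              x$modal_transiting_speed, x$foraging_threshold))
  invisible(x)
}
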