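# Plain-text interchange: track and dive CSVs, a long-format CSV dialect for
# gridded fields, and flat key-value (DCF) scenario configuration files.

#' Write / read Argos fix tables as CSV
#'
#' Columns `id, timestamp (ISO-8601 UTC), lat, lon, lc`.
#' @param fixes An `argos_fixes` table.
#' @param path File path.
#' @export
write_tracks <- function(fixes, path) {
  df <- data.frame(id = fixes$id,
                   timestamp = format(fixes$time, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC"),
                   lat = fixes$lat, lon = fixes$lon, lc = fixes$lc)
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_tracks
#' @export
read_tracks <- function(path) {
  df <- read.csv(path, colClasses = c(id = "character", lc = "character"))
  as_fixes(df$id, as.POSIXct(df$timestamp, tz = "UTC",
                             format = "%Y-%m-%dT%H:%M:%OSZ"),
           df$lat, df$lon, df$lc)
}

#' Write / read 6-h dive summaries as CSV
#' @param dives `data.frame(id, bin_start, bin_end, mean_depth_m)`.
#' @param path File path.
#' @export
write_dives <- function(dives, path) {
  df <- data.frame(id = dives$id,
                   bin_start = format(dives$bin_start, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC"),
                   bin_end = format(dives$bin_end, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC"),
                   mean_depth_m = dives$mean_depth_m)
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_dives
#' @export
read_dives <- function(path) {
  df <- read.csv(path, colClasses = c(id = "character"))
  data.frame(id = df$id,
             bin_start = as.POSIXct(df$bin_start, tz = "UTC",
                                    format = "%Y-%m-%dT%H:%M:%OSZ"),
             bin_end = as.POSIXct(df$bin_end, tz = "UTC",
                                  format = "%Y-%m-%dT%H:%M:%OSZ"),
             mean_depth_m = df$mean_depth_m, stringsAsFactors = FALSE)
}

#' Write / read a gridded field in the plain-text grid dialect
#'
#' Long-format CSV with one row per cell: coordinate columns (`lat`, `lon`,
#' optionally `depth` or `window`) followed by one column per variable, and a
#' first comment line `# pelagitrack-grid v1` carrying the variable names.
#' This is the package's portable text serialization for SSH, wind, current,
#' chlorophyll and climatology grids.
#'
#' @param grid A list with `lat`, `lon` and matrix/array components.
#' @param path File path.
#' @param vars Names of the matrix/array components to serialize (default:
#'   all matrix-valued entries).
#' @export
write_grid_csv <- function(grid, path, vars = NULL) {
  if (is.null(vars))
    vars <- names(grid)[vapply(grid, function(x)
      is.matrix(x) || (is.array(x) && length(dim(x)) == 3), TRUE)]
  dims <- dim(grid[[vars[1]]])
  third <- if (length(dims) == 3) {
    if (!is.null(grid$depths)) "depth" else "window"
  } else NULL
  co <- expand.grid(lat = grid$lat, lon = grid$lon,
                    third = if (is.null(third)) NA else
                      if (third == "depth") grid$depths else seq_along(grid$windows))
  df <- co[c("lat", "lon")]
  if (!is.null(third)) df[[third]] <- co$third
  for (v in vars) df[[v]] <- as.vector(grid[[v]])
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# pelagitrack-grid v1 vars=%s", paste(vars, collapse = ",")), con)
  write.csv(df, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_grid_csv
#' @export
read_grid_csv <- function(path) {
  header <- readLines(path, n = 1)
  if (!startsWith(header, "# pelagitrack-grid"))
    stop("not a pelagitrack grid file")
  vars <- strsplit(sub(".*vars=", "", header), ",")[[1]]
  df <- read.csv(path, skip = 1)
  lat <- sort(unique(df$lat)); lon <- sort(unique(df$lon))
  out <- list(lat = lat, lon = lon)
  third <- intersect(c("depth", "window"), names(df))
  if (length(third)) {
    tv <- sort(unique(df[[third]]))
    if (third == "depth") out$depths <- tv
    dims <- c(length(lat), length(lon), length(tv))
  } else dims <- c(length(lat), length(lon))
  ord <- if (length(third))
    order(df[[third]], match(df$lon, lon), match(df$lat, lat)) else
    order(match(df$lon, lon), match(df$lat, lat))
  for (v in vars) out[[v]] <- array(df[[v]][ord], dim = dims)
  out
}

#' Write / read a simulation scenario as a flat key-value file
#'
#' Debian-control-format (DCF) text with a `version` field; regimes are
#' serialized one per `regime_<i>` field as comma-separated
#' `name,center,lo,hi,sd,kappa,occupancy`.
#'
#' @param scenario A [sim_scenario()].
#' @param path File path.
#' @export
write_scenario_config <- function(scenario, path) {
  rg <- vapply(scenario$regimes, function(r)
    paste(r$name, r$speed_center, r$speed_band[1], r$speed_band[2],
          r$speed_sd, r$turning_concentration, r$occupancy, sep = ","), "")
  fields <- c(
    version = "1", name = scenario$name,
    start_lat = scenario$start[1], start_lon = scenario$start[2],
    duration_days = scenario$duration_days,
    start_time = format(scenario$start_time, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC"),
    step_hours = scenario$step_hours, switch_prob = scenario$switch_prob,
    fix_rate = scenario$fix_rate, fix_schedule = scenario$fix_schedule,
    gap_spec = paste(vapply(scenario$gap_spec, paste, "", collapse = ","),
                     collapse = ";"),
    class_mix = paste(scenario$class_mix, collapse = ","),
    class_sd_km = paste(scenario$class_sd_km, collapse = ","),
    seed = if (is.null(scenario$seed)) "" else scenario$seed,
    setNames(rg, paste0("regime_", seq_along(rg))))
  write.dcf(t(as.matrix(fields)), path)
  invisible(path)
}

#' @rdname write_scenario_config
#' @export
read_scenario_config <- function(path) {
  d <- read.dcf(path)
  g <- function(k) unname(d[1, k])
  if (g("version") != "1") stop("unsupported scenario config version")
  rg_keys <- grep("^regime_", colnames(d), value = TRUE)
  regimes <- lapply(rg_keys, function(k) {
    p <- strsplit(g(k), ",")[[1]]
    movement_regime(p[1], as.numeric(p[2]), as.numeric(p[3:4]),
                    as.numeric(p[5]), as.numeric(p[6]), as.numeric(p[7]))
  })
  gaps <- if (nzchar(g("gap_spec")))
    lapply(strsplit(g("gap_spec"), ";")[[1]],
           function(s) as.numeric(strsplit(s, ",")[[1]])) else list()
  sim_scenario(
    name = g("name"), regimes = regimes,
    start = c(as.numeric(g("start_lat")), as.numeric(g("start_lon"))),
    duration_days = as.numeric(g("duration_days")),
    start_time = as.POSIXct(g("start_time"), tz = "UTC",
                            format = "%Y-%m-%dT%H:%M:%OSZ"),
    step_hours = as.numeric(g("step_hours")),
    switch_prob = as.numeric(g("switch_prob")),
    fix_rate = as.numeric(g("fix_rate")), fix_schedule = g("fix_schedule"),
    gap_spec = gaps,
    class_mix = setNames(as.numeric(strsplit(g("class_mix"), ",")[[1]]),
                         ARGOS_CLASSES),
    class_sd_km = setNames(as.numeric(strsplit(g("class_sd_km"), ",")[[1]]),
                           ARGOS_CLASSES),
    seed = if (nzchar(g("seed"))) as.integer(g("seed")) else NULL)
}
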