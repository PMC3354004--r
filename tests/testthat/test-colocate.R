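test_that("thermocline depth is the steepest-gradient layer midpoint", {
  expect_equal(thermocline_depth(c(25, 24, 15, 14), c(0, 50, 100, 150)), 75)
  # isothermal profile is undefined
  expect_true(is.na(thermocline_depth(rep(20, 4), c(0, 50, 100, 150))))
  # equal maximal gradients break toward the shallower pair
  expect_equal(thermocline_depth(c(25, 20, 19, 14), c(0, 50, 100, 150)), 25)
  expect_error(thermocline_depth(c(25, 24), c(0, 50)), "3 depth")
  expect_error(thermocline_depth(c(25, NA, 14), c(0, 50, 100)), "finite")
})

test_that("nutricline depth interpolates the threshold crossing", {
  expect_equal(nutricline_depth(c(0.5, 1, 3), c(0, 50, 100), 2), 75)
  expect_equal(nutricline_depth(c(5, 6, 7), c(0, 50, 100), 2), 0)
  expect_true(is.na(nutricline_depth(c(0.1, 0.2, 0.3), c(0, 50, 100), 2)))
  # monotone in the threshold on increasing profiles
  prof <- c(0.2, 0.8, 1.6, 2.8, 6)
  z <- c(0, 40, 80, 120, 200)
  ths <- c(0.5, 1, 2, 3, 5)
  ds <- vapply(ths, function(t) nutricline_depth(prof, z, t), 0)
  expect_true(all(diff(ds) >= 0))
})

test_that("generator targets are recovered exactly at climatology cells", {
  oc <- synth_ocean(ocean_params(lat_range = c(0, 40), lon_range = c(-40, -30),
                                 n_windows = 2, chl_res_deg = 1), seed = 2)
  tg <- thermocline_grid(oc$clim)
  expect_equal(tg, oc$clim$target_thermocline, tolerance = 1e-9)
  ng <- nutricline_grid(oc$clim)
  expect_equal(ng, oc$clim$target_nutricline, tolerance = 1e-9)
  # constant requested thermocline shape: the generator snaps the target to
  # the nearest standard-layer midpoint, and the analysis recovers that
  # snapped target exactly at every cell
  ocf <- synth_ocean(ocean_params(lat_range = c(0, 10), lon_range = c(0, 10),
                                  therm_shallow = 75, therm_deep = 75,
                                  n_windows = 2, chl_res_deg = 1), seed = 3)
  tgf <- thermocline_grid(ocf$clim)
  expect_equal(tgf, ocf$clim$target_thermocline, tolerance = 1e-12)
  expect_true(all(abs(tgf - 75) <= 12.5 + 1e-9))  # within half a layer
})

test_that("chlorophyll sampling uses nearest cell with bounded ring search", {
  ch <- mk_chl(vals = 0.5)
  t0 <- ch$windows[1] + 3600
  expect_equal(sample_chl(ch, 0.5, 0.5, t0), 0.5)
  # center cell cloudy: mean of the 8 neighbours
  ch2 <- mk_chl(vals = 0.5)
  ci <- which(ch2$lat == 0.5); cj <- which(ch2$lon == 0.5)
  ch2$values[ci, cj, 1] <- NA
  ch2$values[ci - 1, cj, 1] <- 0.9
  expect_equal(sample_chl(ch2, 0.5, 0.5, t0), mean(c(0.9, rep(0.5, 7))))
  # all rings cloudy -> missing
  ch3 <- mk_chl(vals = NA_real_)
  expect_true(is.na(sample_chl(ch3, 0.5, 0.5, t0, max_rings = 3)))
  # outside the grid or coverage -> missing
  expect_true(is.na(sample_chl(ch, 10, 0.5, t0)))
  expect_true(is.na(sample_chl(ch, 0.5, 0.5, t0 + 365 * 86400)))
})

test_that("chlorophyll summaries exclude missing values", {
  s <- chl_summary(c(0.1, 0.2, 0.3, NA))
  expect_equal(s$mean, 0.2)
  expect_equal(c(s$min, s$max), c(0.1, 0.3))
  expect_equal(s$n, 3)
  expect_true(is.na(chl_summary(c(0.5))$sd))
  expect_error(chl_summary(c(NA_real_, NA_real_)), "missing")
})

test_that("synthetic box means are recovered within sampling error", {
  p <- ocean_params(lat_range = c(0, 60), lon_range = c(-30, -25),
                    chl_res_deg = 0.25, n_windows = 3)
  oc <- synth_ocean(p, seed = 4)
  gyre <- oc$chl$lat >= p$gyre_lat[1] & oc$chl$lat <= p$gyre_lat[2]
  v <- oc$chl$values[gyre, , ]
  v <- v[!is.na(v)]
  se <- sd(v) / sqrt(length(v))
  expect_lt(abs(mean(v) - p$chl_gyre_mean), 3 * se)
  # foraging box mean exceeds the gyre mean whenever generator means do
  forg <- oc$chl$lat >= p$foraging_lat[1] & oc$chl$lat <= p$foraging_lat[2]
  expect_gt(mean(oc$chl$values[forg, , ], na.rm = TRUE), mean(v))
})

test_that("dive summaries link to the local thermocline", {
  oc <- synth_ocean(ocean_params(lat_range = c(-10, 45), lon_range = c(-55, -15),
                                 n_windows = 2, chl_res_deg = 1), seed = 5)
  sc <- sim_scenario("d", list(movement_regime("r", 30, c(5, 60), 6, 30, 1)),
                     start = c(10, -35), duration_days = 30, seed = 6)
  tr <- simulate_true_track(sc)
  # zero noise + identity link reproduces the thermocline exactly
  dv <- synth_dive_summaries(tr, oc, noise_sd = 0, seed = 7)
  ii <- round(tr$lat - oc$clim$lat[1]) + 1
  jj <- round(tr$lon - oc$clim$lon[1]) + 1
  expect_equal(dv$mean_depth_m, oc$clim$target_thermocline[cbind(ii, jj)],
               tolerance = 1e-9)
  expect_identical(synth_dive_summaries(tr, oc, seed = 8),
                   synth_dive_summaries(tr, oc, seed = 8))
  # a monotone link preserves shallow-vs-deep ordering
  dvl <- synth_dive_summaries(tr, oc, noise_sd = 0, link = function(d) 0.5 * d)
  expect_equal(dvl$mean_depth_m, 0.5 * dv$mean_depth_m, tolerance = 1e-9)
})

test_that("dive depths bin by latitude with climatology context", {
  oc <- synth_ocean(ocean_params(lat_range = c(0, 20), lon_range = c(-40, -30),
                                 n_windows = 2, chl_res_deg = 1), seed = 9)
  t0 <- as.POSIXct("2005-01-01", tz = "UTC")
  track <- data.frame(id = "a", time = t0 + (0:9) * 21600,
                      lat = c(rep(10.2, 5), rep(12.7, 5)),
                      lon = rep(-35, 10))
  dives <- data.frame(id = "a", bin_start = track$time,
                      bin_end = track$time + 21600,
                      mean_depth_m = c(rep(50, 5), rep(90, 5)))
  tab <- bin_dive_depths(dives, track, oc$clim)
  expect_equal(tab$bin_center_lat, c(10.5, 12.5))
  expect_equal(tab$mean_depth, c(50, 90))
  expect_equal(tab$n, c(5L, 5L))
  expect_true(all(is.finite(tab$mean_thermocline)))
  # an unjoinable record is dropped with a message
  dives2 <- rbind(dives, data.frame(id = "b", bin_start = t0,
                                    bin_end = t0 + 21600, mean_depth_m = 10))
  expect_message(tab2 <- bin_dive_depths(dives2, track, oc$clim), "joined")
  expect_equal(sum(tab2$n), 10)
  # zero-noise identity-link closure: binned dive depth equals binned
  # thermocline depth when the track sits at cell centers
  track3 <- data.frame(id = "c", time = t0 + (0:4) * 21600,
                       lat = rep(10, 5), lon = rep(-35, 5))
  d3 <- data.frame(id = "c", bin_start = track3$time,
                   bin_end = track3$time + 21600,
                   mean_depth_m = rep(oc$clim$target_thermocline[11, 6], 5))
  tab3 <- bin_dive_depths(d3, track3, oc$clim)
  expect_equal(tab3$mean_depth, tab3$mean_thermocline, tolerance = 1e-9)
})
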