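test_that("constant SSH yields zero geostrophic flow", {
  oc <- synth_ocean(ocean_params(lat_range = c(10, 30), lon_range = c(-40, -20),
                                 ssh = "flat", n_windows = 2,
                                 chl_res_deg = 1), seed = 1)
  g <- geostrophic_from_ssh(oc$ssh)
  expect_true(all(abs(g$u) < 1e-12))
  expect_true(all(abs(g$v) < 1e-12))
})

test_that("meridional SSH slope matches the closed-form zonal jet", {
  oc <- synth_ocean(ocean_params(lat_range = c(25, 35), lon_range = c(-40, -30),
                                 ssh = "slope", ssh_alpha = 1e-7,
                                 n_windows = 2, chl_res_deg = 1))
  g <- geostrophic_from_ssh(oc$ssh)
  i30 <- which(g$lat == 30)
  f <- 2 * 7.292115e-5 * sin(30 * pi / 180)
  expected_ms <- -9.81 * 1e-7 / f          # -0.013453 m/s
  expect_equal(g$u[i30, 5] / 86.4, expected_ms, tolerance = 1e-3)
  expect_equal(g$v[i30, 5], 0, tolerance = 1e-9)
})

test_that("beta-plane blending is finite and continuous at the band edge", {
  oc <- synth_ocean(ocean_params(lat_range = c(-10, 10), lon_range = c(-40, -30),
                                 res_deg = 0.2, ssh = "slope",
                                 ssh_alpha = 1e-7, n_windows = 2,
                                 chl_res_deg = 1))
  g <- geostrophic_from_ssh(oc$ssh, band_deg = 4)
  expect_true(all(is.finite(g$u)) && all(is.finite(g$v)))
  # no blow-up inside the equatorial band
  inband <- abs(g$lat) < 4
  expect_true(all(abs(g$u[inband, ]) <= 150))
  # continuity across +/- 4 degrees: less than 5% jump between 3.9 and 4.1
  u39 <- g$u[which.min(abs(g$lat - 3.9)), 5]
  u41 <- g$u[which.min(abs(g$lat - 4.1)), 5]
  expect_lt(abs(u39 - u41), 0.05 * abs(u41))
  expect_error(geostrophic_from_ssh(list(lat = c(0, 2), lon = c(0, 2),
                                         z = matrix(0, 2, 2))), "coarse")
})

test_that("Ekman flow deflects with the expected hemisphere signs", {
  wind <- list(lat = c(-30, 0, 30), lon = c(0, 1, 2),
               tau_x = matrix(0.1, 3, 3), tau_y = matrix(0, 3, 3))
  ek <- ekman_from_wind(wind)
  expect_gt(ek$v[1, 1], 0)    # southern hemisphere: left of the wind
  expect_lt(ek$v[3, 1], 0)    # northern hemisphere: right of the wind
  expect_true(all(is.finite(ek$u[2, ])))  # finite on the equator
  zero <- ekman_from_wind(list(lat = c(-30, 0, 30), lon = 0:2,
                               tau_x = matrix(0, 3, 3),
                               tau_y = matrix(0, 3, 3)))
  expect_true(all(zero$u == 0) && all(zero$v == 0))
})

test_that("current sampling is exact at nodes, bilinear between, NA outside", {
  f <- mk_field(lat = c(0, 2), lon = c(0, 2))
  f$u <- matrix(c(1, 3, 2, 4), 2, 2)       # u[lat, lon]
  expect_equal(sample_current(f, 0, 0)$u_kmd, 1)
  expect_equal(sample_current(f, 2, 0)$u_kmd, 3)
  expect_equal(sample_current(f, 1, 1)$u_kmd, mean(c(1, 2, 3, 4)))
  expect_true(is.na(sample_current(f, 5, 0)$u_kmd))
  expect_true(is.na(sample_current(f, 0, -1)$u_kmd))
})

test_that("current correction is the exact inverse of adding the current", {
  fx <- mk_equatorial_fixes(30, speed_kmd = 30)
  tr <- mask_gaps(regularize(fx, 6, 1), fx)
  fld <- mk_field(u = 10, v = -4)
  sw <- correct_track(tr, fld)
  expect_equal(sw$u_swim, sw$u_ground - 10, tolerance = 1e-12)
  expect_equal(sw$v_swim, sw$v_ground + 4, tolerance = 1e-12)
  # round trip: swimming + current recovers ground velocity exactly
  expect_equal(sw$u_swim + sw$u_cur, sw$u_ground, tolerance = 1e-12)
  expect_equal(sw$v_swim + sw$v_cur, sw$v_ground, tolerance = 1e-12)
  # worked example: ground (30, 0) minus current (10, 0) swims at 20 km/d
  expect_equal(sw$ground_speed_kmd, rep(30, nrow(sw)), tolerance = 1e-6)
  expect_equal(sw$speed_kmd, sqrt((sw$u_ground - 10)^2 + (sw$v_ground + 4)^2),
               tolerance = 1e-12)
  # zero current leaves speeds unchanged
  sw0 <- correct_track(tr, mk_field(u = 0, v = 0))
  expect_equal(sw0$speed_kmd, sw0$ground_speed_kmd, tolerance = 1e-12)
  # outside the field hull the step is flagged missing, not zero
  swna <- correct_track(tr, mk_field(lat = c(50, 60), lon = c(0, 10)))
  expect_true(all(is.na(swna$speed_kmd)))
})
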