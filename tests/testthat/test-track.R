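test_that("speed filter removes implausible jumps with forward-pass semantics", {
  # 1 degree in 1 h is ~111.2 km/h: removed
  fx <- mk_fixes(lat = c(0, 1), lon = c(0, 0), hours = c(0, 1))
  out <- filter_fixes(fx, max_speed_kmh = 10, drop_classes = character(0))
  expect_equal(nrow(out), 1)
  # single fix passes through
  expect_equal(nrow(filter_fixes(mk_fixes(0, 0, 0))), 1)
  # forward pass: speed measured from the last KEPT fix, so the third fix
  # (0.05 deg from the first over 2 h, ~2.8 km/h) is kept
  fx3 <- mk_fixes(lat = c(0, 1, 0.05), lon = c(0, 0, 0), hours = c(0, 1, 2))
  out3 <- filter_fixes(fx3, 10, character(0))
  expect_equal(out3$lat, c(0, 0.05))
  # class dropping happens before the speed pass
  fxz <- mk_fixes(lat = c(0, 0.01), lon = c(0, 0), hours = c(0, 6),
                  lc = c("3", "Z"))
  expect_equal(nrow(filter_fixes(fxz, 10, "Z")), 1)
  expect_equal(nrow(filter_fixes(fxz, 10, character(0))), 2)
  # empty input is fine; non-monotone times are not
  expect_equal(nrow(filter_fixes(fx[0, ], 10)), 0)
  bad <- fx
  bad$time <- rev(bad$time)
  expect_error(filter_fixes(bad, 10, character(0)), "increasing")
})

test_that("speed filter is idempotent and enforces the speed bound", {
  set.seed(21)
  n <- 120
  fx <- mk_fixes(lat = cumsum(rnorm(n, 0, 0.2)),
                 lon = cumsum(rnorm(n, 0.05, 0.2)),
                 hours = cumsum(runif(n, 0.5, 4)))
  f1 <- filter_fixes(fx, 10, character(0))
  f2 <- filter_fixes(f1, 10, character(0))
  expect_identical(f1, f2)
  v <- great_circle_km(head(f1$lat, -1), head(f1$lon, -1),
                       f1$lat[-1], f1$lon[-1]) /
       as.numeric(diff(f1$time), units = "hours")
  expect_true(all(v <= 10 + 1e-9))
})

test_that("regularization interpolates at exact knots", {
  # two fixes 12 h apart: the 6-h knot is the great-circle midpoint
  fx <- mk_fixes(lat = c(0, 0), lon = c(0, 1), hours = c(0, 12))
  tr <- regularize(fx, interval_h = 6, smooth_window = 1)
  expect_equal(nrow(tr), 3)
  expect_equal(tr$lon[2], 0.5, tolerance = 1e-9)
  # fixes already at exact 6-h spacing pass through unchanged
  fx6 <- mk_equatorial_fixes(9)
  tr6 <- regularize(fx6, 6, smooth_window = 1)
  expect_equal(tr6$lat, fx6$lat, tolerance = 1e-12)
  expect_equal(tr6$lon, fx6$lon, tolerance = 1e-9)
  # three collinear equatorial fixes, window 3: the knot at the middle fix
  # time takes the smoothed (longitude-mean) position; end knots outside the
  # smoothed time support are not extrapolated
  fx3 <- mk_fixes(lat = c(0, 0, 0), lon = c(0, 0.4, 0.6), hours = c(0, 6, 12))
  tr3 <- regularize(fx3, 6, smooth_window = 3)
  mid <- which(as.numeric(tr3$time) == as.numeric(fx3$time[2]))
  expect_equal(tr3$lon[mid], mean(c(0, 0.4, 0.6)), tolerance = 1e-6)
  expect_error(regularize(mk_fixes(0, 0, 0)), "at least 2")
})

test_that("gap masking invalidates exactly the knots inside long gaps", {
  hours <- c(0, 6, 12, 12 + 96, 12 + 102)   # a 4-day hole after 12 h
  fx <- mk_fixes(lat = rep(0, 5), lon = c(0, .1, .2, .3, .4), hours = hours)
  tr <- mask_gaps(regularize(fx, 6, 1), fx, max_gap_days = 3)
  kt <- as.numeric(tr$time - tr$time[1], units = "hours")
  inside <- kt > 12 & kt < 12 + 96
  expect_identical(tr$valid, !inside)
  expect_equal(length(unique(tr$segment[tr$valid])), 2)
  expect_true(all(is.na(tr$segment[!tr$valid])))
  # a 2-day gap is tolerated
  fx2 <- mk_fixes(lat = rep(0, 4), lon = c(0, .1, .2, .3),
                  hours = c(0, 6, 54, 60))
  tr2 <- mask_gaps(regularize(fx2, 6, 1), fx2, 3)
  expect_true(all(tr2$valid))
  # two long gaps give three segments
  fx3 <- mk_fixes(lat = rep(0, 6), lon = seq(0, 0.5, 0.1),
                  hours = c(0, 6, 110, 116, 220, 226))
  tr3 <- mask_gaps(regularize(fx3, 6, 1), fx3, 3)
  expect_equal(length(unique(na.omit(tr3$segment))), 3)
})

test_that("speeds come from first differences and never span segments", {
  # consecutive 6-h positions 10 km apart = 40 km/d
  step_deg <- 10 / (pi * 6371 / 180)
  fx <- mk_fixes(lat = c(0, step_deg, 2 * step_deg), lon = c(0, 0, 0),
                 hours = c(0, 6, 12))
  sp <- compute_speeds(regularize(fx, 6, 1))
  expect_equal(sp$speed_kmd, c(40, 40), tolerance = 1e-9)
  # stationary animal
  fx0 <- mk_fixes(lat = rep(5, 3), lon = rep(5, 3), hours = c(0, 6, 12))
  expect_equal(compute_speeds(regularize(fx0, 6, 1))$speed_kmd, c(0, 0))
  # no speed across a masked gap
  fxg <- mk_fixes(lat = rep(0, 4), lon = c(0, .1, .3, .4),
                  hours = c(0, 6, 6 + 96, 12 + 96))
  trg <- mask_gaps(regularize(fxg, 6, 1), fxg, 3)
  spg <- compute_speeds(trg)
  expect_true(all(spg$segment %in% trg$segment))
  expect_lt(nrow(spg), sum(trg$valid) - 1)   # the boundary pair was skipped
  # no valid pairs -> empty series, not an error
  expect_equal(nrow(compute_speeds(trg[trg$valid & trg$segment == 99, ])), 0)
})

test_that("noise-free exactly-6h tracks reproduce generator speeds", {
  sc <- sim_scenario(
    "exact", list(movement_regime("r", 30, c(5, 60), 8, 10, 1)),
    start = c(10, -40), duration_days = 20, fix_rate = 4,
    fix_schedule = "regular",
    class_mix = c("3" = 1, "2" = 0, "1" = 0, "0" = 0, A = 0, B = 0, Z = 0),
    class_sd_km = c("3" = 0, "2" = 0, "1" = 0, "0" = 0, A = 0, B = 0, Z = 0),
    seed = 31)
  tr <- simulate_true_track(sc)
  fx <- degrade_to_argos(tr, sc)
  sp <- compute_speeds(regularize(fx, 6, smooth_window = 1))
  truth <- tr$speed_kmd[-1]
  expect_equal(length(sp$speed_kmd), length(truth))
  rel <- abs(sp$speed_kmd - truth) / truth
  expect_lt(max(rel), 1e-6)
})
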