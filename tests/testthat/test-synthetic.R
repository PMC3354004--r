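test_that("single-regime zero-variance scenario moves at exactly the set pace", {
  sc <- sim_scenario(
    "const", list(movement_regime("r", 21, c(0, 60), 0, 50, 1)),
    start = c(0, 0), duration_days = 1, seed = 1)
  tr <- simulate_true_track(sc)
  expect_equal(nrow(tr), 5)  # 4 six-hour steps plus the start
  d <- great_circle_km(head(tr$lat, -1), head(tr$lon, -1),
                       tr$lat[-1], tr$lon[-1])
  expect_equal(d, rep(21 / 4, 4), tolerance = 1e-9)
})

test_that("simulation is reproducible and validates occupancies", {
  sc <- scenario_na(duration_days = 20, seed = 9)
  expect_identical(simulate_true_track(sc), simulate_true_track(sc))
  bad <- sc
  bad$regimes[[1]]$occupancy <- 0.5
  expect_error(simulate_true_track(bad), "sum to 1")
})

test_that("Markov regime occupancies converge to the stationary weights", {
  sc <- scenario_na(duration_days = 2500, seed = 10)   # 10^4 steps
  tr <- simulate_true_track(sc)
  states <- tr$regime[-1]
  n <- length(states)
  s <- sc$switch_prob
  inflate <- (2 - s) / s   # variance inflation of an AR(1)-like indicator
  for (rg in sc$regimes) {
    p <- rg$occupancy
    se <- sqrt(p * (1 - p) / n * inflate)
    expect_lt(abs(mean(states == rg$name) - p), 2 * se + 1e-12)
  }
})

test_that("speed mixture draws respect bands and occupancies", {
  sc <- scenario_na()
  sp <- simulate_speed_mixture(10000, sc$regimes, seed = 12)
  expect_true(all(sp >= 0 & sp <= 70))
  # i.i.d. draws: binomial SE applies
  expect_lt(abs(mean(sp <= 15) - 0.29), 3 * sqrt(0.29 * 0.71 / 1e4))
  expect_lt(abs(mean(sp >= 20 & sp <= 45) - 0.42), 3 * sqrt(0.42 * 0.58 / 1e4))
})

test_that("Argos degradation honours schedule, gaps, classes and noise", {
  sc <- sim_scenario(
    "clean", list(movement_regime("r", 24, c(0, 60), 5, 20, 1)),
    start = c(5, -30), duration_days = 10, fix_rate = 4,
    fix_schedule = "regular",
    class_mix = c("3" = 1, "2" = 0, "1" = 0, "0" = 0, A = 0, B = 0, Z = 0),
    class_sd_km = c("3" = 0, "2" = 0, "1" = 0, "0" = 0, A = 0, B = 0, Z = 0),
    seed = 13)
  tr <- simulate_true_track(sc)
  fx <- degrade_to_argos(tr, sc)
  # zero error + fix rate equal to step rate: fixes equal true positions
  expect_equal(fx$lat, tr$lat, tolerance = 1e-12)
  expect_equal(fx$lon, tr$lon, tolerance = 1e-12)
  expect_identical(degrade_to_argos(tr, sc), fx)   # same seed, same fixes
  # a transmission hole removes exactly the fixes inside days [3, 5)
  scg <- sc; scg$gap_spec <- list(c(3, 2))
  fg <- degrade_to_argos(tr, scg)
  day <- as.numeric(fg$time - fg$time[1], units = "days")
  expect_false(any(day >= 3 & day < 5))
  expect_true(any(day < 3) && any(day >= 5))
  # class mix concentrated on Z yields all-Z fixes
  scz <- sc
  scz$class_mix <- c("3" = 0, "2" = 0, "1" = 0, "0" = 0, A = 0, B = 0, Z = 1)
  expect_true(all(degrade_to_argos(tr, scz)$lc == "Z"))
})

test_that("noise-free full chain recovers drawn speeds closely", {
  sc <- sim_scenario(
    "rec", scenario_na()$regimes, start = c(12, -50), duration_days = 40,
    fix_rate = 4, fix_schedule = "regular",
    class_mix = c("3" = 1, "2" = 0, "1" = 0, "0" = 0, A = 0, B = 0, Z = 0),
    class_sd_km = c("3" = 0, "2" = 0, "1" = 0, "0" = 0, A = 0, B = 0, Z = 0),
    seed = 14)
  tr <- simulate_true_track(sc)
  fx <- degrade_to_argos(tr, sc)
  sp <- compute_speeds(regularize(fx, 6, smooth_window = 1))
  rel <- abs(sp$speed_kmd - tr$speed_kmd[-1]) / pmax(tr$speed_kmd[-1], 1e-9)
  expect_lt(median(rel), 0.02)
})

test_that("scenario presets encode the study conditions", {
  na <- scenario_na()
  occ <- vapply(na$regimes, `[[`, 0, "occupancy")
  expect_equal(sum(occ), 1)
  expect_equal(occ[[1]], 0.29)                 # slow band 0-15
  expect_equal(occ[[3]], 0.42)                 # transit band 20-45
  expect_equal(na$regimes[[1]]$speed_center, 12.5)
  expect_equal(na$regimes[[3]]$speed_center, 37.5)
  ep <- scenario_ep()
  expect_equal(ep$regimes[[1]]$speed_center, 21)
  expect_equal(ep$regimes[[1]]$occupancy, 1)
  expect_error(movement_regime("x", 10, c(20, 30), 1, 1, 0.5),
               "speed_center")
})
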