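test_that("degenerate generator emits the constant baseline", {
  s <- generate_salinity(constant_config(10))
  expect_equal(nrow(s), 365)
  expect_true(all(s$salinity == 10))
  expect_false(any(duplicated(s$date)))
})

test_that("generation is byte-identical under the same seed", {
  cfg <- salinity_gen_config(basins = c("Barataria", "Calcasieu"),
                             stations_per_basin = 2, years = 2018:2019, seed = 99)
  expect_identical(generate_salinity(cfg), generate_salinity(cfg))
})

test_that("an injected event creates exactly the planned exposure run", {
  ev <- low_salinity_event("Terrebonne", "all", "2018-06-01", 40, target_level = 2)
  s <- generate_salinity(constant_config(10, events = list(ev)))
  w <- exposure_window("summer", 2018)
  expect_equal(max_consecutive_days_in_bin(s, w, "1-3"), 40)
  expect_equal(total_days_in_bin(s, w, "1-3"), 40)
  expect_equal(total_days_below(s, w, 9), 40)
})

test_that("events change values only on their own station-dates", {
  ev <- low_salinity_event("Terrebonne", "all", "2018-06-01", 10, target_level = 1)
  base <- generate_salinity(constant_config(8, seed = 5))
  with_ev <- generate_salinity(constant_config(8, seed = 5, events = list(ev)))
  in_ev <- with_ev$date >= as.Date("2018-06-01") & with_ev$date <= as.Date("2018-06-10")
  expect_equal(with_ev$salinity[!in_ev], base$salinity[!in_ev])
  expect_true(all(with_ev$salinity[in_ev] == 1))
})

test_that("overlapping events on the same station-dates are rejected", {
  e1 <- low_salinity_event("Terrebonne", "all", "2018-06-01", 20, 2)
  e2 <- low_salinity_event("Terrebonne", "all", "2018-06-15", 10, 1)
  expect_error(generate_salinity(constant_config(10, events = list(e1, e2))),
               "overlapping")
})

test_that("salinity is never negative even with heavy noise", {
  cfg <- salinity_gen_config(basins = "Vermilion-Teche", stations_per_basin = 2,
                             years = 2018, seasonal_amplitude = 6, noise_sd = 5,
                             seed = 3)
  expect_true(all(generate_salinity(cfg)$salinity >= 0))
})

test_that("noiseless abundance reproduces the linear predictor exactly", {
  s <- generate_salinity(constant_config(10))
  et <- build_exposure_table(s)
  truth <- model_truth(alpha = c(Terrebonne = 30), sigma_station = 0, sigma = 0)
  a <- generate_abundance(truth, et, records = FALSE)
  expect_true(all(a$abundance == 30))

  ev <- low_salinity_event("Terrebonne", "all", "2018-06-01", 20, 0.5)
  s2 <- generate_salinity(constant_config(10, events = list(ev)))
  et2 <- build_exposure_table(s2)
  expect_equal(et2$s_d_su0.1[1], 20)
  truth2 <- model_truth(alpha = c(Terrebonne = 30), sigma_station = 0,
                        gamma = c(s_d_su0.1 = -0.5), sigma = 0)
  a2 <- generate_abundance(truth2, et2, records = FALSE)
  expect_equal(a2$abundance, 30 - 0.5 * 20)
})

test_that("abundance draws match the generating moments at large n", {
  s <- generate_salinity(salinity_gen_config(basins = "Barataria",
                                             stations_per_basin = 1,
                                             years = 2018, seasonal_amplitude = 0,
                                             ar1_coefficient = 0, noise_sd = 0,
                                             baseline_mean = 10, seed = 1))
  et <- build_exposure_table(s)
  big <- et[rep(1, 4000), ]
  big$station_id <- sprintf("Barataria-S%d", seq_len(nrow(big)))
  truth <- model_truth(alpha = c(Barataria = 25), sigma_station = 0, sigma = 4)
  a <- generate_abundance(truth, big, records = FALSE, seed = 2)
  se <- 4 / sqrt(nrow(big))
  expect_lt(abs(mean(a$abundance) - 25), 3 * se)
  expect_lt(abs(sd(a$abundance) - 4), 0.3)
})

test_that("missing covariate columns named in the truth raise a clear error", {
  s <- generate_salinity(constant_config(10))
  et <- build_exposure_table(s)
  truth <- model_truth(alpha = c(Terrebonne = 30), gamma = c(nope = 1), sigma = 0)
  expect_error(generate_abundance(truth, et), "nope")
})

test_that("fixtures record their truth and satisfy table invariants", {
  fx <- make_fixture("null", seed = 4, stations_per_basin = 3)
  expect_true(all(fx$truth$gamma == 0))
  fx2 <- make_fixture("negative-slope-east", seed = 4, stations_per_basin = 3)
  expect_lt(fx2$truth$gamma[["c.d_su0.1"]], 0)
  for (f in list(fx, fx2)) {
    expect_true(all(f$salinity$salinity >= 0))
    expect_false(any(duplicated(f$exposure[, c("station_id", "year")])))
    expect_true(all(f$exposure$c.d_su0.1 <= f$exposure$s_d_su0.1))
    expect_equal(nrow(f$abundance), nrow(f$exposure))
  }
  expect_error(make_fixture("no-such-scenario"), "arg")
})

test_that("the rf-step fixture plants a detectable step", {
  fx <- make_fixture("rf-step", seed = 8, stations_per_basin = 3)
  expect_equal(fx$truth$step_at, 40)
  lo <- fx$abundance$abundance[fx$exposure$c.d_su0.1 <= 40]
  hi <- fx$abundance$abundance[fx$exposure$c.d_su0.1 > 40]
  expect_gt(mean(lo) - mean(hi), 25)
})
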