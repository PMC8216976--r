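test_that("seasonal range spans all loggers and sites", {
  flat <- make_temps(rep(30, 24))
  r <- seasonal_range(flat)
  expect_equal(c(r$min_c, r$max_c), c(30, 30))

  two <- dplyr::bind_rows(make_temps(c(35, 40), logger = 1),
                          make_temps(c(36, 45), logger = 2))
  r2 <- seasonal_range(two)
  expect_equal(r2$max_c, 45)
  expect_equal(r2$min_c, 35)
  expect_error(seasonal_range(two, season = "cool"), "no readings")
})

test_that("percent of days exceeding counts strict daily maxima", {
  # 10 days, daily peak 46 on the first 3 days, 44 otherwise
  peaks <- c(46, 46, 46, rep(44, 7))
  temps <- make_temps(as.numeric(vapply(peaks, function(p) {
    c(rep(30, 12), p, rep(30, 11))
  }, numeric(24))))
  out <- pct_days_exceeding(temps, threshold = 45)
  expect_equal(out$pct, 30)
  expect_equal(out$n_days, 10)

  # maxima exactly at the threshold never exceed under the strict convention
  at_thr <- make_temps(rep(45, 48))
  expect_equal(pct_days_exceeding(at_thr, 45)$pct, 0)
  expect_equal(pct_days_exceeding(at_thr, 45, strict = FALSE)$pct, 100)
})

test_that("exceedance is monotone non-increasing in the threshold", {
  set.seed(3)
  temps <- make_temps(runif(24 * 30, 20, 50))
  pcts <- vapply(seq(25, 50, by = 5), function(thr) {
    pct_days_exceeding(temps, thr)$pct
  }, numeric(1))
  expect_true(all(diff(pcts) <= 0))
})

test_that("logger pooling by max differs from mean pooling", {
  hot_logger <- make_temps(rep(46, 24), logger = 1)
  cool_logger <- make_temps(rep(30, 24), logger = 2)
  temps <- dplyr::bind_rows(hot_logger, cool_logger)
  expect_equal(pct_days_exceeding(temps, 45, pool = "max")$pct, 100)
  expect_equal(pct_days_exceeding(temps, 45, pool = "mean")$pct, 0)
})

test_that("day partitioning covers every reading exactly once", {
  temps <- make_temps(runif(24 * 7, 20, 40))
  out <- pct_days_exceeding(temps, 25)
  expect_equal(out$n_days, 7)
  expect_equal(out$n_days * 24, nrow(temps))
})

test_that("safety margins compare seasonal maxima to tolerance constants", {
  hot <- make_temps(c(rep(40, 23), 55.5))
  sm <- safety_margin(hot, lt50 = c(E_malaccana = 56.0))
  expect_equal(sm$margin_c, 0.5)

  # average LT50 of the two species against the hot-season maximum
  sm2 <- safety_margin(hot, lt50 = mean(c(56.5, 55.5)))
  expect_equal(sm2$margin_c, 0.5)

  cool <- make_temps(c(rep(20, 23), 49.1), season = "cool")
  sm3 <- safety_margin(cool, lt50 = c(E_radiata = 55.5))
  expect_equal(sm3$margin_c, 6.4)

  # ABT exceedance: 1 of 24 hourly readings above the breakpoint
  sm4 <- safety_margin(hot, lt50 = 56, abt = 50)
  expect_equal(sm4$pct_hours_above_abt, 100 / 24)
})

test_that("temperature generator is deterministic and respects degenerate settings", {
  sc <- thermal_scenario("hot", days = 5, peak_mean = 30, peak_sd = 0,
                         trough_mean = 30, trough_sd = 0, noise_sd = 0,
                         n_loggers = 1)
  a <- simulate_temperatures(sc, seed = 4)
  b <- simulate_temperatures(sc, seed = 4)
  expect_identical(a$temp_c, b$temp_c)
  # flat sinusoid, no noise: constant series
  expect_true(all(a$temp_c == 30))
})

test_that("target envelope is hit exactly and the cool scenario stays inside it", {
  hot <- simulate_temperatures(
    thermal_scenario("hot", days = 20, target_range = c(24.1, 55.5)),
    seed = 12)
  r <- seasonal_range(hot)
  expect_equal(r$min_c, 24.1, tolerance = 1e-9)
  expect_equal(r$max_c, 55.5, tolerance = 1e-9)

  cool <- simulate_temperatures(
    thermal_scenario("cool", days = 15, target_range = c(4.0, 49.1)),
    seed = 13)
  rc <- seasonal_range(cool)
  expect_gte(rc$min_c, 4.0 - 1e-9)
  expect_lte(rc$max_c, 49.1 + 1e-9)
})

test_that("calibrated generator recovers the target exceedance fraction", {
  sc <- thermal_scenario("hot", days = 79, exceed_threshold = 45,
                         target_exceedance = 0.42, noise_sd = 0.2)
  temps <- simulate_temperatures(sc, seed = 8)
  out <- pct_days_exceeding(temps, 45)
  se <- sqrt(0.42 * 0.58 / 79)
  expect_lt(abs(out$pct - 42), 100 * 3 * se)
})
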