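test_that("derive_pool counts individuals of each sex from the pair table", {
  cases <- list(
    # hand count of the individuals in the rising-tide trail pairs
    list(counts = c(68, 26, 12, 20), m = 132, n = 120),
    list(counts = c(0, 5, 0, 0), m = 10, n = 0),   # all-male pairs
    list(counts = c(1, 0, 1, 0), m = 2, n = 2)     # two mixed pairs
  )
  for (cs in cases) {
    k <- cs$counts
    pool <- derive_pool(pair_counts(FM = k[1], MM = k[2], MF = k[3],
                                    FF = k[4]))
    expect_equal(pool$m, cs$m)
    expect_equal(pool$n, cs$n)
    expect_equal(pool$m + pool$n, 2 * sum(k))
  }
  expect_error(pair_counts(FM = 0, MM = 0, MF = 0, FF = 0), "empty table")
})

test_that("closed-form expectations match hand-derived values", {
  # large mixed pool from the rising-tide trail pairs
  e <- expected_random_pairing(sexed_pool(132, 120), N = 126)
  expect_equal(e$expected[["FM"]], 60 * 132 / 251, tolerance = 1e-12)
  expect_equal(round(e$expected[["FM"]], 1), 31.6)

  # single-sex pool forces the one possible combination
  e2 <- expected_random_pairing(sexed_pool(0, 6), N = 3)
  expect_equal(unname(e2$expected), c(0, 0, 0, 3))

  # m = n = 2: exact enumeration of the 3 matchings x orientations gives
  # E[FM] = E[MF] = 2/3 and E[MM] = E[FF] = 1/3
  e3 <- expected_random_pairing(sexed_pool(2, 2), N = 2)
  expect_equal(unname(e3$expected), c(2, 1, 2, 1) / 3, tolerance = 1e-15)

  expect_error(expected_random_pairing(sexed_pool(3, 3), N = 4),
               "inconsistent")
})

test_that("expectations conserve N and are symmetric in the mixed categories", {
  for (pool in random_pool_battery()) {
    e <- expected_random_pairing(pool)
    expect_equal(sum(e$expected), (pool$m + pool$n) / 2, tolerance = 1e-12)
    expect_identical(e$expected[["FM"]], e$expected[["MF"]])
    expect_true(all(e$expected >= 0))
  }
})

test_that("goodness-of-fit test reproduces the printed statistics", {
  rising <- pair_counts(FM = 68, MM = 26, MF = 12, FF = 20)
  g <- chi_squared_gof(rising)
  expect_equal(g$chi2, 58.79, tolerance = 0.02 / 58.79)
  expect_equal(g$df, 3L)
  expect_lt(g$p_value, 0.001)

  towers <- pair_counts(FM = 23, MM = 17, MF = 7, FF = 17,
                        association_type = "tower")
  g2 <- chi_squared_gof(towers)
  expect_equal(g2$chi2, 8.25, tolerance = 0.02 / 8.25)
  expect_lt(g2$p_value, 0.05)

  # cross-check the Pearson statistic against stats::chisq.test given the
  # same expectations (independent of our accumulation)
  ref <- suppressWarnings(
    stats::chisq.test(unclass(rising$counts),
                      p = g$expected$expected / rising$N)
  )
  expect_equal(g$chi2, unname(ref$statistic), tolerance = 1e-12)
})

test_that("zero-expectation categories are dropped and df reduced", {
  all_female <- pair_counts(FM = 0, MM = 0, MF = 0, FF = 3)
  g <- chi_squared_gof(all_female)
  expect_equal(g$chi2, 0)
  expect_equal(g$df, 0L)
  expect_equal(g$p_value, 1)
  expect_true(any(grepl("dropped zero-expectation", g$warnings)))
})

test_that("small expected counts trigger a warning entry", {
  g <- chi_squared_gof(pair_counts(FM = 2, MM = 1, MF = 0, FF = 1))
  expect_true(any(grepl("below 5", g$warnings)))
  expect_true(any(g$expected$expected < 5))
})

test_that("significance formatting follows the reporting convention", {
  expect_equal(format_p_convention(0.0005), "p < .001")
  expect_equal(format_p_convention(0.01), "p < .05")
  expect_equal(format_p_convention(0.2), "n.s.")
})

test_that("preference estimator recovers the boundary and plug-in cases", {
  # O_FM below the null expectation clips to 0
  low <- pair_counts(FM = 5, MM = 40, MF = 35, FF = 20)
  est <- preference_estimate(low)
  expect_equal(est$theta_hat, 0)
  expect_true(est$clipped)

  # every pair FM estimates theta = 1
  all_fm <- pair_counts(FM = 8, MM = 0, MF = 0, FF = 0)
  expect_equal(preference_estimate(all_fm)$theta_hat, 1)

  # plug-in for the rising-tide trail table: (68 - 31.55)/(126 - 31.55)
  est2 <- preference_estimate(pair_counts(FM = 68, MM = 26, MF = 12, FF = 20))
  expect_equal(est2$theta_hat, (68 - 60 * 132 / 251) / (126 - 60 * 132 / 251),
               tolerance = 1e-12)
  expect_equal(est2$theta_hat, 0.386, tolerance = 0.002)

  expect_error(preference_estimate(pair_counts(FM = 0, MM = 5, MF = 0,
                                               FF = 0)),
               "single-sex")
})
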