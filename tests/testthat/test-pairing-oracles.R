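test_that("brute-force enumeration agrees with the closed form", {
  # every even pool up to 8 individuals
  for (tot in c(2, 4, 6, 8)) {
    for (m in 0:tot) {
      ex <- exact_enumeration(sexed_pool(m, tot - m))
      cf <- expected_random_pairing(sexed_pool(m, tot - m))$expected
      expect_equal(ex$expected, cf, tolerance = 1e-12)
      expect_equal(sum(ex$distribution$prob), 1, tolerance = 1e-12)
    }
  }
})

test_that("enumeration handles the hand-checkable pools", {
  expect_equal(exact_enumeration(sexed_pool(2, 2))$expected[["FM"]], 2 / 3,
               tolerance = 1e-15)
  ex <- exact_enumeration(sexed_pool(1, 1))
  expect_equal(ex$expected[["FM"]], 0.5, tolerance = 1e-15)
  expect_equal(ex$expected[["MF"]], 0.5, tolerance = 1e-15)
  expect_equal(exact_enumeration(sexed_pool(4, 0))$expected[["MM"]], 2,
               tolerance = 1e-15)
  expect_error(exact_enumeration(sexed_pool(10, 10)), "cap")
  expect_error(exact_enumeration(sexed_pool(2, 1)), "even")
})

test_that("Monte-Carlo means sit within 3 standard errors of the closed form", {
  pools <- list(sexed_pool(6, 4), sexed_pool(5, 5), sexed_pool(20, 10))
  for (i in seq_along(pools)) {
    mc <- monte_carlo_null(pools[[i]], replicates = 3000, seed = 300 + i)
    for (j in 1:4) {
      se <- max(mc$summary$se[j], 1e-9)
      expect_lt(abs(mc$summary$mean[j] - mc$summary$analytic[j]), 3 * se)
    }
  }
})

test_that("Monte-Carlo null is deterministic given the seed and degenerate for single-sex pools", {
  a <- monte_carlo_null(sexed_pool(4, 4), replicates = 100, seed = 9)
  b <- monte_carlo_null(sexed_pool(4, 4), replicates = 100, seed = 9)
  expect_identical(a$counts, b$counts)
  expect_identical(a$chi2, b$chi2)

  allf <- monte_carlo_null(sexed_pool(0, 6), replicates = 50, seed = 2)
  expect_true(all(allf$counts[, "FF"] == 3))
  expect_true(all(allf$counts[, c("FM", "MM", "MF")] == 0))

  expect_error(monte_carlo_null(sexed_pool(3, 2), seed = 1), "even")
})

test_that("Monte-Carlo p-value agrees with the analytic tail for a large balanced pool", {
  obs <- pair_counts(FM = 68, MM = 26, MF = 12, FF = 20)
  pool <- derive_pool(obs)
  mc <- monte_carlo_null(pool, replicates = 2000, seed = 77, observed = obs)
  # chi2 = 58.8 is far in the tail of both references
  expect_lt(mc$p_value, 0.01)
  g <- chi_squared_gof(obs, method = "monte_carlo", null = mc)
  expect_equal(g$p_value, mc$p_value)
  expect_identical(g$method, "monte_carlo")
})
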