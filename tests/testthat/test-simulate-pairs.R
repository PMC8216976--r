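test_that("pair generator is deterministic given the seed", {
  sc <- pairing_scenario(m = 20, n = 16, theta = 0.3, seed = 5)
  a <- simulate_pairs(sc)
  b <- simulate_pairs(sc)
  expect_identical(a$counts, b$counts)
  expect_identical(attr(a, "truth"), attr(b, "truth"))
})

test_that("theta = 1 with a balanced pool forces every pair to FM", {
  for (seed in 1:5) {
    tab <- simulate_pairs(pairing_scenario(m = 12, n = 12, theta = 1,
                                           seed = seed))
    expect_equal(unname(tab$counts), c(12, 0, 0, 0))
    expect_equal(attr(tab, "truth")$n_fallback, 0)
  }
})

test_that("infeasible preference events fall back to null pairing and are logged", {
  # only 2 females available but theta = 1 asks for 6 directed pairs
  tab <- simulate_pairs(pairing_scenario(m = 10, n = 2, theta = 1, seed = 31))
  truth <- attr(tab, "truth")
  expect_equal(truth$n_preference, 2)
  expect_gt(truth$n_fallback, 0)
  expect_equal(tab$N, 6)
})

test_that("theta = 0 draws match the null expectations", {
  pool <- sexed_pool(14, 10)
  e <- expected_random_pairing(pool)$expected
  counts <- t(vapply(1:400, function(s) {
    unclass(simulate_pairs(pairing_scenario(14, 10, theta = 0,
                                            seed = 9000 + s))$counts)
  }, integer(4)))
  for (j in 1:4) {
    se <- stats::sd(counts[, j]) / sqrt(nrow(counts))
    expect_lt(abs(mean(counts[, j]) - e[j]), 3 * max(se, 1e-9))
  }
})

test_that("scenario validation rejects impossible configurations", {
  expect_error(pairing_scenario(m = 5, n = 4, N = 5, theta = 0, seed = 1),
               "2 \\* N")
  expect_error(pairing_scenario(m = 4, n = 4, theta = 1.2, seed = 1),
               "theta")
  expect_error(pairing_scenario(m = 4, n = 4, theta = 0), "seed")
})

test_that("power is near alpha at theta = 0 and saturates at theta = 1", {
  pc <- power_curve(m = 20, n = 20, theta = c(0, 1), alpha = 0.05,
                    replicates = 120, seed = 17, method = "monte_carlo",
                    null_replicates = 1500)
  p0 <- pc$power[pc$theta == 0]
  expect_lt(p0, 0.05 + 3 * sqrt(0.05 * 0.95 / 120))
  expect_gt(pc$power[pc$theta == 1], 0.99)
  # analytic route is conservative, never anti-conservative
  pa <- power_curve(m = 20, n = 20, theta = 0, alpha = 0.05,
                    replicates = 120, seed = 18, method = "analytic")
  expect_lt(pa$power, 0.05 + 3 * sqrt(0.05 * 0.95 / 120))
})
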