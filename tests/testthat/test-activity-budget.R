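test_that("each activity category is scored at most once per individual", {
  # two stress-mitigation behaviors together count once
  s1 <- score_individual(c("aggregating", "in_crevice"))
  expect_equal(s1[["stress_mitigation"]], 1)
  expect_equal(sum(s1), 1)

  # multifunctional: mating while turning flags two categories
  s2 <- score_individual(c("mating", "turning"))
  expect_equal(s2[["reproduction"]], 1)
  expect_equal(s2[["foraging"]], 1)
  expect_equal(sum(s2), 2)

  s3 <- score_individual("stationary")
  expect_equal(unname(s3), c(0, 0, 0, 1))

  expect_error(score_individual("basking"), "unknown behavior")
  expect_error(score_individual(character(0)), "non-empty")
})

test_that("hourly budget reports percent of scanned individuals per behavior", {
  sets <- c(replicate(4, "moving", simplify = FALSE),
            replicate(6, "stationary", simplify = FALSE))
  hb <- hourly_budget(make_scans(sets))
  expect_equal(hb$pct[hb$behavior == "moving"], 40)
  expect_equal(hb$n_scanned[1], 10)

  # all ten snails mating while moving: both behaviors at 100%, summing to 200
  hb2 <- hourly_budget(make_scans(replicate(10, c("mating", "moving"),
                                            simplify = FALSE)))
  expect_equal(hb2$pct[hb2$behavior == "mating"], 100)
  expect_equal(hb2$pct[hb2$behavior == "moving"], 100)
  expect_equal(sum(hb2$pct), 200)

  # an hour with no individuals simply does not appear
  expect_false(as.POSIXct("2015-08-01 11:00:00", tz = "UTC") %in% hb$hour)
})

test_that("seasonal allocation pools individual-scans and covers all categories", {
  all_still <- seasonal_allocation(make_scans(replicate(20, "stationary",
                                                        simplify = FALSE)))
  expect_equal(all_still$pct[all_still$category == "inactive"], 100)
  expect_equal(sum(all_still$pct), 100)

  half <- make_scans(c(replicate(10, "moving", simplify = FALSE),
                       replicate(10, "standing", simplify = FALSE)))
  al <- seasonal_allocation(half)
  expect_equal(al$pct[al$category == "foraging"], 50)
  expect_equal(al$pct[al$category == "stress_mitigation"], 50)
  expect_equal(al$pct[al$category == "reproduction"], 0)
})

test_that("allocations sum to 100 exactly without multifunctional scans, above otherwise", {
  plain <- make_scans(c(replicate(5, "moving", simplify = FALSE),
                        replicate(5, "mating", simplify = FALSE),
                        replicate(5, "stationary", simplify = FALSE)))
  expect_equal(sum(seasonal_allocation(plain)$pct), 100)

  multi <- make_scans(c(replicate(5, c("mating", "moving"), simplify = FALSE),
                        replicate(5, "stationary", simplify = FALSE)))
  expect_gt(sum(seasonal_allocation(multi)$pct), 100)
})

test_that("pooled and hour-averaged allocations differ under unequal abundance", {
  h1 <- make_scans(replicate(30, "moving", simplify = FALSE),
                   timestamp = as.POSIXct("2015-08-01 10:00:00", tz = "UTC"))
  h2 <- make_scans(replicate(2, "stationary", simplify = FALSE),
                   timestamp = as.POSIXct("2015-08-01 11:00:00", tz = "UTC"))
  recs <- dplyr::bind_rows(h1, h2)
  pooled <- seasonal_allocation(recs, basis = "pooled")
  hourly <- seasonal_allocation(recs, basis = "hourly_mean")
  expect_equal(pooled$pct[pooled$category == "foraging"], 100 * 30 / 32)
  expect_equal(hourly$pct[hourly$category == "foraging"], 50)
})

test_that("generator round-trip recovers the configured category mix", {
  sc <- tide_scenario(regime = "hot")
  recs <- simulate_scans(sc, hours = 48, snails_per_quadrat = 6, seed = 21)
  truth <- attr(recs, "truth")
  al <- seasonal_allocation(recs)
  n <- nrow(recs)
  for (cat in levels(al$category)) {
    p_true <- truth$expected_allocation$pct[
      truth$expected_allocation$category == cat] / 100
    se <- sqrt(max(p_true * (1 - p_true), 1e-9) / n)
    got <- al$pct[al$category == cat] / 100
    expect_lt(abs(got - p_true), 3 * se + 1e-9)
  }
})

test_that("hourly budget recovers the configured mating fraction when awash on a rising tide", {
  sc <- tide_scenario(regime = "hot")
  recs <- simulate_scans(sc, hours = 72, snails_per_quadrat = 6, seed = 33)
  rising <- recs[recs$phase == "awash_rising", ]
  hb <- hourly_budget(rising)
  mating <- hb[hb$behavior == "mating", ]
  n <- sum(unique(hb[, c("hour", "n_scanned")])$n_scanned)
  # configured: 15% mating+moving and 5% mating alone => 20% show mating
  overall <- 100 * sum(mating$n_individuals) / n
  expect_lt(abs(overall - 20), 100 * 3 * sqrt(0.2 * 0.8 / n))
})

test_that("cool-season regime has no reproduction and no shell posturing", {
  recs <- simulate_scans(tide_scenario(regime = "cool"), hours = 48,
                         seed = 44)
  al <- seasonal_allocation(recs)
  expect_equal(al$pct[al$category == "reproduction"], 0)
  expect_lt(al$pct[al$category == "foraging"], 5)
  hb <- hourly_budget(recs)
  expect_false(any(hb$behavior %in% c("standing", "towering")))
})
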