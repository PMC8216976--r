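# Shared fixtures built in code.

# A battery of valid pools (even total, both small and large, including
# single-sex) drawn once under a fixed seed.
random_pool_battery <- function(n_pools = 30, max_half = 120, seed = 101) {
  set.seed(seed)
  lapply(seq_len(n_pools), function(i) {
    N <- sample(1:max_half, 1)
    m <- sample(0:(2 * N), 1)
    sexed_pool(m = m, n = 2 * N - m)
  })
}

# Scan records where every individual-scan is a literal behavior set.
make_scans <- function(behavior_sets,
                       timestamp = as.POSIXct("2015-08-01 10:00:00",
                                              tz = "UTC"),
                       species = "E_malaccana", season = "hot") {
  tibble::tibble(
    timestamp = timestamp,
    quadrat = 1L,
    species = species,
    individual = seq_along(behavior_sets),
    behaviors = vapply(behavior_sets, paste, "", collapse = ";"),
    season = season
  )
}

# Hourly series with one reading per hour at the given temperatures.
make_temps <- function(temp_c, logger = 1L, site = 1L, season = "hot",
                       start = as.POSIXct("2015-07-01 00:00:00", tz = "UTC")) {
  tibble::tibble(
    timestamp = start + 3600 * (seq_along(temp_c) - 1),
    logger = logger, site = site, temp_c = temp_c, season = season
  )
}
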