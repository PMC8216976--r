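#!/usr/bin/env Rscript
# Seasonal activity budgets from simulated scan surveys: a hot-season and a
# cool-season 24-hr hourly survey (10 quadrats per hour) generated from the
# tidal-cycle behavior model, summarized as hourly behavior percentages and
# seasonal category allocations.

suppressPackageStartupMessages({
  library(tidepair)
  library(dplyr)
})

dir.create("results", showWarnings = FALSE)

hot <- simulate_scans(tide_scenario(regime = "hot"), hours = 24,
                      snails_per_quadrat = 6, season = "hot", seed = 2015)
cool <- simulate_scans(tide_scenario(regime = "cool"), hours = 24,
                       snails_per_quadrat = 6, season = "cool",
                       start = as.POSIXct("2016-02-01 00:00:00", tz = "UTC"),
                       seed = 2016)
records <- bind_rows(hot, cool)

budget <- hourly_budget(records)
readr::write_tsv(budget, "results/hourly_budget.tsv")

alloc_pooled <- bind_rows(seasonal_allocation(hot),
                          seasonal_allocation(cool))
alloc_hourly <- bind_rows(seasonal_allocation(hot, basis = "hourly_mean"),
                          seasonal_allocation(cool, basis = "hourly_mean"))
readr::write_tsv(alloc_pooled, "results/seasonal_allocation_pooled.tsv")
readr::write_tsv(alloc_hourly, "results/seasonal_allocation_hourly_mean.tsv")

cat("Seasonal category allocations (pooled individual-scans):\n")
print(as.data.frame(alloc_pooled), row.names = FALSE)

cat("\nHot-season hours where behavior percentages sum above 100\n")
over <- budget |>
  filter(hour %in% unique(hot$timestamp)) |>
  group_by(hour) |>
  summarise(total_pct = sum(pct), .groups = "drop") |>
  filter(total_pct > 100)
cat(sprintf("  %d of %d surveyed hours (multifunctional behavior)\n",
            nrow(over), dplyr::n_distinct(hot$timestamp)))

cat("\nReading: the simulated hot season splits activity across foraging,\n",
    "reproduction and shell-posturing stress mitigation keyed to the tidal\n",
    "phase, while the cool season is dominated by crevice/aggregation\n",
    "stress mitigation and inactivity, with reproduction absent.\n", sep = "")
cat("\nWrote results/hourly_budget.tsv and seasonal allocation tables\n")
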