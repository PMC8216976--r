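#!/usr/bin/env Rscript
# Thermal environment of the snail resting zone: simulated hot-season
# (79 days) and cool-season (73 days) hourly logger series at two sites,
# summarized as seasonal ranges, percent of days whose maximum exceeds a
# threshold, and thermal-safety margins against the species' LT50s.

suppressPackageStartupMessages({
  library(tidepair)
  library(dplyr)
})

dir.create("results", showWarnings = FALSE)

# Site exceedance targets for the hot (45 C) and cool (40 C) season models
hot <- bind_rows(
  simulate_temperatures(thermal_scenario("hot", days = 79, site = 1,
                                         exceed_threshold = 45,
                                         target_exceedance = 0.25),
                        seed = 301),
  simulate_temperatures(thermal_scenario("hot", days = 79, site = 2,
                                         exceed_threshold = 45,
                                         target_exceedance = 0.42),
                        seed = 302)
)
cool <- bind_rows(
  simulate_temperatures(thermal_scenario("cool", days = 73, site = 1,
                                         exceed_threshold = 40,
                                         target_exceedance = 0.08),
                        seed = 303),
  simulate_temperatures(thermal_scenario("cool", days = 73, site = 2,
                                         exceed_threshold = 40,
                                         target_exceedance = 0.03),
                        seed = 304)
)
temps <- bind_rows(hot, cool)

ranges <- seasonal_range(temps)
cat("Seasonal temperature ranges (all loggers, both sites):\n")
print(as.data.frame(ranges), row.names = FALSE)
readr::write_tsv(ranges, "results/thermal_ranges.tsv")

exceed <- bind_rows(pct_days_exceeding(hot, threshold = 45),
                    pct_days_exceeding(cool, threshold = 40))
cat("\nPercent of days whose maximum exceeded the seasonal threshold:\n")
print(as.data.frame(exceed), row.names = FALSE)
readr::write_tsv(exceed, "results/thermal_exceedance.tsv")

# summer LT50 in air: 56.5 C (E. malaccana), 55.5 C (E. radiata)
margins <- safety_margin(temps, lt50 = c(E_malaccana = 56.5,
                                         E_radiata = 55.5))
cat("\nThermal-safety margins (LT50 minus seasonal maximum):\n")
print(as.data.frame(margins), row.names = FALSE)
readr::write_tsv(margins, "results/thermal_safety_margins.tsv")

cat("\nReading: hot-season daily maxima approach the lethal limits of both\n",
    "species (margins of only a few degrees), which is the selective\n",
    "context for the stress-mitigating behaviors in the activity budget.\n",
    sep = "")
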