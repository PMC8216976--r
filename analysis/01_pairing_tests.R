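#!/usr/bin/env Rscript
# Are trail-following pairs and two-snail towers random with respect to sex?
# Tests each observed count table against the finite-pool random-pairing
# null and writes the tidy report to results/pairing_tests.tsv.

suppressPackageStartupMessages({
  library(tidepair)
  library(dplyr)
})

dir.create("results", showWarnings = FALSE)

tabs <- printed_pair_tables()
fits <- lapply(tabs, chi_squared_gof)

for (g in fits) print(g)

write_report(fits, "results/pairing_tests.tsv")

summary <- bind_rows(lapply(fits, function(g) {
  tibble::tibble(
    association = g$observed$association_type,
    species = g$observed$species,
    tide_phase = g$observed$tide_phase,
    N = g$observed$N,
    chi2 = round(g$chi2, 2),
    df = g$df,
    significance = format_p_convention(g$p_value)
  )
}))
cat("\nSummary of the eight tests:\n")
print(as.data.frame(summary), row.names = FALSE)

cat("\nReading: on rising tides and in towers the dominant combination is a\n",
    "male tracking (or on top of) a female — far more often than random\n",
    "pairing predicts. On falling tides trail-following sexes are random,\n",
    "consistent with a switch from mate search to aggregation formation.\n",
    sep = "")
cat("\nWrote results/pairing_tests.tsv\n")
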