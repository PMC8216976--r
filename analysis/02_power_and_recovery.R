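#!/usr/bin/env Rscript
# How strong is the rising-tide pairing preference, and could the sampling
# design have detected weaker ones? Estimates the preference strength theta
# for each observed table, maps the power of the goodness-of-fit test across
# theta at the rising-tide trail geometry (m = 132, n = 120, N = 126), and
# checks that the moment estimator recovers known theta from simulation.

suppressPackageStartupMessages({
  library(tidepair)
  library(dplyr)
})

dir.create("results", showWarnings = FALSE)
seed <- 20160401

tabs <- printed_pair_tables()

cat("Plug-in preference estimates (theta_hat):\n")
ests <- bind_rows(lapply(names(tabs), function(nm) {
  est <- preference_estimate(tabs[[nm]])
  tibble::tibble(table = nm, o_fm = est$o_fm,
                 e_fm = round(est$e_fm, 2),
                 theta_hat = round(est$theta_hat, 3))
}))
print(as.data.frame(ests), row.names = FALSE)
readr::write_tsv(ests, "results/preference_estimates.tsv")

cat("\nPower of the test across theta at the rising-tide geometry:\n")
pc <- power_curve(m = 132, n = 120, theta = c(0, 0.1, 0.2, 0.39, 0.6, 1),
                  replicates = 400, seed = seed)
print(as.data.frame(pc), row.names = FALSE)
readr::write_tsv(pc, "results/power_curve.tsv")

cat("\nParameter recovery (400 replicates per theta):\n")
exp_obj <- expected_random_pairing(sexed_pool(132, 120))
recovery <- bind_rows(lapply(c(0.2, 0.4, 0.6, 0.8), function(theta) {
  est <- vapply(seq_len(400), function(r) {
    tab <- simulate_pairs(pairing_scenario(
      132, 120, theta = theta, seed = seed + round(1e4 * theta) + r))
    preference_estimate(tab, expected = exp_obj)$theta_hat
  }, numeric(1))
  tibble::tibble(theta = theta, mean_theta_hat = round(mean(est), 4),
                 sd = round(sd(est), 4))
}))
print(as.data.frame(recovery), row.names = FALSE)
readr::write_tsv(recovery, "results/recovery.tsv")

cat("\nReading: at the observed geometry the test has essentially full power\n",
    "for the plug-in theta_hat of ~0.39, and the estimator is unbiased to\n",
    "well within its Monte-Carlo error across the theta grid.\n", sep = "")
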