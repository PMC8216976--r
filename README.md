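# tidepair

Random-pairing null models, activity budgets and thermal summaries for the
behavioral ecology of high-shore littorinid snails.

Tropical high-shore periwinkles (*Echinolittorina malaccana*,
*E. radiata*) can only move, feed and mate during the short window when the
tide washes their zone; the rest of the cycle is spent mitigating rock
temperatures that approach their lethal limits. Two behaviors in this
system are candidates for *multifunctionality*: following another snail's
mucus trail, and standing two-deep in "towers". If males use them to find
females, the sexes of observed pairs should depart from random pairing in a
specific direction — males tracking (or on top of) females.

`tidepair` implements the statistics to test that, and the surrounding
pipeline:

* **Random-pairing null model** — closed-form expected counts of the four
  ordered sex combinations (`FM`, `MM`, `MF`, `FF`) when `m` males and `n`
  females form `N = (m+n)/2` pairs as a uniform perfect matching with
  fair role assignment:

  `E[FM] = E[MF] = mn / 2(m+n−1)`,
  `E[MM] = m(m−1) / 2(m+n−1)`,
  `E[FF] = n(n−1) / 2(m+n−1)`

  with Pearson χ² goodness-of-fit tests (`chi_squared_gof()`), an
  exact-enumeration oracle for small pools, a Monte-Carlo oracle that also
  provides a calibrated p-value, and a moment estimator of preference
  strength (`preference_estimate()`).
* **Activity budgets** — ethogram-based scoring of quadrat scan surveys
  into four fitness-associated activities (reproduction, foraging, stress
  mitigation, inactive), hourly behavior percentages and seasonal
  allocations (`hourly_budget()`, `seasonal_allocation()`).
* **Thermal summaries** — seasonal ranges, percent of days whose maximum
  exceeds a threshold, and thermal-safety margins against species LT50s
  (`seasonal_range()`, `pct_days_exceeding()`, `safety_margin()`).
* **Seeded generators** for pair tables with known preference strength,
  tidal-cycle scan surveys, and seasonal logger series
  (`simulate_pairs()`, `simulate_scans()`, `simulate_temperatures()`), so
  every stage is testable with known ground truth.

The published observed count tables (trail pairs and towers, two species,
rising and falling tides) ship as plain-text fixtures and load with
`printed_pair_tables()`.

## Worked example

Rising-tide trail-following pairs of *E. malaccana*: 126 pairs, of which 68
were a male tracking a female.

```r
library(tidepair)

obs <- pair_counts(FM = 68, MM = 26, MF = 12, FF = 20,
                   species = "E_malaccana", tide_phase = "rising")
chi_squared_gof(obs)
#> Random-pairing goodness of fit: trail_following, E_malaccana, rising
#>   pool: m = 132, n = 120; N = 126 pairs
#>  combination observed expected
#>           FM       68     31.6
#>           MM       26     34.4
#>           MF       12     31.6
#>           FF       20     28.4
#>   chi-squared = 58.79, df = 3, p < .001 (p = 1.064e-12, analytic)

preference_estimate(obs)
#> theta_hat = 0.386 (O_FM = 68, null E_FM = 31.55, N = 126)
```

Reading: the pairs contained 132 males and 120 females; random pairing
would put ~31.6 of the 126 pairs in the female-marker/male-tracker
combination, but 68 were observed — a departure far beyond chance
(χ² = 58.79, df = 3). The plug-in preference estimate says roughly 39% of
pairs formed as directed male-follows-female events. On falling tides the
same test is non-significant (χ² = 3.75, n.s.): the behavior's function
shifts from mate search to aggregation formation over the tidal cycle.

The numbered scripts under `analysis/` run the full workflow and write
tidy tables to `results/`: `01_pairing_tests.R` (all eight published
tables), `02_power_and_recovery.R` (preference estimates, power curve,
estimator recovery), `03_activity_budget.R` (simulated hot/cool scan
surveys → budgets), `04_thermal_summary.R` (simulated logger series →
ranges, exceedance, safety margins).

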