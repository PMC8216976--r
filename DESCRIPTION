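Package: tidepair
Title: Random-Pairing Null Models and Activity Budgets for High-Shore
    Littorinid Behavior
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Statistical tools for quantitative ethology of high-shore
    littorinid snails. Implements a finite-pool random-pairing null model
    for sexed two-animal associations (mucus-trail-following pairs and
    two-snail towers), with closed-form expected frequencies, Pearson
    chi-squared goodness-of-fit tests, exact-enumeration and Monte-Carlo
    oracles, and a moment estimator of pairing preference. Also provides
    an ethogram-based scan-sampling activity-budget pipeline (hourly
    behavior percentages and seasonal activity allocations) and
    temperature-logger summaries (seasonal ranges, daily-maximum threshold
    exceedance, thermal-safety margins), plus seeded synthetic-data
    generators for pair tables, tidal-cycle scan surveys and seasonal
    temperature series so every stage is testable without field data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
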