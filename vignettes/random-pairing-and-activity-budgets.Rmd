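---
title: "Random-pairing null models and activity budgets for high-shore littorinids"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Random-pairing null models and activity budgets for high-shore littorinids}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tidepair)
```

High-shore littorinid snails (*Echinolittorina malaccana*, *E. radiata*)
live at the hot edge of the intertidal: activity is possible only in the
brief window when the rising or falling tide washes their zone, and the rest
of the time is spent mitigating heat stress. Two behaviors in this system
are *multifunctional* — mucus-trail following and two-snail "towers" can
serve mate search, thermoregulation, or both, depending on tidal state. The
statistical question this package answers is: **are the sexed two-animal
associations we observe random, or dominated by a particular sex
combination?** Around that core it provides the scan-survey activity-budget
pipeline and temperature-logger summaries that put the pairing behavior in
its seasonal thermal context, and seeded generators so the whole pipeline
can be exercised and validated without field data.

## The random-pairing null model

An observed table counts the four ordered sex combinations of `N` pairs,
written `XY` = role-1 individual of sex `X` with role-2 individual of sex
`Y`. Role 1 is the trail *marker* (or the *bottom* snail of a tower), role 2
the *tracker* (or *top* snail), so `FM` is the combination of interest when
males seek females: a male following a female's trail, or a male on top of a
female.

The null model has two ingredients, fixed by design:

1. the `m` males and `n` females observed in the pairs form a **uniformly
   random perfect matching** into `N = (m + n)/2` pairs, and
2. each pair's roles are assigned by a **fair coin** (each individual has a
   50% chance of being marker or tracker).

A focal individual's partner is then a uniform draw from the other
`m + n - 1` individuals, giving closed-form expected counts

$$E[FM] = E[MF] = \tfrac{1}{2}\,\frac{mn}{m+n-1}, \qquad
  E[MM] = \tfrac{1}{2}\,\frac{m(m-1)}{m+n-1}, \qquad
  E[FF] = \tfrac{1}{2}\,\frac{n(n-1)}{m+n-1}.$$

Two algebraic identities make good invariant tests and are asserted across
a randomized pool battery in the test suite: the four expectations sum to
`N` exactly, and the two mixed combinations always have equal expectation.
`m` and `n` are not free inputs: every individual appears in exactly one
pair, so `derive_pool()` recovers them from the counts
(`m = 2 MM + FM + MF`, `n = 2 FF + FM + MF`).

```{r}
obs <- pair_counts(FM = 68, MM = 26, MF = 12, FF = 20,
                   species = "E_malaccana", tide_phase = "rising")
chi_squared_gof(obs)
```

### Two oracles, one closed form

The closed form is cross-checked by two independent routes, both exposed as
user functions because they are useful beyond testing:

* `exact_enumeration()` enumerates *every* perfect matching and every role
  orientation with equal weight (feasible to `m + n = 12`); its expectations
  match the closed form to machine precision.
* `monte_carlo_null()` samples the null directly (one random permutation,
  paired off adjacently, is exactly a uniform matching with fair
  orientation) and returns the empirical count distributions and the null
  distribution of the Pearson statistic.

### Degrees of freedom, and why a Monte-Carlo p-value is offered

The conventional test compares
$\chi^2 = \sum (O - E)^2 / E$ over the four categories to a chi-squared
distribution with `df = 3`, and that analytic test is what
`chi_squared_gof()` reports by default. It is worth knowing that this
reference is *conservative* for this design: because the pool totals `m`
and `n` are fixed by the observed pairs, the counts satisfy a second linear
constraint (`2 MM + FM + MF = m`) beyond `ΣO = N`, leaving roughly two free
dimensions rather than three. Simulation at the rising-tide geometry puts
the analytic type-I error near 0.02 at a nominal 0.05. Conservatism only
strengthens the published rejections, but for calibrated inference —
and whenever any expected count falls below 5, where the result carries a
warning — `method = "monte_carlo"` computes the p-value against the exact
matching null instead; its measured type-I error sits inside the binomial
envelope of the nominal level (asserted in the test suite at 2,000 null
tables against a 4,000-draw shared null).

Other reporting conventions mirror the field's tables: full precision is
kept internally, printing rounds expectations to 1 decimal and the
statistic to 2; p-values are annotated `p < .001`, `p < .05` or `n.s.`
with the raw value retained. Categories with zero expectation (single-sex
pools) are dropped with `df` reduced; if only one category remains the test
is degenerate and `p = 1` with a warning. One published table (the
*E. radiata* falling-tide trail pairs) omits its `FF` row; `read_pairs()`
infers the missing count from the declared total of 120 and every
downstream result carries an `inferred` flag rather than silently assuming
it. Chains of three or more trail-followers are represented in these tables
by their two leading animals only, so the pair container needs no special
case for them.

## The preference parameter and its estimator

To ask *how strong* the rising-tide preference is, the generator defines a
one-parameter alternative nesting the null: each of the `N` pairs is,
independently with probability `theta`, a **directed preference event** — a
female takes role 1 and a male role 2 — and otherwise forms by the null
matching. Pairs being exchangeable, `simulate_pairs()` realizes this as a
`Binomial(N, theta)` number of preference pairs removed from the pool first
(truncated at `min(m, n)` with any excess falling back to null pairing and
logged in the ground-truth record), followed by a uniform matching of the
remainder. This formulation keeps the per-pair definition of `theta` exact;
an interleaved draw that consumes females as it goes exhausts one sex near
the end of the sequence at high `theta`, which visibly biases estimation —
the reason the preference events are committed up front.

Since `E[O_FM] = N\theta + (1-\theta)E_{FM}` up to a small pool-depletion
term, the moment estimator is
$\hat\theta = (O_{FM} - E_{FM})/(N - E_{FM})$, clipped to `[0, 1]`.
Simulation at the published rising-tide geometry (`m = 132, n = 120,
N = 126`; 1,000 replicates per `theta`) recovers
`theta ∈ {0.2, 0.4, 0.6, 0.8}` with |bias| under 0.02 — asserted in the
test suite. `power_curve()` maps the rejection rate of the test across
`theta`; at that geometry power is essentially 1 by `theta ≈ 0.4`, the
plug-in estimate for the observed rising-tide table.

## Activity budgets

The scan-survey pipeline converts quadrat records (one row per individual
per scan, with a semicolon-separated behavior set) into budgets using an
ethogram mapping nine behaviors to four fitness-associated activities:
mating and fighting → **reproduction**; moving and turning → **foraging**
(grazing cannot be observed directly, so any movement is ascribed to
foraging); crevice occupation, towering, standing and aggregating →
**stress mitigation**; stationary → **inactive**. Two scoring rules carry
the statistical weight:

* **one count per activity**: an individual showing several behaviors of
  the same category (aggregating *in* a crevice) scores that category once,
  avoiding bias toward activities with many behaviors;
* **multifunctional individuals count in every category they express**, so
  hourly behavior percentages — and category allocations — can legitimately
  sum above 100%.

`hourly_budget()` pools quadrats within each hour (binned half-open on the
hour, local time) and reports the percentage of scanned individuals per
behavior; hours with no individuals are absent, not zero.
`seasonal_allocation()` aggregates category flags per individual-scan over
a season. Its default basis pools individual-scans, which matches the
quadrat-count design and is robust to hours with few snails; an
hour-averaged basis (`basis = "hourly_mean"`) weights hours equally and is
provided because published seasonal summaries do not state which
aggregation they used — with the raw survey sheets unpublished, neither
mode claims to reproduce those numbers, and the two can differ materially
under unequal abundance (both are exercised in the tests).

`simulate_scans()` generates surveys from a pure semidiurnal sinusoid
(period 12.42 h) classified into four phases — awash-rising, awash-falling,
submerged, emersed — by the water level relative to the snail band, with a
phase-conditioned distribution over behavior *sets* (so multifunctional
combinations like `mating;moving` arise with configured probability). The
default hot regime places reproduction and foraging in the awash-rising
phase and shell-posturing in the falling/emersed phases; the cool regime
has no reproduction, no standing or towering, and under 1% foraging,
mirroring the qualitative seasonal contrast in this system. Snails per
quadrat are Poisson (default mean 5 across 10 quadrats per hour, a
realistic density for these scans). The generator emits its exact per-phase
category probabilities as ground truth, and the round-trip test requires
`seasonal_allocation()` to recover them within three standard errors. What
the generator does not emulate — spatial structure, weather, observer
error, between-day variation — bounds what passing tests say about real
surveys: they validate the pipeline's arithmetic and rules, not the
field protocol.

## Thermal summaries

`seasonal_range()`, `pct_days_exceeding()` and `safety_margin()` summarize
hourly logger series. "Days exceeding a threshold" is operationalized as
*daily maximum strictly above* the threshold (the natural reading for rock
temperatures that spike at midday); the boundary convention is configurable
to `>=`, and `basis = "readings"` gives the alternative interpretation
(fraction of individual readings above threshold) since published
percentages do not state which was counted. Loggers within a site replicate
the same zone, so they pool by maximum for exceedance — a day is hot if any
logger exceeded — with a mean-based alternative. Safety margins are
`LT50 - seasonal max` per species (summer LT50s in air: 56.5 °C for
*E. malaccana*, 55.5 °C for *E. radiata*), with percent of hours above the
Arrhenius breakpoint temperature when one is supplied.

`simulate_temperatures()` draws independent daily peaks and troughs and
interpolates a diurnal half-cosine (trough ~02:00, peak ~14:00) plus logger
noise. Two calibrations serve different validation targets:
`target_exceedance` sets the daily-peak mean so the expected fraction of
days above a threshold matches a target (checked to within three binomial
standard errors over a deployment), and `target_range` affinely rescales a
finished series onto a seasonal envelope such as 24.1–55.5 °C (hot) or
4.0–49.1 °C (cool) — an envelope is a property of a season's extremes, so
it is pinned exactly rather than imposed by clipping, which would distort
the daily shape. The defaults (79 hot days, 73 cool days, three loggers)
match the deployment scale this design describes.

## Problem sizes and numerical choices

The test suite and the analysis scripts run at desk scale by design:
exact enumeration to 10 individuals (≤ 30,240 outcomes), Monte-Carlo nulls
of 4,000–10,000 replicates, calibration at 2,000 simulated tables,
recovery at 1,000 replicates per `theta`, surveys of 24–72 hours, and
logger series of 73–79 days — together a couple of minutes on one core.
All generators take explicit integer seeds and are bit-reproducible; no
global RNG state is consumed silently. Ties in the Monte-Carlo p-value are
handled by the add-one estimator `(1 + #{χ²_null ≥ χ²_obs})/(R + 1)`,
counting ties as at least as extreme.

## Limitations

The pairing null conditions on the observed pool composition; it does not
model detection, repeated sampling of the same individuals across tides, or
between-site heterogeneity (sites are pooled, as in the source tables). The
preference model is deliberately the simplest one-parameter alternative —
it cannot distinguish female choice from male search efficiency, only
departure from randomness in the `FM` direction. The tide model is a
sinusoid, not a tide table; the thermal generator reproduces summary
statistics of a season, not serial correlation of weather. Published
seasonal allocation percentages and exceedance values derive from
unpublished raw records and are therefore validated here only through the
generator round-trips and envelope targets, never by numeric equality.
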