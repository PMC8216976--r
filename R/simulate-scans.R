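# Tidal-cycle scan-survey generator: phase-conditioned behavior sets with
# known ground truth for round-trip testing of the activity-budget pipeline.

TIDE_PHASES <- c("awash_rising", "awash_falling", "emersed", "submerged")

default_behavior_probs <- function(regime = c("hot", "cool")) {
  regime <- match.arg(regime)
  if (regime == "hot") {
    list(
      awash_rising = tibble(
        behaviors = c("mating;moving", "mating", "moving", "turning",
                      "aggregating;turning", "stationary"),
        prob = c(0.15, 0.05, 0.35, 0.10, 0.05, 0.30)
      ),
      awash_falling = tibble(
        behaviors = c("moving", "standing", "towering", "aggregating",
                      "in_crevice", "stationary"),
        prob = c(0.25, 0.10, 0.10, 0.15, 0.10, 0.30)
      ),
      emersed = tibble(
        behaviors = c("standing", "towering", "in_crevice", "aggregating",
                      "stationary"),
        prob = c(0.15, 0.10, 0.20, 0.15, 0.40)
      ),
      submerged = tibble(
        behaviors = c("moving", "aggregating", "stationary"),
        prob = c(0.20, 0.10, 0.70)
      )
    )
  } else {
    # cool season: no reproduction, no shell posturing (standing/towering),
    # almost no foraging; snails aggregate in crevices or sit inactive
    quiet <- tibble(
      behaviors = c("in_crevice", "aggregating;in_crevice", "aggregating",
                    "moving", "stationary"),
      prob = c(0.30, 0.25, 0.15, 0.005, 0.295)
    )
    list(awash_rising = quiet, awash_falling = quiet,
         emersed = quiet, submerged = quiet)
  }
}

#' Scenario for a tidal-cycle scan survey
#'
#' The tide is a pure semidiurnal sinusoid; each hour is classified into one
#' of four phases by the water level relative to the snail band: awash (rising
#' or falling, when the level is within `awash_width` of the band height),
#' submerged (level above the band) or emersed (level below). Behavior sets
#' are drawn per individual from a phase-conditioned distribution over sets
#' (sets may span categories, e.g. `"mating;moving"`, generating the
#' multifunctional combinations seen in the field).
#'
#' @param period_h Tidal period in hours (default 12.42, semidiurnal).
#' @param amplitude Tidal amplitude (m).
#' @param mean_level Mean water level (m above datum).
#' @param band_height Height of the snail band (m above datum).
#' @param awash_width Half-width of the awash zone (m).
#' @param regime `"hot"` or `"cool"` season defaults for the behavior table.
#' @param behavior_probs Optional named list (one element per phase:
#'   `awash_rising`, `awash_falling`, `emersed`, `submerged`) of tibbles with
#'   columns `behaviors` (semicolon-joined set) and `prob` (summing to 1).
#' @return A list of class `tide_scenario`.
#' @export
tide_scenario <- function(period_h = 12.42, amplitude = 1.0, mean_level = 2.0,
                          band_height = 2.2, awash_width = 0.35,
                          regime = c("hot", "cool"), behavior_probs = NULL) {
  regime <- match.arg(regime)
  if (is.null(behavior_probs)) behavior_probs <- default_behavior_probs(regime)
  missing_phases <- setdiff(TIDE_PHASES, names(behavior_probs))
  if (length(missing_phases)) {
    stop("behavior_probs lacks phase(s): ",
         paste(missing_phases, collapse = ", "), call. = FALSE)
  }
  for (ph in TIDE_PHASES) {
    tab <- behavior_probs[[ph]]
    if (!all(c("behaviors", "prob") %in% names(tab))) {
      stop("behavior_probs$", ph, " needs columns `behaviors` and `prob`",
           call. = FALSE)
    }
    if (abs(sum(tab$prob) - 1) > 1e-8) {
      stop("behavior-set probabilities for phase ", ph, " must sum to 1",
           call. = FALSE)
    }
  }
  structure(list(period_h = period_h, amplitude = amplitude,
                 mean_level = mean_level, band_height = band_height,
                 awash_width = awash_width, regime = regime,
                 behavior_probs = behavior_probs),
            class = "tide_scenario")
}

#' Tide phase experienced by the snail band at given hours
#'
#' @param scenario A [tide_scenario()].
#' @param hours Numeric vector of hours since the start of the survey.
#' @return Character vector of phases.
#' @export
tide_phase_at <- function(scenario, hours) {
  stopifnot(inherits(scenario, "tide_scenario"))
  w <- 2 * pi / scenario$period_h
  level <- scenario$mean_level + scenario$amplitude * sin(w * hours)
  rising <- cos(w * hours) > 0
  delta <- level - scenario$band_height
  ifelse(abs(delta) <= scenario$awash_width,
         ifelse(rising, "awash_rising", "awash_falling"),
         ifelse(delta > 0, "submerged", "emersed"))
}

# P(category flagged) per phase, from the configured set distribution.
phase_category_probs <- function(scenario, ethogram = default_ethogram()) {
  rows <- lapply(TIDE_PHASES, function(ph) {
    tab <- scenario$behavior_probs[[ph]]
    flag_mat <- t(vapply(split_behavior_sets(tab$behaviors),
                         function(s) score_individual(s, ethogram),
                         integer(length(ACTIVITY_CATEGORIES))))
    tibble(phase = ph,
           category = ACTIVITY_CATEGORIES,
           prob = as.numeric(tab$prob %*% flag_mat))
  })
  dplyr::bind_rows(rows)
}

#' Simulate a tidal-cycle scan survey with known ground truth
#'
#' Each survey hour, `n_quadrats` quadrats are scanned; the number of snails
#' per quadrat is Poisson with mean `snails_per_quadrat`. Every snail's
#' behavior set is an independent draw from the phase-conditioned set
#' distribution of the scenario. The true per-phase category probabilities
#' and the phase schedule are attached as the `truth` attribute, so
#' [seasonal_allocation()] and [hourly_budget()] output can be checked
#' against construction.
#'
#' @param scenario A [tide_scenario()].
#' @param hours Number of survey hours (default 24).
#' @param n_quadrats Quadrats per hour (default 10).
#' @param snails_per_quadrat Mean snails per quadrat (default 5).
#' @param species Species label written into the records.
#' @param season Season label written into the records (defaults to the
#'   scenario regime).
#' @param start Survey start time.
#' @param seed Integer seed; required.
#' @return A tibble of scan records (`timestamp`, `quadrat`, `species`,
#'   `individual`, `behaviors`, `season`) with attribute `truth`: list with
#'   `phase_schedule` (tibble hour/phase), `category_probs` (per-phase
#'   category flag probabilities), `expected_allocation` (tibble category/pct,
#'   weighted by realized snails per phase) and the scenario itself.
#' @export
simulate_scans <- function(scenario, hours = 24L, n_quadrats = 10L,
                           snails_per_quadrat = 5, species = "E_malaccana",
                           season = NULL,
                           start = as.POSIXct("2015-08-01 00:00:00",
                                              tz = "UTC"),
                           seed) {
  stopifnot(inherits(scenario, "tide_scenario"))
  if (missing(seed) || is.null(seed)) {
    stop("`seed` is required for simulate_scans()", call. = FALSE)
  }
  if (is.null(season)) season <- scenario$regime
  set.seed(as.integer(seed))

  hour_seq <- seq_len(hours) - 1L
  phases <- tide_phase_at(scenario, hour_seq + 0.5)

  rows <- vector("list", hours)
  for (h in seq_len(hours)) {
    tab <- scenario$behavior_probs[[phases[h]]]
    n_per_quadrat <- stats::rpois(n_quadrats, snails_per_quadrat)
    n_total <- sum(n_per_quadrat)
    if (n_total == 0) next
    sets <- sample(tab$behaviors, n_total, replace = TRUE, prob = tab$prob)
    rows[[h]] <- tibble(
      timestamp = start + 3600 * hour_seq[h],
      quadrat = rep(seq_len(n_quadrats), n_per_quadrat),
      species = species,
      individual = sequence(n_per_quadrat),
      behaviors = sets,
      season = season,
      phase = phases[h]
    )
  }
  records <- dplyr::bind_rows(rows)

  cat_probs <- phase_category_probs(scenario)
  phase_n <- dplyr::summarise(dplyr::group_by(records, .data$phase),
                              n = dplyr::n(), .groups = "drop")
  expected_allocation <- dplyr::summarise(
    dplyr::group_by(
      dplyr::left_join(cat_probs, phase_n, by = "phase"),
      .data$category
    ),
    pct = 100 * sum(.data$prob * ifelse(is.na(.data$n), 0, .data$n)) /
      sum(phase_n$n),
    .groups = "drop"
  )

  attr(records, "truth") <- list(
    scenario = scenario,
    seed = as.integer(seed),
    phase_schedule = tibble(hour = hour_seq, phase = phases),
    category_probs = cat_probs,
    expected_allocation = expected_allocation
  )
  records
}
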