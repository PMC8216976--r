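# Seasonal temperature-logger generator: daily sinusoid with day-to-day
# variation in peak and trough, calibratable to a target exceedance fraction
# or pinned to a target seasonal envelope.

#' Scenario for a seasonal hourly temperature series
#'
#' Each day draws an independent peak and trough temperature; the hourly
#' trajectory interpolates between them with a diurnal half-cosine (trough
#' near 02:00, peak near 14:00) plus per-logger Gaussian noise. Two optional
#' calibrations: `target_exceedance` sets the daily-peak mean so that the
#' expected fraction of days whose peak exceeds `exceed_threshold` equals the
#' target; `target_range` affinely rescales the finished series so its global
#' minimum and maximum hit the envelope exactly (a target for the season's
#' extremes, not a clip).
#'
#' @param season Season label (e.g. `"hot"`, `"cool"`).
#' @param days Number of days (hot-season deployments here run 79 days, cool
#'   73).
#' @param peak_mean,peak_sd Mean and sd of the daily maximum (degrees C).
#' @param trough_mean,trough_sd Mean and sd of the daily minimum.
#' @param noise_sd Per-reading logger noise sd (degrees C).
#' @param n_loggers Loggers per site (default 3).
#' @param site Site identifier.
#' @param exceed_threshold,target_exceedance Optional calibration: fraction of
#'   daily peaks expected above the threshold.
#' @param target_range Optional length-2 numeric `c(min, max)` envelope the
#'   finished series is rescaled onto.
#' @param start First day of the deployment.
#' @return A list of class `thermal_scenario`.
#' @export
thermal_scenario <- function(season = c("hot", "cool"), days = 79L,
                             peak_mean = NULL, peak_sd = 4, trough_mean = NULL,
                             trough_sd = 1.5, noise_sd = 0.3, n_loggers = 3L,
                             site = 1L,
                             exceed_threshold = NULL, target_exceedance = NULL,
                             target_range = NULL,
                             start = NULL) {
  season <- match.arg(season)
  if (is.null(peak_mean)) peak_mean <- if (season == "hot") 43 else 27
  if (is.null(trough_mean)) trough_mean <- if (season == "hot") 27.5 else 13
  if (is.null(start)) {
    start <- as.Date(if (season == "hot") "2015-06-01" else "2016-01-01")
  }
  if (!is.null(target_exceedance)) {
    if (is.null(exceed_threshold)) {
      stop("target_exceedance needs exceed_threshold", call. = FALSE)
    }
    if (target_exceedance <= 0 || target_exceedance >= 1) {
      stop("target_exceedance must lie strictly in (0, 1)", call. = FALSE)
    }
    # P(peak > threshold) = target  =>  mean = threshold - sd * qnorm(1 - target)
    peak_mean <- exceed_threshold -
      peak_sd * stats::qnorm(1 - target_exceedance)
  }
  if (!is.null(target_range)) {
    stopifnot(length(target_range) == 2, target_range[1] < target_range[2])
  }
  structure(list(season = season, days = as.integer(days),
                 peak_mean = peak_mean, peak_sd = peak_sd,
                 trough_mean = trough_mean, trough_sd = trough_sd,
                 noise_sd = noise_sd, n_loggers = as.integer(n_loggers),
                 site = site, exceed_threshold = exceed_threshold,
                 target_exceedance = target_exceedance,
                 target_range = target_range, start = as.Date(start)),
            class = "thermal_scenario")
}

#' Simulate an hourly temperature-logger series
#'
#' @param scenario A [thermal_scenario()].
#' @param seed Integer seed; required.
#' @return A tibble with columns `timestamp` (hourly), `logger`, `site`,
#'   `temp_c`, `season`, suitable for [seasonal_range()],
#'   [pct_days_exceeding()] and [safety_margin()]. The scenario is attached
#'   as attribute `truth`.
#' @examples
#' sc <- thermal_scenario("hot", days = 10, noise_sd = 0)
#' temps <- simulate_temperatures(sc, seed = 1)
#' seasonal_range(temps)
#' @export
simulate_temperatures <- function(scenario, seed) {
  stopifnot(inherits(scenario, "thermal_scenario"))
  if (missing(seed) || is.null(seed)) {
    stop("`seed` is required for simulate_temperatures()", call. = FALSE)
  }
  set.seed(as.integer(seed))

  days <- scenario$days
  peaks <- stats::rnorm(days, scenario$peak_mean, scenario$peak_sd)
  troughs <- stats::rnorm(days, scenario$trough_mean, scenario$trough_sd)
  # keep each day's trough at or below its peak (equal gives a flat day)
  troughs <- pmin(troughs, peaks)

  hours <- 0:23
  # diurnal shape in [0, 1]: trough at 02:00, peak at 14:00
  shape <- (1 + cos(2 * pi * (hours - 14) / 24)) / 2
  base <- rep(troughs, each = 24) +
    rep(peaks - troughs, each = 24) * rep(shape, days)

  stamps <- as.POSIXct(scenario$start, tz = "UTC") +
    3600 * (seq_len(days * 24L) - 1L)

  out <- dplyr::bind_rows(lapply(seq_len(scenario$n_loggers), function(lg) {
    tibble(timestamp = stamps,
           logger = lg,
           site = scenario$site,
           temp_c = base + stats::rnorm(length(base), 0, scenario$noise_sd),
           season = scenario$season)
  }))

  if (!is.null(scenario$target_range)) {
    lo <- min(out$temp_c)
    hi <- max(out$temp_c)
    tr <- scenario$target_range
    out$temp_c <- tr[1] + (out$temp_c - lo) * (tr[2] - tr[1]) / (hi - lo)
  }

  attr(out, "truth") <- list(scenario = scenario, seed = as.integer(seed))
  out
}
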