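# Temperature-logger summaries: seasonal extrema, daily threshold exceedance
# and thermal-safety margins against species tolerance constants.

validate_temps <- function(temps) {
  required <- c("timestamp", "logger", "site", "temp_c")
  missing_cols <- setdiff(required, names(temps))
  if (length(missing_cols)) {
    stop("temperature series lacks column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  temps <- as_tibble(temps)
  temps$timestamp <- as.POSIXct(temps$timestamp)
  if (!"season" %in% names(temps)) temps$season <- "all"
  bad <- dplyr::summarise(
    dplyr::group_by(temps, .data$site, .data$logger),
    unsorted = is.unsorted(.data$timestamp, strictly = TRUE),
    .groups = "drop"
  )
  if (any(bad$unsorted)) {
    stop("timestamps must be strictly increasing within logger(s): ",
         paste(sprintf("site %s logger %s", bad$site[bad$unsorted],
                       bad$logger[bad$unsorted]), collapse = ", "),
         call. = FALSE)
  }
  temps
}

#' Seasonal temperature range over all loggers and sites
#'
#' @param temps A data frame with columns `timestamp`, `logger`, `site`,
#'   `temp_c`, and optionally `season`.
#' @param season Optional single season label to restrict to.
#' @return A tibble with `season`, `min_c`, `max_c`, `n_readings`.
#' @export
seasonal_range <- function(temps, season = NULL) {
  temps <- validate_temps(temps)
  if (!is.null(season)) {
    temps <- temps[temps$season %in% season, , drop = FALSE]
    if (nrow(temps) == 0) {
      stop("no readings in season: ", paste(season, collapse = ", "),
           call. = FALSE)
    }
  }
  dplyr::summarise(
    dplyr::group_by(temps, .data$season),
    min_c = min(.data$temp_c),
    max_c = max(.data$temp_c),
    n_readings = dplyr::n(),
    .groups = "drop"
  )
}

#' Percentage of days whose temperature exceeds a threshold, per site
#'
#' A day (local calendar date) counts as exceeding when its daily maximum is
#' strictly above the threshold. Loggers within a site are pooled by maximum
#' by default (a day is hot if any logger exceeded); `pool = "mean"` first
#' averages loggers at each timestamp. `basis = "readings"` instead reports
#' the percentage of individual readings above the threshold, an alternative
#' operationalization of "day temperatures exceeding" the threshold.
#'
#' @param temps Temperature series as in [seasonal_range()].
#' @param threshold Threshold in degrees C.
#' @param strict If `TRUE` (default) use `>`; if `FALSE`, `>=`.
#' @param pool `"max"` (default) or `"mean"` across loggers.
#' @param basis `"daily_max"` (default) or `"readings"`.
#' @return A tibble with `season`, `site`, `n_days` (or `n_readings`),
#'   `n_exceed`, `pct`.
#' @export
pct_days_exceeding <- function(temps, threshold, strict = TRUE,
                               pool = c("max", "mean"),
                               basis = c("daily_max", "readings")) {
  temps <- validate_temps(temps)
  pool <- match.arg(pool)
  basis <- match.arg(basis)
  exceeds <- if (strict) {
    function(x) x > threshold
  } else {
    function(x) x >= threshold
  }

  if (basis == "readings") {
    at_time <- dplyr::summarise(
      dplyr::group_by(temps, .data$season, .data$site, .data$timestamp),
      temp_c = if (pool == "max") max(.data$temp_c) else mean(.data$temp_c),
      .groups = "drop"
    )
    out <- dplyr::summarise(
      dplyr::group_by(at_time, .data$season, .data$site),
      n_readings = dplyr::n(),
      n_exceed = sum(exceeds(.data$temp_c)),
      .groups = "drop"
    )
    out$pct <- 100 * out$n_exceed / out$n_readings
    return(out)
  }

  temps$day <- as.Date(temps$timestamp)
  at_time <- dplyr::summarise(
    dplyr::group_by(temps, .data$season, .data$site, .data$day,
                    .data$timestamp),
    temp_c = if (pool == "max") max(.data$temp_c) else mean(.data$temp_c),
    .groups = "drop"
  )
  daily <- dplyr::summarise(
    dplyr::group_by(at_time, .data$season, .data$site, .data$day),
    day_max = max(.data$temp_c),
    .groups = "drop"
  )
  out <- dplyr::summarise(
    dplyr::group_by(daily, .data$season, .data$site),
    n_days = dplyr::n(),
    n_exceed = sum(exceeds(.data$day_max)),
    .groups = "drop"
  )
  if (any(out$n_days == 0)) stop("no complete days with data", call. = FALSE)
  out$pct <- 100 * out$n_exceed / out$n_days
  out
}

#' Thermal-safety margins against species tolerance constants
#'
#' Per season, the margin between a species' lethal temperature (`LT50`, the
#' temperature lethal to 50% of individuals in air) and the seasonal maximum
#' the loggers recorded. When an Arrhenius breakpoint temperature (`ABT`, the
#' sublethal heart-rate threshold) is supplied, the percentage of hourly
#' readings above it is also reported.
#'
#' @param temps Temperature series as in [seasonal_range()].
#' @param lt50 Named numeric vector of LT50 values per species (degrees C), or
#'   a single unnamed value.
#' @param abt Optional ABT in degrees C.
#' @return A tibble with `species`, `season`, `seasonal_max`, `lt50`,
#'   `margin_c`, and when `abt` is given `pct_hours_above_abt`.
#' @examples
#' # margin for a season whose maximum was 55.5 C against LT50 = 56.0 C
#' temps <- data.frame(timestamp = as.POSIXct("2015-07-01 14:00:00"),
#'                     logger = 1, site = 1, temp_c = 55.5, season = "hot")
#' safety_margin(temps, lt50 = c(E_malaccana = 56.0))
#' @export
safety_margin <- function(temps, lt50, abt = NULL) {
  temps <- validate_temps(temps)
  if (is.null(names(lt50))) names(lt50) <- rep("all", length(lt50))
  if (any(lt50 <= 0)) stop("LT50 values must be positive", call. = FALSE)

  per_season <- dplyr::summarise(
    dplyr::group_by(temps, .data$season),
    seasonal_max = max(.data$temp_c),
    n_readings = dplyr::n(),
    n_above_abt = if (is.null(abt)) NA_integer_ else
      sum(.data$temp_c > abt),
    .groups = "drop"
  )
  out <- tidyr::expand_grid(species = names(lt50), per_season)
  out$lt50 <- unname(lt50[out$species])
  out$margin_c <- out$lt50 - out$seasonal_max
  if (!is.null(abt)) {
    out$abt <- abt
    out$pct_hours_above_abt <- 100 * out$n_above_abt / out$n_readings
  }
  dplyr::select(out, -"n_above_abt")
}
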