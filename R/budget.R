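# Scan-survey activity budgets: hourly behavior percentages and seasonal
# allocation of individual-scans to fitness-associated activity categories.

split_behavior_sets <- function(x) {
  strsplit(as.character(x), "[;,]\\s*")
}

# One row per (individual-scan, behavior), with the scan's hour bin and an
# internal scan id. Validates behavior names against the ethogram.
scan_long <- function(records, ethogram) {
  ethogram <- as_ethogram(ethogram)
  required <- c("timestamp", "species", "behaviors")
  missing_cols <- setdiff(required, names(records))
  if (length(missing_cols)) {
    stop("scan records lack column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  records <- as_tibble(records)
  records$scan_id <- seq_len(nrow(records))
  # hours are binned on the hour, local time, half-open [h, h+1)
  records$hour <- as.POSIXct(trunc(as.POSIXct(records$timestamp), "hours"))

  sets <- split_behavior_sets(records$behaviors)
  empty <- lengths(sets) == 0 | vapply(sets, function(s) all(!nzchar(s)),
                                       logical(1))
  if (any(empty)) {
    stop("empty behavior set in record row(s): ",
         paste(utils::head(which(empty), 5), collapse = ", "), call. = FALSE)
  }
  long <- tibble(
    scan_id = rep(records$scan_id, lengths(sets)),
    behavior = unlist(sets)
  )
  unknown <- setdiff(unique(long$behavior), ethogram$behavior)
  if (length(unknown)) {
    bad_rows <- unique(long$scan_id[long$behavior %in% unknown])
    stop("unknown behavior name(s) ", paste(unknown, collapse = ", "),
         " in record row(s): ",
         paste(utils::head(bad_rows, 5), collapse = ", "), call. = FALSE)
  }
  long$category <- ethogram$category[match(long$behavior, ethogram$behavior)]
  long <- dplyr::distinct(long, .data$scan_id, .data$behavior,
                          .keep_all = TRUE)
  list(records = records, long = long)
}

#' Hourly behavior-level activity budget from scan records
#'
#' Pools all quadrats within each hour and reports, per species, hour and
#' behavior, the percentage of scanned individuals exhibiting that behavior.
#' Because individuals may show several behaviors at once, the per-hour
#' percentages can sum above 100. Hours in which no individuals were scanned
#' simply do not appear (missing, not 0).
#'
#' @param records A data frame of individual-scans with columns `timestamp`,
#'   `species`, `behaviors` (behavior names separated by `;`), and optionally
#'   `quadrat`, `individual`, `season`.
#' @param ethogram Ethogram table (default [default_ethogram()]).
#' @return A tibble with columns `species`, `hour`, `behavior`, `n_scanned`,
#'   `n_individuals`, `pct`.
#' @export
hourly_budget <- function(records, ethogram = default_ethogram()) {
  parts <- scan_long(records, ethogram)
  recs <- parts$records
  long <- dplyr::left_join(
    parts$long,
    dplyr::select(recs, "scan_id", "species", "hour"),
    by = "scan_id"
  )
  denom <- dplyr::summarise(
    dplyr::group_by(recs, .data$species, .data$hour),
    n_scanned = dplyr::n(), .groups = "drop"
  )
  num <- dplyr::summarise(
    dplyr::group_by(long, .data$species, .data$hour, .data$behavior),
    n_individuals = dplyr::n_distinct(.data$scan_id), .groups = "drop"
  )
  out <- dplyr::left_join(num, denom, by = c("species", "hour"))
  out$pct <- 100 * out$n_individuals / out$n_scanned
  dplyr::arrange(
    dplyr::select(out, "species", "hour", "behavior", "n_scanned",
                  "n_individuals", "pct"),
    .data$species, .data$hour, .data$behavior
  )
}

#' Seasonal allocation of activity to fitness-associated categories
#'
#' Aggregates individual-scans over a whole season and reports, per species
#' and category (reproduction, foraging, stress mitigation, inactive), the
#' percentage of individual-scans flagging that category. Each category is
#' counted at most once per individual-scan, so allocations sum to exactly
#' 100% when no individual is multifunctional and to more than 100% when
#' individuals show behaviors from several categories simultaneously.
#'
#' @param records Scan records as in [hourly_budget()], with a `season`
#'   column (or pass `season_map`, a named vector mapping dates
#'   `"YYYY-MM-DD"` to season labels).
#' @param ethogram Ethogram table (default [default_ethogram()]).
#' @param basis `"pooled"` (default): percentages over all individual-scans in
#'   the season, robust to unequal per-hour abundance. `"hourly_mean"`: the
#'   mean of per-hour category percentages, weighting hours equally.
#' @param season_map Optional named character vector, `date -> season`.
#' @return A tibble with columns `species`, `season`, `category`, `pct`, and
#'   `n_scans` (pooled basis) or `n_hours` (hourly-mean basis).
#' @export
seasonal_allocation <- function(records, ethogram = default_ethogram(),
                                basis = c("pooled", "hourly_mean"),
                                season_map = NULL) {
  basis <- match.arg(basis)
  parts <- scan_long(records, ethogram)
  recs <- parts$records
  if (!"season" %in% names(recs)) {
    if (is.null(season_map)) {
      stop("records need a `season` column or a `season_map`", call. = FALSE)
    }
    key <- format(as.Date(recs$hour), "%Y-%m-%d")
    unknown <- setdiff(unique(key), names(season_map))
    if (length(unknown)) {
      stop("season_map lacks date(s): ", paste(unknown, collapse = ", "),
           call. = FALSE)
    }
    recs$season <- unname(season_map[key])
  }

  flags <- dplyr::distinct(parts$long, .data$scan_id, .data$category)
  flags <- dplyr::left_join(
    flags, dplyr::select(recs, "scan_id", "species", "season", "hour"),
    by = "scan_id"
  )
  grid <- tidyr::expand_grid(
    dplyr::distinct(recs, .data$species, .data$season),
    category = ACTIVITY_CATEGORIES
  )

  if (basis == "pooled") {
    denom <- dplyr::summarise(
      dplyr::group_by(recs, .data$species, .data$season),
      n_scans = dplyr::n(), .groups = "drop"
    )
    num <- dplyr::summarise(
      dplyr::group_by(flags, .data$species, .data$season, .data$category),
      n_flagged = dplyr::n(), .groups = "drop"
    )
    out <- dplyr::left_join(grid, num,
                            by = c("species", "season", "category"))
    out$n_flagged[is.na(out$n_flagged)] <- 0L
    out <- dplyr::left_join(out, denom, by = c("species", "season"))
    out$pct <- 100 * out$n_flagged / out$n_scans
    out <- dplyr::select(out, "species", "season", "category", "pct",
                         "n_scans")
  } else {
    denom <- dplyr::summarise(
      dplyr::group_by(recs, .data$species, .data$season, .data$hour),
      n_scans = dplyr::n(), .groups = "drop"
    )
    num <- dplyr::summarise(
      dplyr::group_by(flags, .data$species, .data$season, .data$hour,
                      .data$category),
      n_flagged = dplyr::n(), .groups = "drop"
    )
    hour_grid <- tidyr::expand_grid(
      dplyr::distinct(recs, .data$species, .data$season, .data$hour),
      category = ACTIVITY_CATEGORIES
    )
    hourly <- dplyr::left_join(
      hour_grid, num, by = c("species", "season", "hour", "category"))
    hourly$n_flagged[is.na(hourly$n_flagged)] <- 0L
    hourly <- dplyr::left_join(hourly, denom,
                               by = c("species", "season", "hour"))
    hourly$pct <- 100 * hourly$n_flagged / hourly$n_scans
    out <- dplyr::summarise(
      dplyr::group_by(hourly, .data$species, .data$season, .data$category),
      pct = mean(.data$pct), n_hours = dplyr::n(), .groups = "drop"
    )
  }
  out$category <- factor(out$category, levels = ACTIVITY_CATEGORIES)
  dplyr::arrange(out, .data$species, .data$season, .data$category)
}
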