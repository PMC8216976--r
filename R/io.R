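# Delimited-text readers and report writers for the pipeline. All readers
# require a header row and report validation failures with row locations.

read_delim_checked <- function(path, required, optional = character()) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  dat <- tryCatch(
    readr::read_delim(path, show_col_types = FALSE, progress = FALSE,
                      trim_ws = TRUE),
    error = function(e) stop("could not parse ", path, ": ",
                             conditionMessage(e), call. = FALSE)
  )
  if (nrow(dat) == 0 && ncol(dat) == 0) {
    stop(path, ": empty file; expected header with columns ",
         paste(required, collapse = ", "), call. = FALSE)
  }
  missing_cols <- setdiff(required, names(dat))
  if (length(missing_cols)) {
    stop(path, ": missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  dat
}

#' Read observed pair tables from delimited text
#'
#' Accepts either form:
#' * aggregated (canonical for fixtures): columns `combination`
#'   (FM/MM/MF/FF), `count`, plus optional `association_type`, `species`,
#'   `tide_phase`, `declared_N`. Within a context, a single missing `count`
#'   is inferred as `declared_N` minus the others and flagged as inferred.
#' * long: one row per pair with columns `role1_sex`, `role2_sex` (values
#'   `M`/`F`), plus the same optional context columns.
#'
#' @param path Path to a comma- or tab-delimited file with a header row.
#' @return A named list of [pair_counts()] objects, one per distinct
#'   (association_type, species, tide_phase) context.
#' @examples
#' path <- system.file("extdata", "trail_pairs_observed.csv",
#'                     package = "tidepair")
#' read_pairs(path)[["trail_following.E_malaccana.rising"]]
#' @export
read_pairs <- function(path) {
  dat <- read_delim_checked(path, required = character())
  context_cols <- intersect(c("association_type", "species", "tide_phase"),
                            names(dat))

  if ("combination" %in% names(dat)) {
    if (!"count" %in% names(dat)) {
      stop(path, ": aggregated form needs a `count` column", call. = FALSE)
    }
    bad <- which(!dat$combination %in% PAIR_COMBOS)
    if (length(bad)) {
      stop(path, ": unknown combination key(s) at data row(s): ",
           paste(utils::head(bad, 5), collapse = ", "), call. = FALSE)
    }
  } else if (all(c("role1_sex", "role2_sex") %in% names(dat))) {
    bad <- which(!(dat$role1_sex %in% c("M", "F") &
                     dat$role2_sex %in% c("M", "F")))
    if (length(bad)) {
      stop(path, ": sex values must be M or F; bad data row(s): ",
           paste(utils::head(bad, 5), collapse = ", "), call. = FALSE)
    }
    dat$combination <- paste0(dat$role1_sex, dat$role2_sex)
    dat <- dplyr::summarise(
      dplyr::group_by(dat, dplyr::across(dplyr::all_of(
        c(context_cols, "combination")))),
      count = dplyr::n(), .groups = "drop"
    )
  } else {
    stop(path, ": need either `combination` + `count` columns (aggregated) ",
         "or `role1_sex` + `role2_sex` columns (one row per pair)",
         call. = FALSE)
  }

  if (length(context_cols)) {
    key <- do.call(paste, c(dat[context_cols], sep = "."))
  } else {
    key <- rep("all", nrow(dat))
  }
  groups <- split(dat, key)

  out <- lapply(groups, function(g) {
    counts <- stats::setNames(rep(NA_real_, 4), PAIR_COMBOS)
    counts[g$combination] <- g$count
    absent <- setdiff(PAIR_COMBOS, g$combination)
    counts[absent] <- 0
    declared_here <- if ("declared_N" %in% names(g) &&
                         !all(is.na(g$declared_N))) {
      unique(stats::na.omit(g$declared_N))
    } else NULL
    # a combination row left out of the file entirely is inferable too, when
    # the declared total says the explicit rows cannot be the whole table
    if (!anyNA(counts) && length(absent) == 1 && !is.null(declared_here) &&
        sum(counts) != declared_here) {
      counts[absent] <- NA_real_
    }
    inferred <- character()
    if (anyNA(counts)) {
      if (!"declared_N" %in% names(g) || all(is.na(g$declared_N))) {
        stop("missing counts with no declared_N to infer from (context ",
             paste(g[1, context_cols], collapse = "/"), ")", call. = FALSE)
      }
      declared <- unique(stats::na.omit(g$declared_N))
      if (sum(is.na(counts)) > 1) {
        stop("cannot infer more than one missing count per table",
             call. = FALSE)
      }
      inferred <- names(counts)[is.na(counts)]
      counts[inferred] <- declared - sum(counts, na.rm = TRUE)
      if (counts[inferred] < 0) {
        stop("declared_N smaller than the sum of observed counts",
             call. = FALSE)
      }
    }
    if ("declared_N" %in% names(g) && !all(is.na(g$declared_N))) {
      declared <- unique(stats::na.omit(g$declared_N))
      if (sum(counts) != declared) {
        stop("counts sum to ", sum(counts), " but declared_N = ", declared,
             " (context ", paste(g[1, context_cols], collapse = "/"), ")",
             call. = FALSE)
      }
    }
    pair_counts(
      FM = counts[["FM"]], MM = counts[["MM"]],
      MF = counts[["MF"]], FF = counts[["FF"]],
      association_type = if ("association_type" %in% names(g))
        g$association_type[1] else "trail_following",
      species = if ("species" %in% names(g)) g$species[1] else NA_character_,
      tide_phase = if ("tide_phase" %in% names(g)) g$tide_phase[1] else
        NA_character_,
      inferred = inferred
    )
  })
  out
}

#' Read scan-survey records from delimited text
#'
#' One row per individual-scan; required columns `timestamp`, `quadrat`,
#' `species`, `individual`, `behaviors` (behavior names separated by `;`),
#' optional `season`.
#'
#' @param path Path to a delimited file with a header row.
#' @return A tibble of scan records for [hourly_budget()] /
#'   [seasonal_allocation()].
#' @export
read_scans <- function(path) {
  dat <- read_delim_checked(
    path, required = c("timestamp", "quadrat", "species", "individual",
                       "behaviors"))
  dat$timestamp <- as.POSIXct(dat$timestamp, tz = "UTC")
  bad <- which(is.na(dat$timestamp))
  if (length(bad)) {
    stop(path, ": unparseable timestamp at data row(s): ",
         paste(utils::head(bad, 5), collapse = ", "), call. = FALSE)
  }
  as_tibble(dat)
}

#' Read a temperature-logger series from delimited text
#'
#' Required columns `timestamp` (ISO 8601), `logger`, `site`, `temp_c`;
#' optional `season`. Gaps in the hourly cadence are permitted and flagged
#' via a warning.
#'
#' @param path Path to a delimited file with a header row.
#' @return A tibble for [seasonal_range()] and friends.
#' @export
read_temps <- function(path) {
  dat <- read_delim_checked(
    path, required = c("timestamp", "logger", "site", "temp_c"))
  dat$timestamp <- as.POSIXct(dat$timestamp, tz = "UTC")
  bad <- which(is.na(dat$timestamp) | is.na(dat$temp_c))
  if (length(bad)) {
    stop(path, ": unparseable timestamp or temp_c at data row(s): ",
         paste(utils::head(bad, 5), collapse = ", "), call. = FALSE)
  }
  dat <- validate_temps(dat)
  gaps <- dplyr::summarise(
    dplyr::group_by(dat, .data$site, .data$logger),
    n_gaps = sum(diff(as.numeric(.data$timestamp)) > 3600),
    .groups = "drop"
  )
  if (any(gaps$n_gaps > 0)) {
    warning("hourly cadence gaps in logger(s): ",
            paste(sprintf("%s (%d)", gaps$logger[gaps$n_gaps > 0],
                          gaps$n_gaps[gaps$n_gaps > 0]), collapse = ", "),
            call. = FALSE)
  }
  dat
}

#' Write an analysis report to TSV or JSON
#'
#' Accepts a data frame, a single test result (anything with an
#' [tibble::as_tibble()] method, e.g. [chi_squared_gof()] output) or a list
#' of such results, flattens to one tidy table and writes it. Output is
#' bit-stable for fixed inputs.
#'
#' @param results Data frame, result object, or list of result objects.
#' @param path Output path.
#' @param format `"tsv"` or `"json"`.
#' @return `path`, invisibly.
#' @export
write_report <- function(results, path, format = c("tsv", "json")) {
  format <- match.arg(format)
  tidy <- if (is.data.frame(results)) {
    as_tibble(results)
  } else if (inherits(results, c("pairing_gof", "pair_counts"))) {
    as_tibble(results)
  } else if (is.list(results)) {
    dplyr::bind_rows(lapply(results, as_tibble))
  } else {
    stop("cannot tidy results of class ", paste(class(results),
                                                collapse = "/"),
         call. = FALSE)
  }
  if (format == "tsv") {
    readr::write_tsv(tidy, path, progress = FALSE)
  } else {
    jsonlite::write_json(tidy, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE, POSIXt = "ISO8601")
  }
  invisible(path)
}

#' The published pair and tower count tables, as packaged fixtures
#'
#' Loads the eight observed count tables (two species x rising/falling trail
#' pairs, and two species x before-rising/after-falling towers) shipped with
#' the package. The E. radiata falling-tide trail table is published without
#' its FF row; that count is inferred from the declared total of 120 pairs
#' and flagged accordingly.
#'
#' @return A named list of eight [pair_counts()] objects.
#' @examples
#' tabs <- printed_pair_tables()
#' names(tabs)
#' @export
printed_pair_tables <- function() {
  trail <- read_pairs(system.file("extdata", "trail_pairs_observed.csv",
                                  package = "tidepair", mustWork = TRUE))
  tower <- read_pairs(system.file("extdata", "towers_observed.csv",
                                  package = "tidepair", mustWork = TRUE))
  c(trail, tower)
}
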