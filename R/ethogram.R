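# Fitness-associated activity categories, in reporting order.
ACTIVITY_CATEGORIES <- c("reproduction", "foraging", "stress_mitigation",
                         "inactive")

#' Default ethogram: behaviors and their fitness-associated activities
#'
#' The scoring catalogue for high-shore littorinid scan surveys. Mating and
#' fighting serve reproduction; moving and turning are ascribed to foraging
#' (snails rasp the biofilm as they move, so any movement is treated as
#' foraging); crevice occupation, towering, standing and aggregating are
#' stress-mitigating thermoregulatory behaviors; a stationary snail showing no
#' other activity is inactive.
#'
#' @return A tibble with columns `behavior` and `category`.
#' @examples
#' default_ethogram()
#' @export
default_ethogram <- function() {
  tibble(
    behavior = c("mating", "fighting",
                 "moving", "turning",
                 "in_crevice", "towering", "standing", "aggregating",
                 "stationary"),
    category = c("reproduction", "reproduction",
                 "foraging", "foraging",
                 "stress_mitigation", "stress_mitigation",
                 "stress_mitigation", "stress_mitigation",
                 "inactive")
  )
}

#' Validate an ethogram table
#'
#' @param ethogram A data frame with columns `behavior` and `category`, or a
#'   named character vector `behavior -> category`.
#' @return A validated tibble with columns `behavior`, `category`.
#' @export
as_ethogram <- function(ethogram) {
  if (is.character(ethogram) && !is.null(names(ethogram))) {
    ethogram <- tibble(behavior = names(ethogram),
                       category = unname(ethogram))
  }
  if (!is.data.frame(ethogram) ||
      !all(c("behavior", "category") %in% names(ethogram))) {
    stop("ethogram must have columns `behavior` and `category`", call. = FALSE)
  }
  ethogram <- as_tibble(ethogram[, c("behavior", "category")])
  if (anyDuplicated(ethogram$behavior)) {
    stop("each behavior must map to exactly one category", call. = FALSE)
  }
  bad <- setdiff(unique(ethogram$category), ACTIVITY_CATEGORIES)
  if (length(bad)) {
    stop("unknown activity categories: ", paste(bad, collapse = ", "),
         "; must be one of ", paste(ACTIVITY_CATEGORIES, collapse = ", "),
         call. = FALSE)
  }
  ethogram
}

#' Score one individual's behavior set into activity categories
#'
#' Each fitness-associated activity is flagged at most once per individual,
#' however many of its behaviors the snail shows simultaneously (a snail both
#' aggregating and in a crevice scores stress mitigation once). Behaviors from
#' different categories each flag their own category, so a multifunctional
#' individual (e.g. a female mating while moving) contributes to several
#' categories at once.
#'
#' @param behavior_set Non-empty character vector of behavior names.
#' @param ethogram An ethogram table (default [default_ethogram()]).
#' @return Named integer 0/1 vector over the four activity categories.
#' @examples
#' score_individual(c("aggregating", "in_crevice"))  # stress_mitigation once
#' score_individual(c("mating", "turning"))          # reproduction + foraging
#' @export
score_individual <- function(behavior_set, ethogram = default_ethogram()) {
  ethogram <- as_ethogram(ethogram)
  behavior_set <- unique(as.character(behavior_set))
  if (length(behavior_set) == 0 || all(is.na(behavior_set))) {
    stop("behavior set must be non-empty", call. = FALSE)
  }
  unknown <- setdiff(behavior_set, ethogram$behavior)
  if (length(unknown)) {
    stop("unknown behavior name(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  cats <- ethogram$category[match(behavior_set, ethogram$behavior)]
  out <- as.integer(ACTIVITY_CATEGORIES %in% cats)
  names(out) <- ACTIVITY_CATEGORIES
  out
}
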