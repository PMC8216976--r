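#' @importFrom rlang .data
#' @importFrom tibble tibble as_tibble
NULL

# Ordered sex-combination keys: first letter = role-1 sex (marker / bottom
# snail), second = role-2 sex (tracker / top snail).
PAIR_COMBOS <- c("FM", "MM", "MF", "FF")

#' Observed counts of the four ordered sex combinations
#'
#' Container for the observed counts of sexed two-animal associations of one
#' type (trail-following pairs or two-snail towers) in one context (species,
#' tide phase). The combination key `XY` reads: role-1 individual of sex `X`
#' paired with role-2 individual of sex `Y`. For trail following role 1 is the
#' mucus-trail marker and role 2 the tracker; for towers role 1 is the bottom
#' snail and role 2 the snail on top.
#'
#' @param FM,MM,MF,FF Non-negative integer counts of each ordered combination.
#' @param association_type `"trail_following"` or `"tower"`.
#' @param species Species label (free text, e.g. `"E_malaccana"`).
#' @param tide_phase Tide-phase label (e.g. `"rising"`, `"after_falling"`).
#' @param role_labels Length-2 character vector naming role 1 and role 2.
#' @param inferred Character vector of combination keys whose counts were not
#'   observed directly but inferred from a declared total (see [read_pairs()]).
#'
#' @return An object of class `pair_counts`.
#' @examples
#' pair_counts(FM = 68, MM = 26, MF = 12, FF = 20,
#'             species = "E_malaccana", tide_phase = "rising")
#' @export
pair_counts <- function(FM, MM, MF, FF,
                        association_type = c("trail_following", "tower"),
                        species = NA_character_,
                        tide_phase = NA_character_,
                        role_labels = NULL,
                        inferred = character()) {
  association_type <- match.arg(association_type)
  counts <- c(FM = FM, MM = MM, MF = MF, FF = FF)
  if (anyNA(counts)) {
    stop("all four combination counts must be supplied (no NA); use ",
         "`read_pairs()` with a declared N to infer a missing count",
         call. = FALSE)
  }
  if (any(counts < 0) || any(counts != round(counts))) {
    stop("combination counts must be non-negative integers", call. = FALSE)
  }
  counts <- as.integer(round(counts))
  names(counts) <- PAIR_COMBOS
  if (sum(counts) < 1L) {
    stop("empty table: total number of pairs must be at least 1", call. = FALSE)
  }
  if (is.null(role_labels)) {
    role_labels <- if (association_type == "tower") {
      c("bottom", "top")
    } else {
      c("marker", "tracker")
    }
  }
  structure(
    list(counts = counts,
         N = sum(counts),
         association_type = association_type,
         species = species,
         tide_phase = tide_phase,
         role_labels = role_labels,
         inferred = inferred),
    class = "pair_counts"
  )
}

#' @export
print.pair_counts <- function(x, ...) {
  cat(sprintf("<pair_counts> %s, %s, %s (N = %d)\n",
              x$association_type, x$species, x$tide_phase, x$N))
  lab <- sprintf("%s->%s", x$role_labels[1], x$role_labels[2])
  cat(sprintf("  combinations (%s): %s\n", lab,
              paste(sprintf("%s=%d", names(x$counts), x$counts),
                    collapse = ", ")))
  if (length(x$inferred)) {
    cat("  inferred from declared N:", paste(x$inferred, collapse = ", "), "\n")
  }
  invisible(x)
}

#' @exportS3Method tibble::as_tibble
as_tibble.pair_counts <- function(x, ...) {
  tibble(association_type = x$association_type,
         species = x$species,
         tide_phase = x$tide_phase,
         combination = names(x$counts),
         count = unname(x$counts),
         inferred = names(x$counts) %in% x$inferred)
}

#' Pool of sexed individuals available for pairing
#'
#' @param m Number of males.
#' @param n Number of females.
#' @return An object of class `sexed_pool`.
#' @examples
#' sexed_pool(m = 132, n = 120)
#' @export
sexed_pool <- function(m, n) {
  if (anyNA(c(m, n)) || m < 0 || n < 0 || m != round(m) || n != round(n)) {
    stop("m and n must be non-negative integers", call. = FALSE)
  }
  if (m + n < 2) {
    stop("pool must contain at least 2 individuals", call. = FALSE)
  }
  structure(list(m = as.integer(m), n = as.integer(n)), class = "sexed_pool")
}

#' @export
print.sexed_pool <- function(x, ...) {
  cat(sprintf("<sexed_pool> m = %d males, n = %d females (%d individuals)\n",
              x$m, x$n, x$m + x$n))
  invisible(x)
}

#' Derive the sexed pool implied by a table of paired individuals
#'
#' Every individual in the observed associations appears in exactly one pair,
#' so the numbers of males and females in the pool follow directly from the
#' combination counts: each MM pair holds two males, each FF pair two females,
#' and each mixed pair one of each.
#'
#' @param counts A [pair_counts()] object.
#' @return A [sexed_pool()] with `m = 2*MM + FM + MF` and `n = 2*FF + FM + MF`.
#' @examples
#' derive_pool(pair_counts(FM = 68, MM = 26, MF = 12, FF = 20))
#' @export
derive_pool <- function(counts) {
  stopifnot(inherits(counts, "pair_counts"))
  k <- counts$counts
  sexed_pool(m = 2L * k[["MM"]] + k[["FM"]] + k[["MF"]],
             n = 2L * k[["FF"]] + k[["FM"]] + k[["MF"]])
}
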