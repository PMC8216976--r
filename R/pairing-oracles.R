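# Independent oracles for the random-pairing null: brute-force enumeration of
# all matchings x orientations (small pools) and Monte-Carlo simulation.

# One draw from the matching null: a uniformly random permutation of the
# individuals, paired off adjacently, gives a uniform perfect matching with a
# uniformly random within-pair order (the fair-coin role assignment).
draw_null_counts <- function(sexes) {
  s <- sample(sexes)
  r1 <- s[seq(1, length(s), by = 2)]
  r2 <- s[seq(2, length(s), by = 2)]
  c(FM = sum(r1 == "F" & r2 == "M"),
    MM = sum(r1 == "M" & r2 == "M"),
    MF = sum(r1 == "M" & r2 == "F"),
    FF = sum(r1 == "F" & r2 == "F"))
}

#' Monte-Carlo simulation of the random-pairing null
#'
#' Simulates the null sampling model directly: each replicate draws a uniform
#' perfect matching of the `m + n` individuals into `N` pairs and assigns each
#' pair's roles by a fair coin, then tallies the four ordered sex
#' combinations. The resulting empirical distributions serve as an oracle for
#' [expected_random_pairing()] and as the calibrated reference distribution
#' for [chi_squared_gof()] with `method = "monte_carlo"`.
#'
#' @param pool A [sexed_pool()] with an even number of individuals.
#' @param N Number of pairs; defaults to `(m + n) / 2`.
#' @param replicates Number of simulated matchings (>= 1).
#' @param seed Integer seed; required, so results are reproducible.
#' @param observed Optionally a [pair_counts()] object; if supplied, a
#'   Monte-Carlo p-value for its chi-squared statistic is reported.
#' @return An object of class `pairing_mc_null`: `counts` (replicates x 4
#'   matrix), `summary` (tibble with mean, sd and standard error per
#'   combination), `chi2` (null distribution of the Pearson statistic),
#'   `p_value` (if `observed` given), `pool`, `N`, `seed`.
#' @examples
#' mc <- monte_carlo_null(sexed_pool(4, 2), replicates = 500, seed = 1)
#' mc$summary
#' @export
monte_carlo_null <- function(pool, N = (pool$m + pool$n) / 2,
                             replicates = 10000L, seed, observed = NULL) {
  stopifnot(inherits(pool, "sexed_pool"))
  if (missing(seed) || is.null(seed)) {
    stop("`seed` is required for monte_carlo_null()", call. = FALSE)
  }
  if (replicates < 1) stop("replicates must be >= 1", call. = FALSE)
  tot <- pool$m + pool$n
  if (tot %% 2 != 0) {
    stop("pool size m + n must be even to form complete pairs", call. = FALSE)
  }
  if (tot != 2 * N) {
    stop("N must equal (m + n) / 2", call. = FALSE)
  }

  exp_obj <- expected_random_pairing(pool, N)
  E <- exp_obj$expected
  retained <- E > 0

  sexes <- c(rep("M", pool$m), rep("F", pool$n))
  set.seed(as.integer(seed))
  counts <- t(vapply(seq_len(replicates),
                     function(i) draw_null_counts(sexes),
                     integer(4)))
  colnames(counts) <- PAIR_COMBOS

  chi2 <- as.numeric(
    (sweep(counts[, retained, drop = FALSE], 2, E[retained])^2 %*%
       (1 / E[retained]))
  )

  summ <- tibble(
    combination = PAIR_COMBOS,
    mean = colMeans(counts),
    sd = apply(counts, 2, stats::sd),
    se = apply(counts, 2, stats::sd) / sqrt(replicates),
    analytic = unname(E)
  )

  p_value <- NULL
  if (!is.null(observed)) {
    stopifnot(inherits(observed, "pair_counts"))
    O <- as.numeric(observed$counts)
    obs_chi2 <- sum((O[retained] - E[retained])^2 / E[retained])
    p_value <- (1 + sum(chi2 >= obs_chi2)) / (replicates + 1)
  }

  structure(list(counts = counts, summary = summ, chi2 = chi2,
                 p_value = p_value, pool = pool, N = as.integer(N),
                 replicates = as.integer(replicates),
                 seed = as.integer(seed)),
            class = "pairing_mc_null")
}

#' @export
print.pairing_mc_null <- function(x, ...) {
  cat(sprintf("<pairing_mc_null> m = %d, n = %d, N = %d; %d replicates (seed %d)\n",
              x$pool$m, x$pool$n, x$N, x$replicates, x$seed))
  print(x$summary)
  if (!is.null(x$p_value)) cat(sprintf("  MC p-value: %.4g\n", x$p_value))
  invisible(x)
}

#' Exact enumeration of the random-pairing null for small pools
#'
#' Brute-force oracle: enumerates every perfect matching of the pool's
#' individuals and every role orientation of each pair, all with equal
#' weight, and tallies the exact probability distribution of the four
#' combination counts. Feasible for small pools only (`(m+n-1)!! * 2^N`
#' outcomes); expectations agree with the closed form of
#' [expected_random_pairing()] to machine precision.
#'
#' @param pool A [sexed_pool()] with even `m + n`.
#' @param cap Largest pool size `m + n` accepted (default 12).
#' @return A list of class `pairing_exact`: `distribution` (tibble of distinct
#'   count vectors with exact probabilities), `expected` (named numeric),
#'   `n_outcomes`, `pool`.
#' @examples
#' ex <- exact_enumeration(sexed_pool(2, 2))
#' ex$expected  # FM = MF = 2/3, MM = FF = 1/3
#' @export
exact_enumeration <- function(pool, cap = 12L) {
  stopifnot(inherits(pool, "sexed_pool"))
  tot <- pool$m + pool$n
  if (tot %% 2 != 0) {
    stop("pool size m + n must be even to form complete pairs", call. = FALSE)
  }
  if (tot > cap) {
    stop(sprintf("pool size %d exceeds enumeration cap %d", tot, cap),
         call. = FALSE)
  }

  sexes <- c(rep("M", pool$m), rep("F", pool$n))
  acc <- new.env(parent = emptyenv())

  unit <- function(a, b) {
    v <- c(FM = 0L, MM = 0L, MF = 0L, FF = 0L)
    v[paste0(a, b)] <- 1L
    v
  }
  recurse <- function(s, tally) {
    if (length(s) == 0L) {
      key <- paste(tally, collapse = ".")
      acc[[key]] <- (if (is.null(acc[[key]])) 0 else acc[[key]]) + 1
      return(invisible(NULL))
    }
    a <- s[1]
    rest <- s[-1]
    for (j in seq_along(rest)) {
      b <- rest[j]
      rem <- rest[-j]
      recurse(rem, tally + unit(a, b))  # a takes role 1
      recurse(rem, tally + unit(b, a))  # b takes role 1
    }
    invisible(NULL)
  }
  recurse(sexes, c(FM = 0L, MM = 0L, MF = 0L, FF = 0L))

  keys <- ls(acc)
  weights <- vapply(keys, function(k) acc[[k]], numeric(1))
  n_outcomes <- sum(weights)
  mat <- do.call(rbind, lapply(strsplit(keys, ".", fixed = TRUE), as.integer))
  colnames(mat) <- PAIR_COMBOS
  dist <- as_tibble(as.data.frame(mat))
  dist$prob <- unname(weights / n_outcomes)
  dist <- dist[order(-dist$prob), ]

  expected <- colSums(mat * (weights / n_outcomes))

  structure(list(distribution = dist, expected = expected,
                 n_outcomes = n_outcomes, pool = pool),
            class = "pairing_exact")
}

#' @export
print.pairing_exact <- function(x, ...) {
  cat(sprintf("<pairing_exact> m = %d, n = %d; %g equally-weighted outcomes\n",
              x$pool$m, x$pool$n, x$n_outcomes))
  cat("  ", paste(sprintf("E[%s] = %.4f", names(x$expected), x$expected),
                  collapse = ", "), "\n", sep = "")
  invisible(x)
}
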