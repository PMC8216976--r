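#' Expected combination frequencies under random pairing
#'
#' Under the null model, the `m + n` individuals of a finite pool form `N`
#' pairs as a uniformly random perfect matching, and each pair's two roles
#' (marker/tracker, or bottom/top) are assigned by a fair coin. A focal
#' individual's partner is then a uniform draw from the remaining
#' `m + n - 1` individuals, which gives closed-form expected counts
#'
#' \deqn{E[FM] = n \cdot 0.5 \cdot m/(m+n-1), \quad
#'       E[MM] = m \cdot 0.5 \cdot (m-1)/(m+n-1),}
#' \deqn{E[MF] = m \cdot 0.5 \cdot n/(m+n-1), \quad
#'       E[FF] = n \cdot 0.5 \cdot (n-1)/(m+n-1).}
#'
#' The four expectations always sum to `N` exactly, and the two mixed
#' combinations have equal expectation for every pool.
#'
#' @param pool A [sexed_pool()].
#' @param N Number of pairs; must satisfy `m + n == 2 * N`.
#' @return An object of class `pair_expected`: list with `expected` (named
#'   numeric over FM, MM, MF, FF at full precision), `pool` and `N`.
#' @examples
#' expected_random_pairing(sexed_pool(132, 120), N = 126)
#' @seealso [chi_squared_gof()], [exact_enumeration()], [monte_carlo_null()]
#' @export
expected_random_pairing <- function(pool, N = (pool$m + pool$n) / 2) {
  stopifnot(inherits(pool, "sexed_pool"))
  m <- pool$m
  n <- pool$n
  tot <- m + n
  if (tot < 2) stop("pool must contain at least 2 individuals", call. = FALSE)
  if (tot != 2 * N) {
    stop(sprintf("inconsistent pool: m + n = %d but 2N = %g", tot, 2 * N),
         call. = FALSE)
  }
  expected <- c(
    FM = n * 0.5 * m / (tot - 1),
    MM = m * 0.5 * (m - 1) / (tot - 1),
    MF = m * 0.5 * n / (tot - 1),
    FF = n * 0.5 * (n - 1) / (tot - 1)
  )
  structure(list(expected = expected, pool = pool, N = as.integer(N)),
            class = "pair_expected")
}

#' @export
print.pair_expected <- function(x, ...) {
  cat(sprintf("<pair_expected> random pairing of m = %d, n = %d into N = %d pairs\n",
              x$pool$m, x$pool$n, x$N))
  cat("  ", paste(sprintf("%s = %.1f", names(x$expected), x$expected),
                  collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Chi-squared goodness-of-fit test against random pairing
#'
#' Pearson test of observed combination counts against the [random-pairing
#' expectations][expected_random_pairing]. Categories with zero expectation
#' (possible only for single-sex pools) are dropped and the degrees of freedom
#' reduced; with all four categories retained `df = 3`. The analytic p-value
#' uses the upper tail of the chi-squared distribution, mirroring the
#' conventional analysis of such tables; because the pool sex totals are fixed
#' by the observed pairs, that reference distribution is conservative, and
#' `method = "monte_carlo"` instead calibrates the p-value against the exact
#' matching null simulated by [monte_carlo_null()].
#'
#' @param observed A [pair_counts()] object.
#' @param expected Optionally a precomputed [expected_random_pairing()] result;
#'   by default derived from `observed` via [derive_pool()].
#' @param method `"analytic"` (chi-squared upper tail, default) or
#'   `"monte_carlo"` (p-value from the simulated matching null).
#' @param replicates,seed Monte-Carlo settings, used when
#'   `method = "monte_carlo"` and no `null` object is supplied.
#' @param null Optionally a [monte_carlo_null()] object for the same pool, so
#'   one simulated null can serve many tests.
#' @return An object of class `pairing_gof`: `chi2`, `df`, `p_value`,
#'   `expected`, `observed`, `method`, `warnings`.
#' @examples
#' obs <- pair_counts(FM = 68, MM = 26, MF = 12, FF = 20)
#' chi_squared_gof(obs)
#' @export
chi_squared_gof <- function(observed, expected = NULL,
                            method = c("analytic", "monte_carlo"),
                            replicates = 4000L, seed = NULL, null = NULL) {
  stopifnot(inherits(observed, "pair_counts"))
  method <- match.arg(method)
  if (is.null(expected)) {
    expected <- expected_random_pairing(derive_pool(observed))
  }
  stopifnot(inherits(expected, "pair_expected"))
  if (!identical(names(observed$counts), names(expected$expected))) {
    stop("combination keys of observed and expected tables do not align",
         call. = FALSE)
  }
  if (observed$N != expected$N) {
    stop(sprintf("observed N = %d but expected table has N = %d",
                 observed$N, expected$N), call. = FALSE)
  }

  O <- as.numeric(observed$counts)
  E <- as.numeric(expected$expected)
  names(O) <- names(E) <- PAIR_COMBOS
  warnings <- character()

  retained <- E > 0
  if (!any(retained)) stop("all expected counts are zero", call. = FALSE)
  if (any(!retained)) {
    impossible <- names(E)[!retained & O > 0]
    if (length(impossible)) {
      stop("observed counts in categories impossible under the null (",
           paste(impossible, collapse = ", "),
           "): observed table inconsistent with derived pool", call. = FALSE)
    }
    warnings <- c(warnings,
                  sprintf("dropped zero-expectation categories: %s (df reduced)",
                          paste(names(E)[!retained], collapse = ", ")))
  }
  if (any(E[retained] < 5)) {
    warnings <- c(warnings,
                  sprintf("expected count below 5 in: %s; chi-squared approximation may be poor, consider method = \"monte_carlo\"",
                          paste(names(E)[retained][E[retained] < 5],
                                collapse = ", ")))
  }
  if (length(observed$inferred)) {
    warnings <- c(warnings,
                  sprintf("counts inferred from declared N: %s",
                          paste(observed$inferred, collapse = ", ")))
  }

  chi2 <- sum((O[retained] - E[retained])^2 / E[retained])
  df <- sum(retained) - 1L

  if (df == 0L) {
    # single-sex pool with one possible category: the null predicts the
    # observed table with certainty
    warnings <- c(warnings, "only one category retained; test is degenerate")
  }
  if (method == "analytic") {
    p_value <- if (df == 0L) 1 else
      stats::pchisq(chi2, df = df, lower.tail = FALSE)
  } else {
    if (is.null(null)) {
      if (is.null(seed)) {
        stop("method = \"monte_carlo\" needs a `seed` (or a precomputed `null`)",
             call. = FALSE)
      }
      null <- monte_carlo_null(expected$pool, N = expected$N,
                               replicates = replicates, seed = seed)
    }
    stopifnot(inherits(null, "pairing_mc_null"))
    if (null$pool$m != expected$pool$m || null$pool$n != expected$pool$n) {
      stop("supplied `null` was simulated for a different pool", call. = FALSE)
    }
    # add-one Monte-Carlo p-value; ties with the observed statistic count as
    # at least as extreme
    p_value <- (1 + sum(null$chi2 >= chi2)) / (length(null$chi2) + 1)
  }

  structure(
    list(chi2 = chi2, df = df, p_value = p_value,
         expected = expected, observed = observed,
         method = method, warnings = warnings),
    class = "pairing_gof"
  )
}

#' Format a p-value in the reporting convention used for these tables
#'
#' `"p < .001"`, `"p < .05"` or `"n.s."` (not significant at the 0.05 level).
#' The raw p-value is always retained in the [chi_squared_gof()] result.
#'
#' @param p A p-value in `[0, 1]`.
#' @return A character scalar.
#' @export
format_p_convention <- function(p) {
  stopifnot(is.numeric(p), p >= 0, p <= 1)
  if (p < 0.001) "p < .001" else if (p < 0.05) "p < .05" else "n.s."
}

#' @export
print.pairing_gof <- function(x, ...) {
  obs <- x$observed
  cat(sprintf("Random-pairing goodness of fit: %s, %s, %s\n",
              obs$association_type, obs$species, obs$tide_phase))
  cat(sprintf("  pool: m = %d, n = %d; N = %d pairs\n",
              x$expected$pool$m, x$expected$pool$n, obs$N))
  df <- data.frame(combination = PAIR_COMBOS,
                   observed = as.integer(obs$counts),
                   expected = sprintf("%.1f", x$expected$expected))
  print(df, row.names = FALSE)
  cat(sprintf("  chi-squared = %.2f, df = %d, %s (p = %.4g, %s)\n",
              x$chi2, x$df, format_p_convention(x$p_value), x$p_value,
              x$method))
  for (w in x$warnings) cat("  note:", w, "\n")
  invisible(x)
}

#' @exportS3Method tibble::as_tibble
as_tibble.pairing_gof <- function(x, ...) {
  obs <- x$observed
  tibble(association_type = obs$association_type,
         species = obs$species,
         tide_phase = obs$tide_phase,
         combination = PAIR_COMBOS,
         observed = as.integer(obs$counts),
         expected = unname(x$expected$expected),
         chi2 = x$chi2,
         df = x$df,
         p_value = x$p_value,
         significance = format_p_convention(x$p_value),
         method = x$method,
         warnings = paste(x$warnings, collapse = "; "))
}

#' Moment estimator of directed pairing preference
#'
#' Plug-in estimator of the preference parameter `theta` of the generative
#' model in [simulate_pairs()]: the probability that a pair forms as a
#' directed female-role-1 / male-role-2 event rather than by random pairing.
#' Since `E[O_FM] = N*theta + (1-theta)*E_FM` (to first order in pool
#' depletion), the moment estimator is
#' `theta_hat = (O_FM - E_FM) / (N - E_FM)`, clipped to `[0, 1]`.
#'
#' @param observed A [pair_counts()] object; its pool must contain both sexes.
#' @param expected Optional precomputed [expected_random_pairing()] result.
#' @return A list of class `preference_estimate`: `theta_hat`, `o_fm`, `e_fm`,
#'   `N`, `clipped`.
#' @examples
#' preference_estimate(pair_counts(FM = 68, MM = 26, MF = 12, FF = 20))
#' @export
preference_estimate <- function(observed, expected = NULL) {
  stopifnot(inherits(observed, "pair_counts"))
  if (is.null(expected)) {
    expected <- expected_random_pairing(derive_pool(observed))
  }
  pool <- expected$pool
  if (pool$m == 0 || pool$n == 0) {
    stop("preference is undefined for single-sex pools (m = 0 or n = 0)",
         call. = FALSE)
  }
  e_fm <- expected$expected[["FM"]]
  N <- observed$N
  if (N <= e_fm) {
    stop("estimator undefined: N must exceed the null expectation of FM",
         call. = FALSE)
  }
  raw <- (observed$counts[["FM"]] - e_fm) / (N - e_fm)
  theta_hat <- min(max(raw, 0), 1)
  structure(list(theta_hat = theta_hat,
                 o_fm = observed$counts[["FM"]],
                 e_fm = e_fm, N = N,
                 clipped = !identical(raw, theta_hat)),
            class = "preference_estimate")
}

#' @export
print.preference_estimate <- function(x, ...) {
  cat(sprintf("theta_hat = %.3f (O_FM = %d, null E_FM = %.2f, N = %d%s)\n",
              x$theta_hat, x$o_fm, x$e_fm, x$N,
              if (x$clipped) ", clipped to [0,1]" else ""))
  invisible(x)
}
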