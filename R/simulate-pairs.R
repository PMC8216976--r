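#' Scenario for simulating sexed pair formation
#'
#' @param m,n Males and females in the pool; `m + n` must equal `2 * N`.
#' @param N Number of pairs formed; defaults to `(m + n) / 2`.
#' @param theta Preference strength in `[0, 1]`: the probability that a pair
#'   forms as a directed female-role-1 / male-role-2 event (a male tracking a
#'   female's trail, or a male settling on top of a female) rather than by the
#'   random-pairing null. `theta = 0` is the null model.
#' @param seed Integer seed; required.
#' @return A list of class `pairing_scenario`.
#' @export
pairing_scenario <- function(m, n, N = (m + n) / 2, theta = 0, seed) {
  if (missing(seed) || is.null(seed)) {
    stop("`seed` is required for pairing_scenario()", call. = FALSE)
  }
  pool <- sexed_pool(m, n)
  if (pool$m + pool$n != 2 * N) {
    stop("infeasible pool: m + n must equal 2 * N", call. = FALSE)
  }
  if (theta < 0 || theta > 1) stop("theta must lie in [0, 1]", call. = FALSE)
  structure(list(pool = pool, N = as.integer(N), theta = theta,
                 seed = as.integer(seed)),
            class = "pairing_scenario")
}

#' Simulate a table of sexed pairs with known preference strength
#'
#' Generative model: of the `N` pairs, each is independently a directed
#' preference event with probability `theta` — a female takes role 1 (marker /
#' bottom) and a male role 2 (tracker / top), both removed from the pool. The
#' number of preference pairs is therefore `Binomial(N, theta)`, truncated at
#' feasibility (`min(m, n)`); any excess falls back to null pairing and is
#' recorded in the ground-truth attribute. The remaining individuals then form
#' a uniform perfect matching with fair role assignment, exactly the null
#' model of [monte_carlo_null()]. At `theta = 0` the output is a draw from the
#' null; at `theta = 1` with `m = n` every pair is FM.
#'
#' @param scenario A [pairing_scenario()].
#' @return A [pair_counts()] object with attribute `truth`: list with `theta`,
#'   `m`, `n`, `N`, `seed`, `n_preference` (realized directed pairs) and
#'   `n_fallback` (preference events that were infeasible and fell back to
#'   null pairing).
#' @examples
#' sc <- pairing_scenario(m = 132, n = 120, theta = 0.4, seed = 42)
#' simulate_pairs(sc)
#' @export
simulate_pairs <- function(scenario) {
  stopifnot(inherits(scenario, "pairing_scenario"))
  pool <- scenario$pool
  N <- scenario$N
  set.seed(scenario$seed)

  k_want <- stats::rbinom(1, N, scenario$theta)
  k <- min(k_want, pool$m, pool$n)
  n_fallback <- k_want - k

  counts <- c(FM = k, MM = 0L, MF = 0L, FF = 0L)
  m_left <- pool$m - k
  n_left <- pool$n - k
  if (m_left + n_left > 0) {
    counts <- counts + draw_null_counts(c(rep("M", m_left), rep("F", n_left)))
  }

  out <- pair_counts(FM = counts[["FM"]], MM = counts[["MM"]],
                     MF = counts[["MF"]], FF = counts[["FF"]],
                     species = "simulated", tide_phase = "simulated")
  attr(out, "truth") <- list(theta = scenario$theta, m = pool$m, n = pool$n,
                             N = N, seed = scenario$seed,
                             n_preference = k, n_fallback = n_fallback)
  out
}

#' Monte-Carlo power of the goodness-of-fit test across preference strengths
#'
#' For each value of `theta`, simulates `replicates` pair tables with
#' [simulate_pairs()] and records the fraction rejected by
#' [chi_squared_gof()] at level `alpha`. At `theta = 0` this is the empirical
#' type-I error; it should sit near `alpha` for the Monte-Carlo test and at or
#' below `alpha` for the (conservative) analytic test.
#'
#' @param m,n,N Pool geometry, as in [pairing_scenario()].
#' @param theta Numeric vector of preference strengths.
#' @param alpha Test level (default 0.05).
#' @param replicates Simulated tables per theta.
#' @param seed Integer seed; required.
#' @param method Passed to [chi_squared_gof()]; for `"monte_carlo"` a single
#'   simulated null distribution (`null_replicates` draws) is shared by all
#'   replicates.
#' @param null_replicates Size of the shared simulated null when
#'   `method = "monte_carlo"`.
#' @return A tibble with columns `theta`, `power`, `se` (binomial standard
#'   error), `rejections`, `replicates`.
#' @export
power_curve <- function(m, n, N = (m + n) / 2, theta = c(0, 0.25, 0.5, 1),
                        alpha = 0.05, replicates = 200L, seed,
                        method = c("analytic", "monte_carlo"),
                        null_replicates = 4000L) {
  if (missing(seed) || is.null(seed)) {
    stop("`seed` is required for power_curve()", call. = FALSE)
  }
  method <- match.arg(method)
  stopifnot(all(theta >= 0 & theta <= 1), alpha > 0, alpha < 1,
            replicates >= 1)
  pool <- sexed_pool(m, n)
  exp_obj <- expected_random_pairing(pool, N)

  null <- NULL
  if (method == "monte_carlo") {
    null <- monte_carlo_null(pool, N, replicates = null_replicates,
                             seed = as.integer(seed) + 1000003L)
  }

  rows <- lapply(seq_along(theta), function(i) {
    th <- theta[i]
    rej <- 0L
    for (r in seq_len(replicates)) {
      sc <- pairing_scenario(m, n, N, theta = th,
                             seed = as.integer(seed) + 131L * i + 7919L * r)
      tab <- simulate_pairs(sc)
      g <- chi_squared_gof(tab, expected = exp_obj, method = method,
                           null = null)
      if (g$p_value < alpha) rej <- rej + 1L
    }
    p_hat <- rej / replicates
    tibble(theta = th, power = p_hat,
           se = sqrt(p_hat * (1 - p_hat) / replicates),
           rejections = rej, replicates = as.integer(replicates))
  })
  dplyr::bind_rows(rows)
}
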