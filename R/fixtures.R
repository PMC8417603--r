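#' Generate reproducible test distributions
#'
#' Seeded generators for the distribution families used throughout the
#' package's test surface and examples — no external data needed.
#' Families:
#'
#' * `uniform`: k equal components (perfect equality).
#' * `point_mass`: all N units in one component, k - 1 null components
#'   (maximum inequality).
#' * `two_level`: a high block and a low block of components, the high
#'   block's per-component units `ratio` times the low block's.
#' * `lognormal`: heavy-tailed positive values, the classic shape of
#'   income- or reaction-time-like data.
#' * `pareto_like`: power-law tail `u^(-1/alpha)` from uniform draws.
#' * `random_dirichlet`: shares drawn uniformly from the simplex
#'   (normalized standard exponentials) and scaled to total N.
#' * `integer_counts`: multinomial counts over k categories with
#'   Dirichlet-random probabilities (a categorical distribution).
#'
#' With a non-`NULL` seed the output is bit-reproducible.
#'
#' @param family one of the families above.
#' @param k number of components (>= 1).
#' @param N total unit sum (families `uniform`, `point_mass`,
#'   `two_level`, `random_dirichlet`, `integer_counts`).
#' @param seed optional integer seed for the random families.
#' @param high_frac fraction of components in the high block
#'   (`two_level`).
#' @param ratio high-to-low per-component unit ratio (`two_level`).
#' @param meanlog,sdlog log-scale parameters (`lognormal`).
#' @param alpha tail exponent (`pareto_like`).
#' @return A [unit_distribution()] (`kind = "categorical"` for
#'   `integer_counts`, `"metric"` otherwise).
#' @examples
#' generate_distribution("two_level", k = 6, N = 760, high_frac = 1/3,
#'                       ratio = 2)
#' generate_distribution("lognormal", k = 50, seed = 7)
#' @export
generate_distribution <- function(family = c("uniform", "point_mass",
                                             "two_level", "lognormal",
                                             "pareto_like", "random_dirichlet",
                                             "integer_counts"),
                                  k, N = 100 * k, seed = NULL,
                                  high_frac = 0.5, ratio = 3,
                                  meanlog = log(100), sdlog = 1,
                                  alpha = 2) {
  family <- match.arg(family)
  if (length(k) != 1L || is.na(k) || k < 1) {
    ineq_stop("`k` must be a positive integer", "ineq_argument_error")
  }
  k <- as.integer(k)
  if (!is.null(seed)) set.seed(seed)

  units <- switch(
    family,
    uniform = rep(N / k, k),
    point_mass = c(N, rep(0, k - 1)),
    two_level = {
      if (high_frac <= 0 || high_frac >= 1 || ratio <= 0) {
        ineq_stop("`high_frac` must be in (0,1) and `ratio` positive",
                  "ineq_argument_error")
      }
      kh <- max(1L, round(k * high_frac))
      kl <- k - kh
      if (kl < 1L) {
        ineq_stop("`high_frac` leaves no low-block components",
                  "ineq_argument_error")
      }
      raw <- c(rep(ratio, kh), rep(1, kl))
      raw * N / sum(raw)
    },
    lognormal = stats::rlnorm(k, meanlog = meanlog, sdlog = sdlog),
    pareto_like = {
      if (alpha <= 0) {
        ineq_stop("`alpha` must be positive", "ineq_argument_error")
      }
      stats::runif(k)^(-1 / alpha)
    },
    random_dirichlet = {
      g <- stats::rgamma(k, shape = 1)
      N * g / sum(g)
    },
    integer_counts = {
      g <- stats::rgamma(k, shape = 1)
      as.numeric(stats::rmultinom(1, size = round(N), prob = g / sum(g)))
    }
  )
  kind <- if (family == "integer_counts") "categorical" else "metric"
  unit_distribution(units, kind = kind)
}
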