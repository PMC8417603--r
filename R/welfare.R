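#' Atkinson index
#'
#' The social-welfare inequality measure
#' \deqn{AI(\varepsilon) = 1 - \frac{M_{1-\varepsilon}(n)}{\bar n}}
#' where \eqn{M_{1-\varepsilon}} is the power mean of order 1 - epsilon
#' of the units (the geometric mean at epsilon = 1) and \eqn{\bar n} the
#' arithmetic mean. The "inequality aversion" parameter epsilon >= 0
#' weights the low range of the distribution: AI(0) = 0 for every
#' distribution, and AI increases with epsilon whenever the distribution
#' is not perfectly equal. Values lie in `[0, 1]`; AI quantifies the
#' fraction of the total unit sum that could be saved if every component
#' were brought to the equally-distributed-equivalent standard
#' (see [ede_standard()]). Values of epsilon between 1.5 and 2 are the
#' classic recommendation for income-type applications.
#'
#' Zero units: for epsilon >= 1 the power mean collapses to 0 and AI = 1;
#' for 0 < epsilon < 1 the index is finite.
#'
#' @param d a metric [unit_distribution()].
#' @param epsilon inequality aversion, a single non-negative number
#'   (required; no default).
#' @return The index value in `[0, 1]`.
#' @examples
#' d <- unit_distribution(c(360, 250, 150))
#' atkinson(d, epsilon = 1)  # 0.06008
#' @export
atkinson <- function(d, epsilon) {
  d <- as_unit_distribution(d)
  check_epsilon(epsilon)
  if (epsilon == 0) {
    return(0)
  }
  n <- d$units
  if (epsilon >= 1 && any(n == 0)) {
    return(1)
  }
  pm <- if (epsilon == 1) {
    exp(mean(log(n)))
  } else {
    om <- 1 - epsilon
    mean(n^om)^(1 / om)
  }
  1 - pm / d$mean_units
}

check_epsilon <- function(epsilon) {
  if (missing(epsilon) || !is.numeric(epsilon) || length(epsilon) != 1L ||
      is.na(epsilon)) {
    ineq_stop("`epsilon` must be a single numeric value", "ineq_parameter_error")
  }
  if (epsilon < 0) {
    ineq_stop("`epsilon` (inequality aversion) must be non-negative",
              "ineq_domain_error")
  }
  invisible(epsilon)
}

#' Equally-distributed-equivalent standard
#'
#' The common per-component standard n_eps = mean(n) * (1 - AI(eps)):
#' the level that, given equally distributed units, would be deemed
#' equivalent (under aversion epsilon) to the observed unequal
#' distribution. Equals the power mean of order 1 - epsilon of the
#' units. The fraction of the total unit sum needed to give every
#' component this standard is 1 - AI: with AI = 0.4, 60% of the total
#' would suffice.
#'
#' @inheritParams atkinson
#' @return The standard, in the same units as `d$units`.
#' @export
ede_standard <- function(d, epsilon) {
  d <- as_unit_distribution(d)
  d$mean_units * (1 - atkinson(d, epsilon))
}

#' Solve for the aversion parameter giving a target standard
#'
#' Inverts [ede_standard()]: finds epsilon >= 0 such that the
#' equally-distributed-equivalent standard equals `target`. Useful when
#' the standard has a substantive interpretation (a reaction-time
#' validity threshold, a clinical cutoff): the Atkinson index at the
#' returned epsilon then quantifies inequality with respect to that
#' standard. The standard is non-increasing in epsilon, from the
#' arithmetic mean at epsilon = 0 down towards the minimum unit (or 0 if
#' any unit is 0), so the root is unique; it is located by bracketed
#' root finding with geometric expansion of the upper bracket.
#'
#' @inheritParams atkinson
#' @param target the desired standard, in unit scale; must lie in
#'   (inf, mean(n)], where inf is the infimum of achievable standards.
#' @param tol convergence tolerance on the standard, relative to the
#'   mean (default 1e-8).
#' @return The aversion parameter epsilon (>= 0).
#' @examples
#' d <- unit_distribution(c(360, 250, 150))
#' epsilon_for_standard(d, ede_standard(d, 1))  # ~1
#' @export
epsilon_for_standard <- function(d, target, tol = 1e-8) {
  d <- as_unit_distribution(d)
  if (!is.numeric(target) || length(target) != 1L || is.na(target)) {
    ineq_stop("`target` must be a single numeric value", "ineq_parameter_error")
  }
  nbar <- d$mean_units
  inf_std <- if (any(d$units == 0)) 0 else min(d$units)
  if (target > nbar * (1 + 1e-12) || target <= inf_std) {
    ineq_stop(
      sprintf("target standard %g is not achievable: the standard ranges over (%g, %g] for these data",
              target, inf_std, nbar),
      "ineq_range_error"
    )
  }
  atol <- tol * nbar
  f <- function(eps) ede_standard(d, eps) - target
  if (abs(f(0)) <= atol) {
    return(0)
  }
  hi <- 1
  while (f(hi) > 0) {
    hi <- hi * 2
    if (hi > 2^24) {
      ineq_stop("could not bracket the target standard; it may be numerically indistinguishable from the infimum",
                "ineq_range_error")
    }
  }
  stats::uniroot(f, lower = 0, upper = hi, tol = atol / 10)$root
}

#' Atkinson index from a generalized entropy value
#'
#' The Atkinson and generalized entropy families are linked through
#' epsilon = 1 - alpha. With GE evaluated at alpha = 1 - epsilon, the
#' index conversions are
#' \deqn{AI = 1 - e^{-GE(0)} \quad (\varepsilon = 1)}
#' \deqn{AI = 1 - \left[1 + \varepsilon(\varepsilon-1)\,GE(1-\varepsilon)\right]^{1/(1-\varepsilon)}
#'   \quad (0 < \varepsilon \ne 1)}
#' both of which follow from the identity
#' (1/k) sum (k p_i)^alpha = 1 + alpha(alpha-1) GE(alpha). Note that the
#' epsilon = 1 branch pairs with the *mean log deviation* GE(0), not the
#' Theil index: epsilon = 1 corresponds to alpha = 0.
#'
#' When the distribution is supplied, the converted value is
#' cross-checked against the direct [atkinson()] computation and a
#' consistency error is raised if the two disagree beyond `1e-8` —
#' surfacing transcription mistakes (a GE value computed at the wrong
#' alpha, say) rather than silently returning a wrong index.
#'
#' @param ge_value a generalized entropy value computed at
#'   `alpha = 1 - epsilon`.
#' @param epsilon inequality aversion, non-negative.
#' @param d optional: the [unit_distribution()] the GE value came from,
#'   enabling the consistency check.
#' @return The Atkinson index value.
#' @examples
#' d <- unit_distribution(c(360, 250, 150))
#' atkinson_ge_link(mean_log_deviation(d), epsilon = 1, d = d)
#' @export
atkinson_ge_link <- function(ge_value, epsilon, d = NULL) {
  check_epsilon(epsilon)
  if (!is.numeric(ge_value) || length(ge_value) != 1L || is.na(ge_value)) {
    ineq_stop("`ge_value` must be a single numeric value", "ineq_parameter_error")
  }
  if (ge_value < 0) {
    ineq_stop("`ge_value` must be non-negative (GE >= 0 always)",
              "ineq_domain_error")
  }
  ai <- if (epsilon == 0) {
    0
  } else if (epsilon == 1) {
    1 - exp(-ge_value)
  } else {
    base <- 1 + epsilon * (epsilon - 1) * ge_value
    if (base <= 0) {
      # only possible for 0 < epsilon < 1 with GE beyond the admissible
      # range for that alpha; the power mean would be complex
      ineq_stop("GE value is outside the range compatible with this epsilon",
                "ineq_domain_error")
    }
    1 - base^(1 / (1 - epsilon))
  }
  if (!is.null(d)) {
    direct <- atkinson(as_unit_distribution(d), epsilon)
    if (abs(ai - direct) > 1e-8) {
      ineq_stop(
        sprintf("GE-converted Atkinson (%.10f) disagrees with direct computation (%.10f); was `ge_value` computed at alpha = 1 - epsilon?",
                ai, direct),
        "ineq_consistency_error"
      )
    }
  }
  ai
}
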