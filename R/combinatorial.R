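#' Herfindahl-Hirschman index
#'
#' The sum of squared unit shares, HHI = sum_i p_i^2: the probability
#' that two units drawn at random *with replacement* stem from the same
#' component. Large shares dominate (0.8^2 = 0.64 but 0.1^2 = 0.01),
#' which is why the index is the standard gauge of market concentration.
#' Null (zero-unit) components are ignored; the index ranges from 1/k'
#' (even shares over the k' non-null components) to 1 (a single
#' component holds everything).
#'
#' The with-replacement urn model is only asymptotically correct for
#' counted categorical data; for small total counts the [simpson()]
#' family is the exact choice, and an advisory message says so.
#'
#' @param d a [unit_distribution()].
#' @param small_n_advisory emit a message steering small-N categorical
#'   data towards the Simpson index (default `TRUE`).
#' @return The index value in `[1/k', 1]`.
#' @examples
#' hhi(unit_distribution(c(360, 250, 150)))  # 0.37154
#' @export
hhi <- function(d, small_n_advisory = TRUE) {
  d <- as_unit_distribution(d)
  if (small_n_advisory && d$kind != "metric" && d$N < 100) {
    message("HHI's with-replacement model is only asymptotically correct for ",
            "counted data; with N = ", d$N,
            " the Simpson index is the exact small-N measure")
  }
  p <- unit_shares(d)
  sum(p[p > 0]^2)
}

#' Simpson index
#'
#' The exact probability that two units drawn at random *without
#' replacement* belong to the same component:
#' S = sum_i n_i (n_i - 1) / (N (N - 1)). Intended for categorical
#' variables with integer counts; it is the small-sample-correct
#' counterpart of [hhi()], to which it converges as N grows with fixed
#' proportions. Ranges over `[0, 1]`.
#'
#' @param d a [unit_distribution()] whose units are integer counts with
#'   total N >= 2.
#' @return The index value in `[0, 1]`.
#' @examples
#' simpson(unit_distribution(c(2, 2), kind = "categorical"))  # 1/3
#' @export
simpson <- function(d) {
  d <- as_unit_distribution(d, kind = "categorical")
  n <- d$units
  if (any(abs(n - round(n)) > 1e-8)) {
    ineq_stop("Simpson index requires integer counts; non-integer units supplied",
              "ineq_type_error")
  }
  n <- round(n)
  N <- sum(n)
  if (N < 2) {
    ineq_stop("Simpson index requires at least two units in total (N >= 2)",
              "ineq_domain_error")
  }
  sum(n * (n - 1)) / (N * (N - 1))
}

#' Gini-Simpson index
#'
#' The complement GS = 1 - S of the [simpson()] index: the probability
#' that two randomly drawn units (without replacement) belong to
#' *different* components. A measure of equality/diversity on `[0, 1]`,
#' also known as the Blau index or the probability of interspecific
#' encounter.
#'
#' @inheritParams simpson
#' @return The index value in `[0, 1]`.
#' @export
gini_simpson <- function(d) {
  1 - simpson(d)
}

#' Inverse Simpson index
#'
#' The reciprocal IS = 1/S of the [simpson()] index, mapping it onto
#' `[1, Inf]`: 1 when all units share one component, `Inf` when every
#' unit is alone in its component (same-component probability 0). A
#' measure of equality/diversity (the "effective number of components"
#' under the without-replacement model).
#'
#' @inheritParams simpson
#' @return The index value in `[1, Inf]`; `Inf` when S = 0.
#' @export
inverse_simpson <- function(d) {
  s <- simpson(d)
  if (s == 0) Inf else 1 / s
}
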