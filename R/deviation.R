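#' Gini index
#'
#' Half the normed average absolute difference between the unit shares of
#' all pairs of components, G = (1/2k) * sum_i sum_j |p_i - p_j|.
#' Graphically, twice the area between the line of equality and the
#' Lorenz curve. Ranges from 0 (perfect equality) to 1 - 1/k (one
#' component holds everything): an *absolute* inequality measure, whose
#' upper bound depends on the number of components. Zero-unit components
#' are retained.
#'
#' The implementation uses the algebraically identical sorted-rank form
#' G = (2/k) * sum_i i*p_(i) - (k+1)/k (ascending order), which is
#' O(k log k) rather than O(k^2).
#'
#' @param d a [unit_distribution()].
#' @return The index value.
#' @examples
#' gini(unit_distribution(c(360, 250, 150)))  # 0.18421
#' @export
gini <- function(d) {
  d <- as_unit_distribution(d)
  p <- sort(unit_shares(d))
  k <- d$k
  (2 / k) * sum(seq_len(k) * p) - (k + 1) / k
}

#' Corrected Gini index
#'
#' The Gini index normalized by its maximum, G' = G / (1 - 1/k), giving a
#' *relative* inequality measure on `[0, 1]` that is comparable across
#' distributions with different numbers of components. Undefined for a
#' single component.
#'
#' @inheritParams gini
#' @return The corrected index in `[0, 1]`.
#' @export
gini_corrected <- function(d) {
  d <- as_unit_distribution(d)
  if (d$k < 2) {
    ineq_stop("corrected Gini is undefined for k = 1 (correction factor 1 - 1/k is 0)",
              "ineq_domain_error")
  }
  gini(d) / (1 - 1 / d$k)
}

#' Hoover index
#'
#' Half the sum of absolute deviations of the unit shares from their mean
#' 1/k: H = (1/2) * sum_i |p_i - 1/k|. Interpretable as the share of
#' units that would have to be redistributed to reach perfect equality
#' (hence the synonyms Robin-Hood, Pietra, Schutz index), and equal to
#' the maximum vertical distance between the Lorenz curve and the line of
#' equality. Ranges over `[0, 1 - 1/k]`.
#'
#' @inheritParams gini
#' @return The index value.
#' @export
hoover <- function(d) {
  d <- as_unit_distribution(d)
  p <- unit_shares(d)
  0.5 * sum(abs(p - 1 / d$k))
}

#' Corrected Hoover index
#'
#' H' = H / (1 - 1/k), the relative form of [hoover()] on `[0, 1]`.
#'
#' @inheritParams gini
#' @return The corrected index in `[0, 1]`.
#' @export
hoover_corrected <- function(d) {
  d <- as_unit_distribution(d)
  if (d$k < 2) {
    ineq_stop("corrected Hoover is undefined for k = 1 (correction factor 1 - 1/k is 0)",
              "ineq_domain_error")
  }
  hoover(d) / (1 - 1 / d$k)
}

#' Rosenbluth (Hall-Tideman) index
#'
#' A rank-based concentration measure: with components sorted descending
#' by share (rank 1 = largest), R = 1 / (2 * sum_i i*p_(i) - 1).
#' Equivalently the reciprocal of twice the area above the concentration
#' curve, and R = 1 / (k * (1 - G)) in terms of the uncorrected Gini
#' index. Ranges from 1/k (perfect equality) to 1 (one component holds
#' everything). Used in economics to gauge how strongly a market is
#' dominated by a monopoly. Ties in the ranking do not affect the value.
#'
#' @inheritParams gini
#' @return The index value in `[1/k, 1]`.
#' @examples
#' rosenbluth(unit_distribution(c(100, 0, 0, 0, 0)))  # 1
#' rosenbluth(unit_distribution(rep(1, 5)))           # 1/5
#' @export
rosenbluth <- function(d) {
  d <- as_unit_distribution(d)
  p <- sort(unit_shares(d), decreasing = TRUE)
  1 / (2 * sum(seq_len(d$k) * p) - 1)
}
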