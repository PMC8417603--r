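#' Shannon index
#'
#' The average information content of the unit distribution,
#' SI = -sum_i p_i log_a(p_i), over the non-null components. With the
#' binary logarithm (the default, units of bits) it is the average number
#' of yes/no questions needed to identify the component of a randomly
#' drawn unit: a single-category sample scores 0, four equally frequent
#' categories score 2. A measure of equality/diversity bounded by
#' `[0, log_a(k')]` with k' the number of non-null components; the value
#' is unchanged when the whole sample is duplicated.
#'
#' @param d a [unit_distribution()] (categorical counts, typically).
#' @param base logarithm base: `2` (bits, default), `exp(1)` or `"e"`
#'   (nats), or `10`.
#' @return The index value.
#' @examples
#' shannon(count_distribution("ABCD"))      # 2 bits
#' shannon(count_distribution("AABBCCDD"))  # 2 bits
#' @export
shannon <- function(d, base = 2) {
  d <- as_unit_distribution(d)
  base <- resolve_log_base(base)
  p <- unit_shares(d)
  p <- p[p > 0]
  # + 0 normalizes the IEEE negative zero of the single-category case
  -sum(p * log(p)) / log(base) + 0
}

resolve_log_base <- function(base) {
  if (is.character(base)) {
    base <- switch(match.arg(base, c("2", "e", "10")),
                   "2" = 2, "e" = exp(1), "10" = 10)
  }
  if (!is.numeric(base) || length(base) != 1L || base <= 0 || base == 1) {
    ineq_stop("`base` must be a single number > 0 and != 1 (use 2, exp(1)/\"e\" or 10)",
              "ineq_parameter_error")
  }
  base
}

#' Category counts of a character string
#'
#' Convenience constructor: tabulates the characters of a string into a
#' categorical [unit_distribution()] (one component per distinct letter,
#' its count as units). Mirrors the information-content framing of the
#' Shannon index.
#'
#' @param s a single character string.
#' @return A categorical `unit_dist` with letter labels.
#' @examples
#' count_distribution("AABBCCDD")$units  # 2 2 2 2
#' @export
count_distribution <- function(s) {
  if (!is.character(s) || length(s) != 1L || nchar(s) == 0L) {
    ineq_stop("`s` must be a single non-empty string", "ineq_argument_error")
  }
  tab <- table(strsplit(s, "")[[1]])
  unit_distribution(as.numeric(tab), kind = "categorical",
                    labels = names(tab))
}

#' Generalized entropy index
#'
#' The entropy-model inequality family for metric variables, measuring
#' the redundancy of the unit distribution relative to the uniform one.
#' With x_i = k*p_i = n_i / mean(n), the three branches are
#' \deqn{GE(\alpha) = \frac{1}{k\alpha(\alpha-1)} \sum_i (x_i^\alpha - 1),
#'   \quad \alpha \notin \{0, 1\}}
#' \deqn{GE(1) = \frac{1}{k} \sum_i x_i \ln x_i \quad \textrm{(Theil index)}}
#' \deqn{GE(0) = -\frac{1}{k} \sum_i \ln x_i \quad \textrm{(mean log deviation)}}
#' GE is non-negative and 0 exactly for the uniform distribution. The
#' parameter alpha tunes tail sensitivity: the more positive alpha, the
#' more weight on inequality in the high range of the distribution; the
#' more negative, the more weight on the low range. Branches are selected
#' by exact equality of `alpha` with 0 or 1; the family is continuous in
#' alpha. Zero units are allowed for alpha > 0 (the 0*ln(0) = 0 limit at
#' alpha = 1) but are a domain error for alpha <= 0.
#'
#' @param d a metric [unit_distribution()].
#' @param alpha the tail-sensitivity parameter (any real).
#' @return The index value (>= 0).
#' @seealso [theil()], [mean_log_deviation()], [atkinson_ge_link()]
#' @export
generalized_entropy <- function(d, alpha) {
  d <- as_unit_distribution(d)
  if (missing(alpha) || !is.numeric(alpha) || length(alpha) != 1L || is.na(alpha)) {
    ineq_stop("`alpha` must be a single numeric value", "ineq_parameter_error")
  }
  x <- d$k * unit_shares(d)
  if (alpha <= 0 && any(x == 0)) {
    ineq_stop(
      sprintf("GE(alpha = %g) requires strictly positive units; zero units at component(s) %s",
              alpha, paste(which(x == 0), collapse = ", ")),
      "ineq_domain_error"
    )
  }
  if (alpha == 1) {
    xl <- ifelse(x > 0, x * log(x), 0)
    sum(xl) / d$k
  } else if (alpha == 0) {
    -sum(log(x)) / d$k
  } else {
    sum(x^alpha - 1) / (d$k * alpha * (alpha - 1))
  }
}

#' Theil index
#'
#' The generalized entropy index at alpha = 1, the direct metric-variable
#' generalization of the Shannon index; more sensitive to inequality in
#' the high range of the distribution than the mean log deviation.
#'
#' @inheritParams generalized_entropy
#' @return `generalized_entropy(d, alpha = 1)`.
#' @export
theil <- function(d) generalized_entropy(d, alpha = 1)

#' Mean log deviation
#'
#' The generalized entropy index at alpha = 0: the average deviation of
#' the log units from the log mean.
#'
#' @inheritParams generalized_entropy
#' @return `generalized_entropy(d, alpha = 0)`.
#' @export
mean_log_deviation <- function(d) generalized_entropy(d, alpha = 0)
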