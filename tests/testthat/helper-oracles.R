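# Independent brute-force oracles. Intentionally naive (O(k^2) / O(N^2)
# loops, no shared code with the package) so they re-derive the defining
# quantities from first principles.

oracle_gini_pairwise <- function(units) {
  stopifnot(length(units) <= 100)
  p <- units / sum(units)
  k <- length(p)
  acc <- 0
  for (i in seq_len(k)) {
    for (j in seq_len(k)) {
      acc <- acc + abs(p[i] - p[j])
    }
  }
  acc / (2 * k)
}

oracle_hoover_direct <- function(units) {
  p <- units / sum(units)
  k <- length(p)
  acc <- 0
  for (i in seq_len(k)) acc <- acc + abs(p[i] - 1 / k)
  acc / 2
}

oracle_rosenbluth_rank <- function(units) {
  p <- sort(units / sum(units), decreasing = TRUE)
  acc <- 0
  for (i in seq_along(p)) acc <- acc + i * p[i]
  1 / (2 * acc - 1)
}

# exact same-component probability by enumerating all unordered pairs of
# individually labelled units
oracle_simpson_enumerate <- function(counts) {
  stopifnot(sum(counts) <= 30, all(counts == round(counts)))
  members <- rep(seq_along(counts), counts)
  n <- length(members)
  same <- 0
  total <- 0
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      total <- total + 1
      if (members[i] == members[j]) same <- same + 1
    }
  }
  same / total
}

oracle_area_trapezoid <- function(x, y) {
  acc <- 0
  for (i in seq_len(length(x) - 1)) {
    acc <- acc + (x[i + 1] - x[i]) * (y[i] + y[i + 1]) / 2
  }
  acc
}

oracle_power_mean <- function(units, order) {
  if (order == 0) exp(mean(log(units))) else mean(units^order)^(1 / order)
}

# random positive distribution for property sweeps
rand_units <- function(k, allow_zero = FALSE) {
  u <- stats::rgamma(k, shape = 1.2, rate = 0.5) + 1e-6
  if (allow_zero && k > 2 && stats::runif(1) < 0.3) {
    u[sample(k, 1)] <- 0
  }
  u
}

rand_dist <- function(k, allow_zero = FALSE) {
  unit_distribution(rand_units(k, allow_zero))
}

rand_counts <- function(k, N = 30) {
  as.numeric(stats::rmultinom(1, N, prob = stats::rgamma(k, 1)))
}
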