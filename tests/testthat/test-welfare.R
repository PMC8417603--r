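test_that("Atkinson reproduces its defining contracts", {
  a <- unit_distribution(c(360, 250, 150))
  expect_equal(atkinson(a, 0), 0)
  set.seed(71)
  for (k in c(2, 8, 30)) expect_equal(atkinson(rand_dist(k), 0), 0)

  for (eps in c(0.25, 0.5, 1, 2, 3)) {
    expect_equal(atkinson(unit_distribution(rep(7, 5)), eps), 0,
                 tolerance = 1e-12)
  }

  # epsilon = 1: one minus geometric mean over arithmetic mean
  gm <- prod(c(360, 250, 150))^(1 / 3)
  expect_equal(atkinson(a, 1), 1 - gm / (760 / 3), tolerance = 1e-12)
  expect_equal(atkinson(a, 1), 0.06009148238725026, tolerance = 1e-10)

  expect_error(atkinson(a, -0.5), class = "ineq_domain_error")
  expect_error(atkinson(a), class = "ineq_parameter_error")
})

test_that("Atkinson equals one minus the relative power mean", {
  set.seed(72)
  for (eps in c(0.25, 0.5, 1, 1.5, 2)) {
    for (k in c(3, 9, 25)) {
      d <- rand_dist(k)
      expect_equal(atkinson(d, eps),
                   1 - oracle_power_mean(d$units, 1 - eps) / d$mean_units,
                   tolerance = 1e-12)
    }
  }
})

test_that("Atkinson zero-unit limits and range", {
  z <- unit_distribution(c(5, 0, 3))
  expect_equal(atkinson(z, 1), 1)
  expect_equal(atkinson(z, 2), 1)
  ai_half <- atkinson(z, 0.5)
  expect_true(ai_half > 0 && ai_half < 1)

  set.seed(73)
  for (i in 1:40) {
    d <- rand_dist(sample(2:50, 1), allow_zero = TRUE)
    for (eps in c(0.25, 0.5, 1, 1.5, 2, 3)) {
      ai <- atkinson(d, eps)
      expect_gte(ai, 0)
      expect_lte(ai, 1)
    }
  }
})

test_that("Atkinson increases with epsilon on non-uniform data and is scale invariant", {
  set.seed(74)
  grid <- c(0.25, 0.5, 1, 1.5, 2, 3)
  for (k in c(3, 10, 25)) {
    d <- rand_dist(k)
    vals <- sapply(grid, function(e) atkinson(d, e))
    expect_true(all(diff(vals) > 0))
    c_ <- stats::runif(1, 0.1, 10)
    for (e in grid) {
      expect_equal(atkinson(unit_distribution(c_ * d$units), e),
                   atkinson(d, e), tolerance = 1e-10)
    }
  }
})

test_that("the equally-distributed-equivalent standard follows n_eps = mean*(1-AI)", {
  a <- unit_distribution(c(360, 250, 150))
  expect_equal(ede_standard(a, 0), a$mean_units)
  expect_equal(ede_standard(a, 1), prod(c(360, 250, 150))^(1 / 3),
               tolerance = 1e-9)
  # an AI of 0.4 means the standard needs only 60% of the total unit sum:
  # k * n_eps / N = 1 - AI for any distribution and epsilon
  set.seed(75)
  for (i in 1:10) {
    d <- rand_dist(sample(3:20, 1))
    eps <- stats::runif(1, 0.2, 3)
    frac_needed <- d$k * ede_standard(d, eps) / d$N
    expect_equal(frac_needed, 1 - atkinson(d, eps), tolerance = 1e-12)
  }
})

test_that("epsilon_for_standard inverts the standard uniquely", {
  a <- unit_distribution(c(360, 250, 150))
  expect_equal(epsilon_for_standard(a, a$mean_units), 0)
  expect_equal(epsilon_for_standard(a, ede_standard(a, 1)), 1,
               tolerance = 1e-5)

  set.seed(76)
  for (i in 1:10) {
    d <- rand_dist(sample(3:15, 1))
    eps <- stats::runif(1, 0.1, 4)
    t <- ede_standard(d, eps)
    expect_equal(ede_standard(d, epsilon_for_standard(d, t)), t,
                 tolerance = 1e-6 * d$mean_units)
  }

  expect_error(epsilon_for_standard(a, a$mean_units * 1.01),
               class = "ineq_range_error")
  expect_error(epsilon_for_standard(a, min(a$units) * 0.5),
               class = "ineq_range_error")
  expect_error(epsilon_for_standard(a, min(a$units) * 0.5), "ranges over")
})

test_that("the GE link converts and cross-checks on every branch", {
  a <- unit_distribution(c(360, 250, 150))
  expect_equal(atkinson_ge_link(0, 2), 0)
  expect_equal(atkinson_ge_link(theil(a), 0), 0)  # eps = 0 always 0

  # eps = 1 pairs with the mean log deviation (alpha = 1 - eps = 0)
  expect_equal(atkinson_ge_link(mean_log_deviation(a), 1, d = a),
               atkinson(a, 1), tolerance = 1e-10)
  expect_equal(atkinson_ge_link(0, 1), 0)

  set.seed(77)
  for (eps in c(0.25, 0.5, 1, 1.5, 2, 3)) {
    for (k in c(3, 12)) {
      d <- rand_dist(k)
      ge <- generalized_entropy(d, 1 - eps)
      expect_equal(atkinson_ge_link(ge, eps, d = d), atkinson(d, eps),
                   tolerance = 1e-10)
    }
  }

  # feeding a GE value computed at the wrong alpha trips the consistency check
  expect_error(atkinson_ge_link(theil(a), 1, d = a),
               class = "ineq_consistency_error")
  expect_error(atkinson_ge_link(-0.1, 1), class = "ineq_domain_error")
})
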