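test_that("the catalog holds exactly the sixteen measures with their metadata", {
  cat_df <- measure_catalog()
  expect_equal(nrow(cat_df), 16)
  expect_setequal(
    cat_df$id,
    c("gini", "gini_corrected", "hoover", "hoover_corrected", "rosenbluth",
      "hhi", "simpson", "gini_simpson", "inverse_simpson", "shannon",
      "generalized_entropy", "atkinson", "palma", "s80_s20", "p90_p10",
      "p50_p10")
  )
  expect_setequal(unique(cat_df$model),
                  c("deviations", "combinatorics", "entropy",
                    "social welfare", "tail ratio"))
  eq <- cat_df$id[cat_df$polarity == "equality"]
  expect_setequal(eq, c("gini_simpson", "inverse_simpson", "shannon"))
  expect_true(grepl("Robin-Hood", cat_df$synonyms[cat_df$id == "hoover"]))
})

test_that("limits instantiate correctly at a given k", {
  expect_equal(measure_limits("gini", 3), c(lower = 0, upper = 1 - 1 / 3))
  expect_equal(measure_limits("rosenbluth", 5), c(lower = 0.2, upper = 1))
  expect_equal(measure_limits("hhi", 5, k_nonnull = 2),
               c(lower = 0.5, upper = 1))
  expect_equal(measure_limits("shannon", 8, k_nonnull = 4),
               c(lower = 0, upper = 2))
  expect_equal(measure_limits("palma", 10), c(lower = 0.25, upper = Inf))
  expect_error(measure_limits("nope", 3), class = "ineq_parameter_error")
})

test_that("measures_report computes requested rows with limits and values", {
  a <- unit_distribution(c(360, 250, 150))
  rep_tab <- measures_report(a, c("gini", "hoover", "rosenbluth", "hhi"))
  expect_s3_class(rep_tab, "ineq_report")
  expect_equal(rep_tab$value,
               c(0.184210526315789, 0.140350877192982,
                 0.408602150537634, 0.371537396121884),
               tolerance = 1e-12)
  g <- rep_tab[rep_tab$measure == "gini", ]
  expect_equal(c(g$lower, g$upper), c(0, 2 / 3), tolerance = 1e-12)
  expect_output(print(rep_tab), "0.18421")
})

test_that("report rows stay within their own limits on varied data", {
  set.seed(91)
  for (i in 1:10) {
    d <- generate_distribution("integer_counts", k = sample(3:15, 1),
                               N = 200, seed = i)
    rep_tab <- suppressWarnings(measures_report(d, alpha = 1, epsilon = 1))
    ok <- !is.na(rep_tab$value)
    expect_true(all(rep_tab$value[ok] >= rep_tab$lower[ok] - 1e-10))
    expect_true(all(rep_tab$value[ok] <= rep_tab$upper[ok] + 1e-10))
  }
})

test_that("uniform singleton data pins inequality rows at lower and equality rows at upper limits", {
  # one unit per component: every measure sits at its equality extreme,
  # including the without-replacement Simpson family (which needs all
  # units in distinct components, not just equal counts, to reach 0)
  u <- unit_distribution(rep(1, 25), kind = "categorical")
  rep_tab <- suppressWarnings(
    suppressMessages(measures_report(u, alpha = 1, epsilon = 1))
  )
  for (i in seq_len(nrow(rep_tab))) {
    row <- rep_tab[i, ]
    if (is.na(row$value)) next
    if (row$polarity == "inequality") {
      expect_equal(row$value, row$lower, tolerance = 1e-10,
                   label = row$measure)
    } else {
      expect_equal(row$value, row$upper, tolerance = 1e-10,
                   label = row$measure)
    }
  }
})

test_that("parameterized measures demand parameters; inapplicable rows degrade gracefully", {
  a <- unit_distribution(c(360, 250, 150))
  expect_error(measures_report(a, "generalized_entropy"),
               class = "ineq_parameter_error")
  expect_error(measures_report(a, "atkinson"),
               class = "ineq_parameter_error")
  expect_error(measures_report(a, "not_a_measure"),
               class = "ineq_parameter_error")

  # Simpson on non-integer values: NA value, note set, other rows intact
  m <- unit_distribution(c(1.5, 2.5, 3.5))
  rep_tab <- suppressWarnings(measures_report(m, c("gini", "simpson")))
  expect_false(is.na(rep_tab$value[rep_tab$measure == "gini"]))
  expect_true(is.na(rep_tab$value[rep_tab$measure == "simpson"]))
  expect_match(rep_tab$note[rep_tab$measure == "simpson"], "integer")
  expect_output(print(rep_tab), "Notes:")

  # defaults: parameterized measures are included only with parameters
  no_par <- suppressWarnings(measures_report(m))
  expect_false(any(c("generalized_entropy", "atkinson") %in% no_par$measure))
  with_par <- suppressWarnings(measures_report(m, alpha = 2, epsilon = 1))
  expect_true(all(c("generalized_entropy", "atkinson") %in% with_par$measure))
})
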