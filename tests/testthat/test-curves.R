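test_that("Lorenz curve vertices follow the ascending-cumulative definition", {
  eq <- lorenz_curve(unit_distribution(rep(1, 4)))
  expect_equal(eq$x, eq$y)  # line of equality

  pm <- lorenz_curve(unit_distribution(c(100, 0, 0)))
  expect_equal(pm$x, c(0, 1 / 3, 2 / 3, 1))
  expect_equal(pm$y, c(0, 0, 0, 1))

  a <- lorenz_curve(unit_distribution(c(360, 250, 150)))
  expect_equal(a$y, c(0, 150, 400, 760) / 760)
  expect_equal(a$x, (0:3) / 3)
})

test_that("concentration curve uses descending ranks on a 0..k x-axis", {
  eq <- concentration_curve(unit_distribution(rep(1, 5)))
  expect_equal(eq$x, 0:5)
  expect_equal(eq$y, (0:5) / 5)

  pm <- concentration_curve(unit_distribution(c(100, 0, 0, 0, 0)))
  expect_equal(pm$y, c(0, 1, 1, 1, 1, 1))

  a <- concentration_curve(unit_distribution(c(360, 250, 150)))
  expect_equal(a$y, c(0, 360, 610, 760) / 760)
})

test_that("curve invariants hold on random distributions", {
  set.seed(31)
  for (k in c(2, 3, 7, 20, 50)) {
    d <- rand_dist(k, allow_zero = TRUE)
    lc <- lorenz_curve(d)
    expect_true(all(lc$y <= lc$x + 1e-12))
    expect_true(all(diff(lc$x) >= 0) && all(diff(lc$y) >= -1e-15))
    cc <- concentration_curve(d)
    expect_true(all(cc$y >= cc$x / k - 1e-12))
    expect_equal(cc$y[k + 1], 1, tolerance = 1e-12)
  }
})

test_that("gap area matches the trapezoid oracle and the extreme cases", {
  expect_equal(lorenz_gap_area(lorenz_curve(unit_distribution(rep(3, 6)))), 0)

  a <- lorenz_curve(unit_distribution(c(360, 250, 150)))
  expect_equal(lorenz_gap_area(a), 0.5 - oracle_area_trapezoid(a$x, a$y))
  expect_equal(lorenz_gap_area(a), 0.0921052631578947, tolerance = 1e-12)

  # one component holding everything: A -> 0.5 as k grows
  big <- lorenz_gap_area(lorenz_curve(unit_distribution(c(1, rep(0, 999)))))
  expect_gt(big, 0.499)
  expect_lt(big, 0.5)
})

test_that("max vertical gap equals the Hoover deviations form", {
  expect_equal(max_vertical_gap(lorenz_curve(unit_distribution(rep(2, 5)))), 0)

  a <- lorenz_curve(unit_distribution(c(360, 250, 150)))
  expect_equal(max_vertical_gap(a), 2 / 3 - 400 / 760, tolerance = 1e-12)

  two <- lorenz_curve(unit_distribution(c(100, 0)))
  expect_equal(max_vertical_gap(two), 0.5)

  set.seed(32)
  for (k in c(2, 5, 13, 40)) {
    d <- rand_dist(k, allow_zero = TRUE)
    expect_equal(max_vertical_gap(lorenz_curve(d)), oracle_hoover_direct(d$units),
                 tolerance = 1e-12)
  }
})

test_that("area above the concentration curve anchors the Rosenbluth extremes", {
  for (k in c(2, 5, 9)) {
    pm <- concentration_curve(unit_distribution(c(50, rep(0, k - 1))))
    expect_equal(concentration_area_above(pm), 0.5)
    eq <- concentration_curve(unit_distribution(rep(7, k)))
    expect_equal(concentration_area_above(eq), k / 2)
  }
  a <- concentration_curve(unit_distribution(c(360, 250, 150)))
  expect_equal(concentration_area_above(a),
               3 - oracle_area_trapezoid(a$x, a$y), tolerance = 1e-12)
  expect_equal(1 / (2 * concentration_area_above(a)), 0.408602150537634,
               tolerance = 1e-10)
})

test_that("area functions refuse the wrong curve kind", {
  d <- unit_distribution(c(3, 2, 1))
  expect_error(lorenz_gap_area(concentration_curve(d)),
               class = "ineq_argument_error")
  expect_error(max_vertical_gap(concentration_curve(d)),
               class = "ineq_argument_error")
  expect_error(concentration_area_above(lorenz_curve(d)),
               class = "ineq_argument_error")
  expect_error(lorenz_gap_area(list(x = 1, y = 1)),
               class = "ineq_argument_error")
})

test_that("Lorenz curve is invariant under component replication", {
  set.seed(33)
  for (m in 2:3) {
    u <- rand_units(6)
    lc1 <- lorenz_curve(unit_distribution(u))
    lc2 <- lorenz_curve(unit_distribution(rep(u / m, each = m)))
    # same polyline: vertices of the original are a subset, areas identical
    expect_equal(lorenz_gap_area(lc1), lorenz_gap_area(lc2), tolerance = 1e-12)
    expect_equal(stats::approx(lc2$x, lc2$y, xout = lc1$x)$y, lc1$y,
                 tolerance = 1e-12)
  }
})

test_that("curve coordinate and plot interfaces work", {
  d <- unit_distribution(c(5, 3, 2))
  cdf <- as.data.frame(lorenz_curve(d))
  expect_named(cdf, c("x", "y"))
  expect_equal(nrow(cdf), 4)
  expect_output(print(lorenz_curve(d)), "lorenz curve")
  f <- tempfile(fileext = ".png")
  grDevices::png(f)
  expect_invisible(plot(lorenz_curve(d)))
  plot(d)
  grDevices::dev.off()
  expect_true(file.exists(f))
  unlink(f)
})
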