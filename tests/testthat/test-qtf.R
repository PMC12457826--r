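# Quantile-threshold discretization: KDE fit, CDF, threshold solving,
# discretization rule, ANOVA validation, and baseline binning methods.

test_that("default bandwidth follows the 0.9 * min(sd, IQR/1.34) * n^(-1/5) rule", {
  set.seed(11)
  x <- rnorm(100)
  model <- fit_kde(x)
  h_ref <- 0.9 * min(sd(x), IQR(x) / 1.34) * length(x)^(-1/5)
  expect_equal(model$bandwidth, h_ref, tolerance = 1e-10)
  # order of magnitude from the hand evaluation at sd ~ IQR/1.34 ~ 1
  expect_lt(abs(model$bandwidth - 0.9 * 100^(-1/5)), 0.12)
  expect_error(fit_kde(rep(2, 50), name = "flat"), "flat")
  expect_error(fit_kde(3), ">= 2")
  # explicit bandwidth lets a degenerate column through: one Gaussian bump
  m1 <- fit_kde(rep(1.5, 10), bandwidth = 1)
  expect_equal(kde_pdf(m1, 1.5), dnorm(0), tolerance = 1e-12)
  expect_equal(kde_cdf(m1, 1.5), 0.5, tolerance = 1e-12)
})

test_that("KDE density matches the standard normal on a large sample and integrates to 1", {
  set.seed(21)
  x <- rnorm(20000)
  model <- fit_kde(x)
  expect_lt(abs(kde_pdf(model, 0) - dnorm(0)), 0.02)
  grid <- seq(-6, 6, length.out = 2001)
  expect_equal(sum(kde_pdf(model, grid)) * diff(grid[1:2]), 1, tolerance = 1e-3)
})

test_that("kde_cdf is monotone with limits 0/1 and agrees with trapezoid integration of the density", {
  set.seed(31)
  x <- c(rnorm(150), rexp(50))
  model <- fit_kde(x)
  expect_equal(kde_cdf(model, -1e6), 0, tolerance = 1e-12)
  expect_equal(kde_cdf(model, 1e6), 1, tolerance = 1e-12)
  pts <- sort(runif(50, -3, 4))
  expect_true(all(diff(kde_cdf(model, pts)) >= 0))
  # oracle: trapezoid integration of the mixture density on a fine grid
  lo <- min(x) - 10 * model$bandwidth
  grid <- seq(lo, 3.2, length.out = 40001)
  dens <- kde_pdf(model, grid)
  dx <- diff(grid[1:2])
  trap <- cumsum((dens[-1] + dens[-length(dens)]) / 2) * dx
  idx <- c(10000, 20000, 35000)
  expect_equal(kde_cdf(model, grid[idx + 1]), trap[idx], tolerance = 1e-6)
})

test_that("solved thresholds sit at the target CDF fractions", {
  set.seed(41)
  model <- solve_thresholds(fit_kde(rnorm(50000)))
  expect_equal(model$target_fractions, c(0.5, 0.75))
  expect_equal(kde_cdf(model, model$thresholds[1]), 0.5, tolerance = 1e-8)
  expect_equal(kde_cdf(model, model$thresholds[2]), 0.75, tolerance = 1e-8)
  # large-sample normal quantiles: 0 and 0.674
  expect_lt(abs(model$thresholds[1] - 0), 0.03)
  expect_lt(abs(model$thresholds[2] - qnorm(0.75)), 0.03)

  u <- solve_thresholds(fit_kde(runif(50000)))
  expect_lt(abs(u$thresholds[1] - 0.5), 0.02)
  expect_lt(abs(u$thresholds[2] - 0.75), 0.02)

  # generalized (n, i): four thresholds at j/6, j = 1..4
  g <- solve_thresholds(fit_kde(rnorm(20000)), n = 4, i = 1)
  expect_equal(kde_cdf(model = g, g$thresholds), (1:4) / 6, tolerance = 1e-8)
  expect_error(solve_thresholds(fit_kde(rnorm(100)), n = 2, i = 3), "i")
})

test_that("discretize applies the boundary rule x <= Q -> lower level and is monotone", {
  col <- discretize(c(-1, 0.5, 2), c(0, 1))
  expect_equal(col$levels, c(0L, 1L, 2L))
  # boundary values belong to the lower level
  expect_equal(discretize(c(0, 1), c(0, 1))$levels, c(0L, 1L))
  set.seed(51)
  x <- sort(rnorm(200))
  lev <- discretize(x, c(-0.5, 0.9))$levels
  expect_true(all(diff(lev) >= 0))
  expect_equal(sum(level_proportions(discretize(x, c(-0.5, 0.9)))), 1)
})

test_that("qtf occupancies approach (0.5, 0.25, 0.25) on continuous data", {
  set.seed(61)
  col <- qtf_discretize(rexp(40000), "e")
  p <- level_proportions(col)
  expect_equal(unname(p), c(0.5, 0.25, 0.25), tolerance = 0.02)
})

test_that("coincident thresholds on extreme point masses collapse with a warning", {
  set.seed(71)
  x <- c(rep(0, 5000), rnorm(50, 10))  # ~99% point mass
  # at a near-degenerate bandwidth both targets fall inside the spike and
  # the solved cut points coincide to within 1e-12
  expect_warning(col <- qtf_discretize(x, "spike", bandwidth = 1e-12),
                 "collapsed")
  expect_lt(col$n_levels, 3L)
  expect_equal(sum(level_proportions(col)), 1)
})

test_that("anova_validate reproduces the hand-computed one-way F and flags degenerate groupings", {
  # groups {0,1}, {1,2}, {2,3}: MSB = 2, MSW = 0.5 -> F = 4 with df (2, 3)
  vals <- c(0, 1, 1, 2, 2, 3)
  col <- ordinal_column(c(0, 0, 1, 1, 2, 2), 3)
  a <- anova_validate(vals, col)
  expect_equal(a$F, 4, tolerance = 1e-12)
  expect_equal(a$df, c(2, 3))
  expect_equal(a$p, pf(4, 2, 3, lower.tail = FALSE), tolerance = 1e-12)
  expect_equal(a$group_means, c(0.5, 1.5, 2.5))
  expect_equal(a$group_ns, c(2L, 2L, 2L))
  # identical group values: zero between-group variance
  z <- anova_validate(c(1, 2, 3, 1, 2, 3),
                      ordinal_column(c(0, 0, 0, 1, 1, 1), 2))
  expect_equal(z$F, 0, tolerance = 1e-12)
  expect_error(anova_validate(vals, ordinal_column(rep(0, 6), 1)),
               "degenerate")
})

test_that("equal-width bins have identical widths and error on zero range", {
  col <- equal_width_discretize(0:9, 3)
  expect_equal(diff(c(0, col$meta$thresholds, 9)), rep(3, 3))
  expect_error(equal_width_discretize(rep(1, 10), 3), "zero range")
  set.seed(81)
  p <- level_proportions(equal_width_discretize(runif(30000), 4))
  expect_equal(unname(p), rep(0.25, 4), tolerance = 0.02)
})

test_that("equal-frequency bins balance occupancy and warn on heavy ties", {
  x <- seq_len(300)
  p <- level_proportions(equal_frequency_discretize(x, 3))
  expect_equal(unname(p) * 300, c(100, 100, 100))
  tied <- c(rep(0, 250), 1:50)
  expect_warning(col <- equal_frequency_discretize(tied, 3), "ties")
  expect_equal(sum(level_proportions(col)), 1)
  # identical values never split across bins
  expect_equal(length(unique(col$levels[tied == 0])), 1L)
})

test_that("k-means discretization is ordinal, seed-deterministic, and exact on separated masses", {
  x <- c(rnorm(50, 0, 0.01), rnorm(50, 10, 0.01), rnorm(50, 20, 0.01))
  col <- kmeans_discretize(x, 3, seed = 2)
  expect_equal(col$levels, rep(0:2, each = 50))
  expect_true(all(diff(col$meta$centers) > 0))
  col2 <- kmeans_discretize(x, 3, seed = 2)
  expect_identical(col$levels, col2$levels)
  expect_error(kmeans_discretize(rep(1, 5), 3), "distinct")
})
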