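test_that("growth_rate implements the Gaussian thermal response", {
  p <- growth_params("x", r_max = 1, mu = 25, sigma = 1)
  expect_equal(growth_rate(p, 25), 1 / sqrt(2 * pi))
  # frozen from an independent evaluation: 2 * dnorm(24, 20, 4)
  p2 <- growth_params("x", r_max = 2, mu = 20, sigma = 4)
  expect_equal(growth_rate(p2, 24), 0.120985362259572, tolerance = 1e-12)
  # peak form drops the density normalization
  expect_equal(growth_rate(p2, 20, response = "peak"), 2)
  expect_error(growth_rate(p, Inf), "finite")
  expect_error(growth_rate(p, NA_real_), "finite")
})

test_that("growth_rate is symmetric about mu and positive", {
  set.seed(7)
  for (i in 1:20) {
    p <- growth_params("x", r_max = runif(1, 0.1, 3), mu = runif(1, 10, 35),
                       sigma = runif(1, 0.5, 8))
    d <- runif(1, 0, 15)
    expect_equal(growth_rate(p, p$mu + d), growth_rate(p, p$mu - d))
    expect_gt(growth_rate(p, p$mu + d), 0)
    expect_lte(growth_rate(p, p$mu + d), growth_rate(p, p$mu))
  }
})

test_that("the thermal response integrates to r_max over all temperatures", {
  set.seed(11)
  for (i in 1:10) {
    p <- growth_params("x", r_max = runif(1, 0.1, 3), mu = runif(1, 10, 35),
                       sigma = runif(1, 0.5, 8))
    q <- integrate(function(T) growth_rate(p, T), -Inf, Inf,
                   rel.tol = 1e-10)$value
    expect_equal(q, p$r_max, tolerance = 1e-6)
  }
})

test_that("temperature_at evaluates the sinusoidal forcing", {
  # constant profile: always M
  expect_equal(temperature_at(temperature_profile(18, 0), 123.4), 18)
  # sine maximum: M + A at a quarter period past theta = 0
  inner <- temperature_profile(24, 7, theta = 0)
  expect_equal(temperature_at(inner, 365 / 4), 31)
  # time average over a period equals M (quadrature)
  gt <- temperature_profile(21, 6)
  avg <- integrate(function(t) temperature_at(gt, t), 0, 365,
                   rel.tol = 1e-12)$value / 365
  expect_equal(avg, 21, tolerance = 1e-9)
  # max - min over one period is 2A
  tgrid <- temperature_at(gt, seq(0, 365, length.out = 100001))
  expect_equal(max(tgrid) - min(tgrid), 12, tolerance = 1e-6)
  # period 2*pi/omega
  expect_equal(temperature_at(gt, 17), temperature_at(gt, 17 + 365))
})

test_that("phase convention places the annual minimum on day_of_min", {
  p <- temperature_profile(20, 5, day_of_min = 45)
  tgrid <- seq(0, 365, by = 0.01)
  expect_equal(tgrid[which.min(temperature_at(p, tgrid))], 45,
               tolerance = 0.02)
  p2 <- temperature_profile(20, 5, theta = 0)  # explicit theta wins
  expect_equal(p2$theta, 0)
})

test_that("sml_rhs matches the coupled logistic form", {
  g <- growth_params(c("a", "b", "c"), r_max = c(1, 2, 1.5),
                     mu = c(20, 24, 28), sigma = c(3, 4, 5))
  eta <- matrix(0, 3, 3)
  prof <- temperature_profile(24, 0)
  # zero state and full capacity both annihilate the derivative
  expect_equal(sml_rhs(0, c(0, 0, 0), g, eta, prof, k = 100), c(0, 0, 0))
  expect_equal(sml_rhs(0, c(50, 30, 20), g, eta, prof, k = 100), c(0, 0, 0))
  # scalar logistic oracle, N = 1
  g1 <- growth_params("a", r_max = 1, mu = 24, sigma = 3)
  R <- growth_rate(g1, 24)
  for (B in c(10, 50, 90))
    expect_equal(sml_rhs(0, B, g1, matrix(0, 1, 1), prof, k = 100),
                 R * B * (1 - B / 100))
  # interaction term raises growth for positive eta
  eta2 <- matrix(c(0, 0.5, 0.5, 0), 2, 2)
  g2 <- growth_params(c("a", "b"), r_max = c(1, 1), mu = c(24, 24),
                      sigma = c(3, 3))
  d0 <- sml_rhs(0, c(10, 10), g2, matrix(0, 2, 2), prof, k = 100)
  d1 <- sml_rhs(0, c(10, 10), g2, eta2, prof, k = 100)
  expect_equal(d1, d0 * (1 + 0.5 * 10))
  expect_error(sml_rhs(0, c(1, 2), g1, matrix(0, 1, 1), prof, k = 100),
               "taxa")
  expect_error(sml_rhs(0, 1, g1, matrix(0, 2, 2), prof, k = 100), "matrix")
})

test_that("integration matches the closed-form logistic", {
  g <- growth_params("x", r_max = 5, mu = 24, sigma = 3)
  prof <- temperature_profile(24, 0)
  R <- growth_rate(g, 24)
  tr <- sml_integrate(g, matrix(0, 1, 1), prof, init = 10, k = 100,
                      times = seq(0, 40, by = 0.5))
  expect_equal(tr$states[, 1], oracle_logistic(tr$times, 10, R, 100),
               tolerance = 1e-6)
})

test_that("integration respects trivial invariants", {
  g2 <- growth_params(c("a", "b"), r_max = c(1, 1), mu = c(24, 24),
                      sigma = c(3, 3))
  prof <- temperature_profile(22, 5)
  eta <- matrix(c(0, 0.002, 0.002, 0), 2, 2)
  # all-zero initial state stays zero
  tr0 <- sml_integrate(g2, eta, prof, init = c(0, 0), k = 100,
                       times = c(0, 10, 50))
  expect_true(all(tr0$states == 0))
  # exchange symmetry: identical taxa with symmetric coupling stay identical
  tr <- sml_integrate(g2, eta, prof, init = c(5, 5), k = 100,
                      times = seq(0, 200, by = 10))
  expect_equal(tr$states[, 1], tr$states[, 2], tolerance = 1e-10)
  expect_true(all(tr$states >= 0))
})

test_that("totals follow a single logistic when taxa are interchangeable", {
  # equal R, eta = 0, constant T: the total obeys scalar logistic to k
  g <- growth_params(c("a", "b", "c"), r_max = c(2, 2, 2), mu = c(24, 24, 24),
                     sigma = c(3, 3, 3))
  prof <- temperature_profile(24, 0)
  R <- growth_rate(g[1, ], 24)
  tr <- sml_integrate(g, matrix(0, 3, 3), prof, init = c(2, 5, 13), k = 100,
                      times = seq(0, 60, by = 1))
  expect_equal(rowSums(tr$states), oracle_logistic(tr$times, 20, R, 100),
               tolerance = 1e-6)
})

test_that("integration is invariant under output-time refinement", {
  g <- growth_params(c("a", "b"), r_max = c(1.5, 0.9), mu = c(22, 26),
                     sigma = c(4, 3))
  prof <- temperature_profile(23, 6)
  eta <- matrix(c(0, 0.004, 0.004, 0), 2, 2)
  coarse <- sml_integrate(g, eta, prof, init = c(10, 10), k = 100,
                          times = seq(0, 100, by = 20))
  fine <- sml_integrate(g, eta, prof, init = c(10, 10), k = 100,
                        times = seq(0, 100, by = 1))
  expect_equal(coarse$states[coarse$times %in% fine$times, ],
               fine$states[fine$times %in% coarse$times, ],
               tolerance = 1e-7)
})

test_that("relative_abundances normalizes to percentages", {
  g <- growth_params(c("a", "b", "c"), r_max = c(1, 1, 1), mu = c(24, 24, 24),
                     sigma = c(3, 3, 3))
  prof <- temperature_profile(24, 0)
  tr <- sml_integrate(g, matrix(0, 3, 3), prof, init = c(25, 25, 50), k = 1e6,
                      times = c(0, 1))
  expect_equal(unname(relative_abundances(tr, 0)), c(25, 25, 50))
  expect_equal(sum(relative_abundances(tr, 0.5)), 100)
  tr1 <- sml_integrate(g, matrix(0, 3, 3), prof, init = c(1, 0, 0), k = 100,
                       times = c(0, 1))
  expect_equal(unname(relative_abundances(tr1, 0)), c(100, 0, 0))
  tr0 <- sml_integrate(g, matrix(0, 3, 3), prof, init = c(0, 0, 0), k = 100,
                       times = c(0, 1))
  expect_error(relative_abundances(tr0, 1), "extinct")
  expect_error(relative_abundances(tr, 99), "range")
})

test_that("trajectory CSV export is tidy and re-readable", {
  g <- growth_params(c("a", "b"), r_max = c(1, 1), mu = c(24, 24),
                     sigma = c(3, 3))
  tr <- sml_integrate(g, matrix(0, 2, 2), temperature_profile(24, 0),
                      init = c(10, 20), k = 100, times = 0:5)
  path <- withr::local_tempfile(fileext = ".csv")
  write_trajectory(tr, path)
  df <- read.csv(path)
  expect_named(df, c("time_days", "taxon", "abundance",
                     "relative_abundance_pct"))
  expect_equal(nrow(df), 12)
  expect_equal(df$abundance[df$taxon == "a" & df$time_days == 0], 10)
})
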