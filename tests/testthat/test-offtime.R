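test_that("power-law density matches its closed form and normalizes", {
  d3 <- off_time_dist(beta = 3, tau_min = 1)
  expect_equal(dofftime(1.0, d3), 2.0)
  expect_equal(dofftime(0.5, d3), 0.0)
  expect_equal(dofftime(2.0, d3), 2 * 2^-3)

  for (b in c(1.5, 2, 3, 10)) {
    d <- off_time_dist(beta = b, tau_min = 1)
    z <- stats::integrate(dofftime, 1, Inf, dist = d, rel.tol = 1e-10)
    expect_equal(z$value, 1, tolerance = 1e-8)
  }
})

test_that("cumulative distribution is the analytic integral of the density", {
  d <- off_time_dist(beta = 3, tau_min = 1)
  expect_equal(pofftime(2, d), 0.75)
  expect_equal(pofftime(1, d), 0)       # lower support edge
  expect_equal(pofftime(0.2, d), 0)
  d2 <- off_time_dist(beta = 2, tau_min = 1)
  expect_equal(pofftime(1e6, d2), 1 - 1e-6)
  # monotone nondecreasing, limit 1
  q <- pofftime(c(1, 2, 5, 50, 1e8), d)
  expect_true(all(diff(q) >= 0))
  expect_lt(abs(q[5] - 1), 1e-15)
  # quantile function inverts it
  p <- c(0.1, 0.5, 0.9, 0.999)
  expect_equal(pofftime(qofftime(p, d), d), p, tolerance = 1e-12)
})

test_that("invalid distribution parameters are rejected", {
  expect_error(off_time_dist(beta = 1, tau_min = 1), "normalizable")
  expect_error(off_time_dist(beta = 0.5, tau_min = 1), "normalizable")
  expect_error(off_time_dist(beta = 3, tau_min = 0), "tau_min")
  expect_error(off_time_dist(beta = 3, tau_min = -2), "tau_min")
})

test_that("inverse-transform sampler follows the analytic law", {
  # closed-form inverse: u = 0.25, beta = 2 -> tau = 4
  d2 <- off_time_dist(beta = 2, tau_min = 1)
  expect_equal(qofftime(0.75, d2), 4.0)

  for (b in c(1.5, 3, 10)) {
    d <- off_time_dist(beta = b, tau_min = 1)
    set.seed(101)
    x <- rofftime(1e5, d)
    expect_true(all(x >= 1))
    ks <- suppressWarnings(stats::ks.test(x, function(q) pofftime(q, d)))
    expect_lt(unname(ks$statistic), 0.01)
  }
  # reproducible under a fixed seed
  set.seed(7); a <- rofftime(10, d2)
  set.seed(7); b <- rofftime(10, d2)
  expect_identical(a, b)
})

test_that("tail heaviness decreases with the glass coefficient", {
  q99 <- vapply(c(1.5, 3, 10), function(b) {
    set.seed(42)
    stats::quantile(rofftime(1e5, off_time_dist(beta = b)), 0.99)
  }, numeric(1))
  expect_true(all(diff(q99) < 0))

  # large beta collapses onto tau_min (conventional-model limit)
  set.seed(42)
  x <- rofftime(1e5, off_time_dist(beta = 200))
  expect_gte(mean(x <= 1.05), 0.999)
})

test_that("constant mode is an exact point mass, not a large-beta proxy", {
  d <- off_time_dist(tau_min = 2.5, mode = "constant")
  expect_identical(rofftime(100, d), rep(2.5, 100))
  expect_equal(pofftime(c(1, 2.5, 10), d), c(0, 1, 1))
  m <- offtime_moments(d, 2L)
  expect_true(m$finite)
  expect_equal(m$value, 0)
})

test_that("moments carry divergence flags in the glassy regime", {
  d3 <- off_time_dist(beta = 3, tau_min = 1)
  m1 <- offtime_moments(d3, 1L)
  expect_true(m1$finite)
  expect_equal(m1$value, 2.0)
  m2 <- offtime_moments(d3, 2L)      # infinite variance at beta <= 3
  expect_false(m2$finite)
  expect_true(is.na(m2$value))
  expect_false(offtime_moments(off_time_dist(beta = 1.8), 1L)$finite)

  # beta = 4: variance against numeric quadrature
  d4 <- off_time_dist(beta = 4, tau_min = 1)
  mean4 <- stats::integrate(function(x) x * dofftime(x, d4), 1, Inf,
                            rel.tol = 1e-10)$value
  raw2 <- stats::integrate(function(x) x^2 * dofftime(x, d4), 1, Inf,
                           rel.tol = 1e-10)$value
  v <- offtime_moments(d4, 2L)
  expect_true(v$finite)
  expect_equal(v$value, raw2 - mean4^2, tolerance = 1e-6)

  expect_error(offtime_moments(d4, 3L), "order")
})

test_that("optional truncation renormalizes the law", {
  d <- off_time_dist(beta = 1.5, tau_min = 1, tau_max = 100)
  z <- stats::integrate(dofftime, 1, 100, dist = d, rel.tol = 1e-10)
  expect_equal(z$value, 1, tolerance = 1e-8)
  set.seed(3)
  x <- rofftime(1e4, d)
  expect_true(all(x <= 100))
  expect_true(offtime_moments(d, 2L)$finite)
})
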