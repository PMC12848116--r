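test_that("cells without force generation do not move", {
  # no motors: no retrograde flow, no tension, no migration
  p0 <- quick_params(n_motors = 0, duration = 200)
  tr <- simulate_cell(p0, seed = 1)
  expect_true(all(tr$x == 0) && all(tr$y == 0))
  # no clutches ever bind: no traction, no migration
  p1 <- quick_params(r_on = 0, duration = 200)
  tr1 <- simulate_cell(p1, seed = 1)
  expect_true(all(tr1$x == 0) && all(tr1$y == 0))
})

test_that("identical parameters and seed reproduce trajectories bit for bit", {
  p <- quick_params(duration = 500)
  a <- simulate_ensemble(p, 3, seed = 11)
  b <- simulate_ensemble(p, 3, seed = 11)
  expect_identical(as.data.frame(a), as.data.frame(b))
  # a single-cell call equals the first child stream of the ensemble
  one <- simulate_cell(p, seed = 11)
  expect_identical(one$x, a$x[a$cell == 1])
  # a different seed gives different paths
  expect_false(identical(a$x, simulate_ensemble(p, 3, seed = 12)$x))
})

test_that("the two migration axes are independent and statistically alike", {
  p2 <- quick_params(duration = 1000, dimensions = 2)
  p1 <- quick_params(duration = 1000, dimensions = 1)
  t2 <- simulate_ensemble(p2, 20, seed = 31)
  t1 <- simulate_ensemble(p1, 20, seed = 32)
  a2 <- fit_alpha(msd(data.frame(cell = t2$cell, time = t2$time, x = t2$x)))
  a1 <- fit_alpha(msd(t1))
  expect_lt(abs(a2$alpha - a1$alpha), 0.35)
  # x and y of one run are uncorrelated
  r <- stats::cor(t2$x, t2$y)
  expect_lt(abs(r), 0.5)
})

test_that("migration has no systematic drift", {
  p <- quick_params(duration = 1000)
  tr <- simulate_ensemble(p, 30, seed = 21)
  xT <- tr$x[tr$time == max(tr$time)]
  se <- stats::sd(xT) / sqrt(length(xT))
  expect_lt(abs(mean(xT)), 3 * se + 1e-9)
})

test_that("conventional runs are near-Gaussian, glassy runs heavy-tailed", {
  pc <- clutch_params(off_time_mode = "constant", tau_s = 10, duration = 2000)
  tc <- simulate_ensemble(pc, 15, seed = 5)
  dc <- unlist(lapply(split(tc$x, tc$cell), diff))
  kc <- kurtosis_number(dc)
  expect_gt(kc, 2)
  expect_lt(kc, 4.5)

  pg <- modify_params(pc, off_time_mode = "glassy", beta = 1.5)
  tg <- simulate_ensemble(pg, 15, seed = 5)
  seg <- segment_motion(tg)
  ks <- c(
    trap = if (nrow(seg$traps) >= 4) kurtosis_number(seg$traps$duration) else NA,
    step = if (nrow(seg$steps) >= 4) kurtosis_number(seg$steps$displacement) else NA
  )
  expect_gt(max(ks, na.rm = TRUE), 5)
})

test_that("inhibition scenarios rescale the actomyosin parameters", {
  p <- clutch_params(tau_s = 10)
  expect_identical(unclass(apply_scenario(p, "control"))[names(unclass(p))],
                   unclass(p)[names(unclass(p))])
  m <- apply_scenario(p, "myosin_inhibited", myosin_factor = 0.5)
  expect_equal(m$n_motors, 25L)
  expect_equal(m$v_u, p$v_u)
  a <- apply_scenario(p, "actin_inhibited")
  expect_equal(a$n_motors, 25L)
  expect_equal(a$v_u, 60)
  # derived quantities track the new parameters
  expect_equal(m$f_stall, 50)
  expect_gt(a$tau_l, 0)
  expect_error(apply_scenario(p, "latrunculin"), "arg")
  expect_error(apply_scenario(p, "myosin_inhibited", myosin_factor = 1.5),
               "factors")
})

test_that("end-state diagnostics are recorded when requested", {
  p <- quick_params(duration = 300)
  tr <- simulate_cell(p, seed = 2, diagnostics = TRUE)
  d <- attr(tr, "diagnostics")
  expect_true(all(c("f_s_left", "f_s_right", "v_r_left", "v_r_right",
                    "n_bound_left", "n_bound_right") %in% names(d)))
  expect_equal(nrow(d), sum(tr$cell == 1))
  expect_true(all(d$n_bound_left >= 0 & d$n_bound_left <= p$n_clutches))
})

test_that("nondimensionalization divides by the clutch time and length scales", {
  p <- quick_params(duration = 200)
  tr <- simulate_cell(p, seed = 1)
  nd <- nondimensionalize(tr)
  expect_equal(nd$time, tr$time * p$r_on)
  expect_equal(nd$x, tr$x / (p$v_u / p$r_on))
})

test_that("parameter validation rejects inconsistent input", {
  expect_error(clutch_params(tau_s = 10, eta = 5), "not both")
  expect_error(clutch_params(beta = 0.8), "normalizable")
  expect_error(clutch_params(k_c = -1), "k_c")
  expect_error(clutch_params(tau_s = 10, dt = 2), "stability")
  expect_error(clutch_params(record_interval = 0.001), ">= dt")
  expect_error(modify_params(clutch_params(), nonsense = 1), "unknown")
  # tau_s = eta / k_a identity
  p <- clutch_params(eta = 20, k_a = 2, k_l = 2)
  expect_equal(p$tau_s, 10)
  p2 <- modify_params(p, tau_s = 100)
  expect_equal(p2$eta, 200)
})
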