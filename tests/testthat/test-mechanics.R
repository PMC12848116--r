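test_that("Bell's law amplifies the unloaded rate exponentially", {
  expect_equal(bell_off_rate(0, tau_off = 5, f_bond = 2), 0.2)
  expect_equal(bell_off_rate(2, tau_off = 1, f_bond = 2), exp(1))
  expect_equal(bell_off_rate(4, tau_off = 2, f_bond = 2), exp(2) / 2)
  # slip bond: monotone in |force|, compression not sign-flipped
  f <- seq(0, 10, by = 0.5)
  r <- bell_off_rate(f, 1, 2)
  expect_true(all(diff(r) > 0))
  expect_equal(bell_off_rate(-3, 1, 2), bell_off_rate(3, 1, 2))
  expect_error(bell_off_rate(1, tau_off = 0, f_bond = 2), "tau_off")
  expect_error(bell_off_rate(1, tau_off = 1, f_bond = -1), "f_bond")
})

test_that("Hill relation interpolates linearly from unloaded to stall", {
  expect_equal(hill_velocity(0, 50, 2, 120), 120)
  expect_equal(hill_velocity(100, 50, 2, 120), 0)   # stall
  expect_equal(hill_velocity(50, 50, 2, 120), 60)
  expect_equal(hill_velocity(500, 50, 2, 120), 0)   # clamped above stall
  expect_equal(hill_velocity(10, 0, 2, 120), 0)     # no motors, no flow
  expect_error(hill_velocity(-1, 50, 2, 120), "non-negative")
})

test_that("SLS creep reproduces the analytic step response", {
  sub <- sls_substrate(k_a = 1, k_l = 1, eta = 10)
  cr <- sls_creep(sub, force = 10, dt = 0.01, t_end = 250)
  # instantaneous elastic response F / (k_a + k_l)
  expect_equal(cr$x_s[2], 5, tolerance = 0.01)
  # long-term F / k_l
  expect_equal(cr$x_s[nrow(cr)], 10, tolerance = 1e-3)
})

test_that("fixed-displacement force relaxation has e-folding time eta/k_a", {
  sub <- sls_substrate(k_a = 1, k_l = 1, eta = 10)  # tau_s = 10 s
  rel <- sls_relaxation(sub, x_fixed = 10, dt = sub$tau_s / 100)
  expect_equal(rel$force[1], 20)                    # (k_a + k_l) x
  expect_equal(rel$force[nrow(rel)], 10, tolerance = 1e-2)
  expect_equal(attr(rel, "efold_time"), 10, tolerance = 0.01)

  # first-order convergence of the semi-implicit scheme
  e100 <- abs(attr(sls_relaxation(sub, 10, dt = 0.1), "efold_time") - 10) / 10
  e1000 <- abs(attr(sls_relaxation(sub, 10, dt = 0.01), "efold_time") - 10) / 10
  expect_lt(e100, 0.01)
  expect_lt(e1000, 0.001)
  expect_gt(e100 / e1000, 5)                        # error ~ dt
})

test_that("the substrate stepper enforces its stability bound", {
  sub <- sls_substrate(k_a = 1, k_l = 1, eta = 10)
  expect_error(sls_step(sub, 5, dt = 2), "tau_s/10")
  s2 <- sls_step(sub, 5, dt = 0.5)
  expect_s3_class(s2, "sls_substrate")
  expect_equal(s2$f_s, 5)
})

test_that("single-clutch kinetics uses exact exponential survival", {
  d <- off_time_dist(beta = 3, tau_min = 1)
  cl <- list(bound = FALSE, x_c = 0, tau_off = NA_real_)
  # r_on = 0: stays unbound with probability 1
  set.seed(1)
  for (i in 1:50) {
    expect_false(clutch_kinetics_step(cl, 0, 1, 0.1, 0, d)$bound)
  }
  # binding probability 1 - exp(-r_on dt) at r_on = 1, dt = 0.01
  set.seed(99)
  n <- 2e4
  hits <- sum(vapply(seq_len(n), function(i) {
    clutch_kinetics_step(cl, 1, 0, 0.01, x_s = 3, d)$bound
  }, logical(1)))
  p <- -expm1(-0.01)
  se <- sqrt(p * (1 - p) / n)
  expect_lt(abs(hits / n - p), 3 * se)
  # binding occurs at zero extension with a fresh time constant
  set.seed(2)
  b <- clutch_kinetics_step(cl, 1e6, 0, 1, x_s = 7, d)
  expect_true(b$bound)
  expect_equal(b$x_c, 7)
  expect_gte(b$tau_off, 1)
})

test_that("steady-state clutch occupancy matches the master-equation balance", {
  # frozen forces (no motors): r_off = 1/tau_off; with r_on = 1 and
  # tau_off = 1/3 the bound fraction is r_on / (r_on + r_off) = 0.25
  p <- clutch_params(n_motors = 0, off_time_mode = "constant", tau_min = 1 / 3,
                     r_on = 1, tau_s = 10, n_clutches = 45)
  e <- simulate_end(p, seed = 4, duration = 3000, record_every = 10)
  occ <- e$n_bound[e$time > 50] / 45
  # MC standard error from batch means over 100 s blocks
  bm <- tapply(occ, (seq_along(occ) - 1) %/% 1000, mean)
  se <- stats::sd(bm) / sqrt(length(bm))
  expect_lt(abs(mean(occ) - 0.25), 3 * se + 1e-3)
})

test_that("a permanently engaged clutch loads the motors to stall", {
  # one never-releasing clutch on a stiff elastic substrate: the transmitted
  # force follows F(t) = F_stall (1 - exp(-k_eff V_u t / F_stall)) with
  # k_eff the clutch/substrate series stiffness
  p <- clutch_params(n_clutches = 1, r_on = 1e3, off_time_mode = "constant",
                     tau_min = 1e9, f_bond = 1e9, k_l = 10, k_a = 10,
                     eta = 1e9, dt = 0.001)
  e <- simulate_end(p, seed = 1, duration = 5, record_every = 100)
  k_eff <- 0.8 * 20 / (0.8 + 20)
  expect_f <- function(t) 100 * (1 - exp(-k_eff * 120 * t / 100))
  expect_equal(e$f_s, expect_f(e$time), tolerance = 0.03)
  # retrograde flow decreases monotonically toward stall
  expect_true(all(diff(e$v_r) <= 1e-9))
  expect_lt(e$v_r[nrow(e)], 2)
})

test_that("constant-off-time ensembles show load-and-fail cycling", {
  p <- elastic_params(off_time_mode = "constant", n_clutches = 45,
                      f_bond = 1.8)
  e <- simulate_end(p, seed = 12, duration = 1000, record_every = 50)
  # collapses: force falls below 5 pN after having exceeded 20 pN
  high <- FALSE
  collapses <- 0L
  for (f in e$f_s) {
    if (f > 20) high <- TRUE
    if (high && f < 5) {
      collapses <- collapses + 1L
      high <- FALSE
    }
  }
  expect_gte(collapses, 5)
})

test_that("force bookkeeping and flow bounds hold along whole runs", {
  p <- quick_params(duration = 400)
  tr <- simulate_cell(p, seed = 3)
  expect_lt(attr(tr, "force_residual"), 1e-9)
  e <- simulate_end(p, seed = 3, duration = 400, record_every = 10)
  expect_true(all(e$v_r >= 0 & e$v_r <= p$v_u))
  expect_lt(attr(e, "force_residual"), 1e-9)
})
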