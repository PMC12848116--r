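# sweep drivers are exercised at reduced size here; the full-scale study
# conditions live in the acceptance suite

test_that("a 1x1 phase diagram equals the simulate + fit composition", {
  base <- quick_params()
  pm <- phase_diagram(1.5, 10, reps = 4, base_params = base, seed = 5)
  cell_seed <- 5 + 7919 * 1
  tr <- simulate_ensemble(modify_params(base, beta = 1.5, tau_s = 10),
                          n_cells = 4, seed = cell_seed)
  expect_equal(pm$alpha[1, 1], fit_alpha(msd(tr))$alpha, tolerance = 1e-12)
  expect_equal(dim(pm$alpha), c(1, 1))
})

test_that("phase maps carry aligned matrices and resume without recompute", {
  base <- quick_params(n_clutches = 10)
  t0 <- Sys.time()
  pm <- phase_diagram(c(1.5, 10), c(10, 1000), reps = 3,
                      base_params = base, seed = 2)
  expect_equal(dim(pm$alpha), c(2, 2))
  expect_equal(dimnames(pm$alpha), dimnames(pm$kurtosis_ratio))
  expect_true(all(!pm$failed))
  df <- as.data.frame(pm)
  expect_equal(nrow(df), 4)
  expect_true(all(c("beta", "tau_s", "alpha", "alpha_se") %in% names(df)))
  # resume: completed cells are reused verbatim, so this is near-instant
  t1 <- Sys.time()
  pm2 <- phase_diagram(c(1.5, 10), c(10, 1000), reps = 3,
                       base_params = base, seed = 2, resume = pm)
  expect_identical(pm2$alpha, pm$alpha)
  expect_lt(as.numeric(Sys.time() - t1, units = "secs"),
            as.numeric(t1 - t0, units = "secs") / 2)
})

test_that("failed grid cells are flagged without aborting the sweep", {
  base <- quick_params(duration = 100)   # too short for alpha fitting
  expect_warning(
    pm <- phase_diagram(1.5, 10, reps = 3, base_params = base, seed = 1),
    "failed")
  expect_true(pm$failed[1, 1])
  expect_true(is.na(pm$alpha[1, 1]))
})

test_that("the relaxation contrast reports both conditions side by side", {
  rc <- relaxation_contrast(quick_params(), reps = 10, seed = 3)
  expect_s3_class(rc, "relaxation_contrast")
  expect_equal(nrow(rc$effects), 6)
  expect_true(all(c("fast", "slow") %in% names(rc$effects)))
  expect_true(is.finite(rc$fast$alpha) && is.finite(rc$slow$alpha))
  expect_equal(rc$fast$vac$vac[1], 1)
  expect_output(print(rc), "alpha")
})

test_that("the inhibition study runs the requested scenarios", {
  st <- inhibition_study(quick_params(), scenarios = c("control",
                                                       "myosin_inhibited"),
                         reps = 8, seed = 3)
  expect_equal(st$comparison$scenario, c("control", "myosin_inhibited"))
  expect_true(all(is.finite(st$comparison$alpha)))
  expect_output(print(st), "scenario")
})
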