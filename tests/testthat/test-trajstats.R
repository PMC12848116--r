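mk_traj <- function(x, y = NULL, dt = 10, cell = 1L) {
  n <- length(x)
  d <- data.frame(cell = cell, time = (seq_len(n) - 1) * dt, x = x)
  if (!is.null(y)) d$y <- y
  d
}

test_that("MSD of deterministic motions matches closed forms", {
  tt <- 0:99
  ball <- mk_traj(5 * tt * 10, 0 * tt)          # speed 5 nm/s, dt = 10 s
  m <- msd(ball)
  expect_equal(m$msd, (5 * m$lag)^2, tolerance = 1e-12)
  still <- mk_traj(rep(2, 100), rep(-1, 100))
  expect_true(all(msd(still)$msd == 0))
})

test_that("MSD of a Gaussian walk matches 2 sigma^2 k in both modes", {
  set.seed(14)
  n <- 200; sg <- 30
  trs <- do.call(rbind, lapply(1:150, function(c) {
    mk_traj(c(0, cumsum(rnorm(n, sd = sg))), c(0, cumsum(rnorm(n, sd = sg))),
            cell = c)
  }))
  me <- msd(trs, mode = "ensemble")
  mt <- msd(trs, mode = "time")
  k <- me$lag / 10
  # the sliding-window estimator pools ~30k pairs per lag: tight check
  expect_equal(mt$msd[k <= 10][-1], (2 * sg^2 * k[k <= 10])[-1],
               tolerance = 0.05)
  # the from-origin estimator has 150 samples per lag: noisier, and for an
  # ergodic process it must agree with the time average (cross-check)
  expect_equal(me$msd[-1], mt$msd[-1], tolerance = 0.15)
  f <- fit_alpha(me)
  expect_equal(f$alpha, 1, tolerance = 0.06)
  expect_equal(f$mu, 2 * sg^2 / 10, tolerance = 0.15)
})

test_that("MSD refuses short or irregular tracks", {
  expect_error(msd(mk_traj(1:20)), "64 frames")
  bad <- mk_traj(1:100)
  bad$time[50] <- bad$time[50] + 3
  expect_error(msd(bad), "uniform|increasing")
  bad2 <- mk_traj(1:100)
  bad2$time[10] <- bad2$time[12]
  expect_error(msd(bad2), "increasing|uniform")
})

test_that("exponent fitting recovers exact power laws to machine precision", {
  lags <- seq(10, 500, by = 10)
  curve <- structure(
    data.frame(lag = c(0, lags), msd = c(0, 3 * lags^1.7), n_obs = 1L),
    mode = "ensemble", class = c("msd_curve", "data.frame"))
  f <- fit_alpha(curve)
  expect_equal(f$alpha, 1.7, tolerance = 1e-9)
  expect_equal(f$mu, 3, tolerance = 1e-9)
  expect_equal(f$r_squared, 1, tolerance = 1e-12)
  expect_equal(unname(coef(f)), c(1.7, 3), tolerance = 1e-9)
  expect_equal(predict(f, 10), 3 * 10^1.7, tolerance = 1e-6)

  tt <- 0:99
  expect_equal(fit_alpha(msd(mk_traj(7 * tt, 7 * tt)))$alpha, 2,
               tolerance = 1e-9)
  # narrow window refusal
  expect_error(fit_alpha(curve, window = c(10, 40)), ">= 8")
})

test_that("velocity autocorrelation is 1 for ballistic, 0 for white steps", {
  tt <- 0:99
  vb <- velocity_autocorrelation(mk_traj(3 * tt, 4 * tt))
  expect_equal(vb$vac, rep(1, nrow(vb)), tolerance = 1e-12)

  set.seed(8)
  trs <- do.call(rbind, lapply(1:40, function(c) {
    mk_traj(c(0, cumsum(rnorm(120))), c(0, cumsum(rnorm(120))), cell = c)
  }))
  v <- velocity_autocorrelation(trs)
  expect_equal(v$vac[1], 1)
  n_pairs <- 40 * 119
  expect_true(all(abs(v$vac[-1]) < 3 / sqrt(n_pairs) + 0.01))

  still <- mk_traj(rep(0, 10), rep(0, 10))
  expect_error(velocity_autocorrelation(still), "normalization")
})

test_that("track straightness is the net-over-total path ratio", {
  tt <- 0:20
  expect_equal(unname(track_straightness(mk_traj(tt, 2 * tt))), 1)
  out_back <- mk_traj(c(0:10, 9:0), rep(0, 21))
  expect_equal(unname(track_straightness(out_back)), 0)
  # two equal perpendicular legs
  ra <- mk_traj(c(0:10, rep(10, 10)), c(rep(0, 11), 1:10))
  expect_equal(unname(track_straightness(ra)), sqrt(2) / 2, tolerance = 1e-12)
  expect_error(track_straightness(mk_traj(rep(1, 5), rep(1, 5))),
               "zero total path")
  # bounded by 1 on random walks
  set.seed(5)
  rw <- mk_traj(c(0, cumsum(rnorm(99))), c(0, cumsum(rnorm(99))))
  expect_lte(unname(track_straightness(rw)), 1)
})

test_that("trap/step segmentation partitions constructed trajectories", {
  # still 10 frames, jump 500 nm in one frame, still 10 frames
  x <- c(rep(0, 11), rep(500, 11))
  tr <- mk_traj(x, rep(0, 22))
  seg <- segment_motion(tr, v_eps = 6, t_min = 30)
  expect_equal(nrow(seg$traps), 2)
  expect_equal(nrow(seg$steps), 1)
  expect_equal(seg$steps$displacement, 500)
  # traps and steps partition the track duration
  expect_equal(sum(seg$traps$duration) + sum(seg$steps$duration),
               max(tr$time))

  ball <- mk_traj(100 * (0:20), rep(0, 21))
  sb <- segment_motion(ball, v_eps = 6, t_min = 30)
  expect_equal(nrow(sb$traps), 0)
  expect_equal(nrow(sb$steps), 1)
})

test_that("raising the speed threshold never shrinks total trapped time", {
  set.seed(77)
  tr <- mk_traj(c(0, cumsum(rnorm(199, sd = 30))),
                c(0, cumsum(rnorm(199, sd = 30))))
  trapped <- vapply(c(0.5, 1, 2, 4, 8), function(v) {
    sum(segment_motion(tr, v_eps = v, t_min = 30)$traps$duration)
  }, numeric(1))
  expect_true(all(diff(trapped) >= 0))
})

test_that("kurtosis number is the fourth standardized moment", {
  expect_equal(kurtosis_number(rep(c(-1, 1), 50)), 1)
  set.seed(10)
  expect_equal(kurtosis_number(rnorm(1e5)), 3, tolerance = 0.1)
  expect_error(kurtosis_number(rep(4, 10)), "zero variance")
  expect_error(kurtosis_number(c(1, 2)), "4 samples")
})

test_that("kurtosis ratio flags tail-weight asymmetry", {
  set.seed(11)
  g <- rnorm(500)
  expect_equal(as.numeric(kurtosis_ratio(g, g)), 1)
  heavy <- (1 - runif(500))^(-1 / 1.5)   # Pareto-like
  expect_gt(as.numeric(kurtosis_ratio(heavy, g)), 1)
  expect_warning(kurtosis_ratio(heavy[1:5], g), "noisy")
})
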