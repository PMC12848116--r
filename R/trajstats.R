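#' Mean squared displacement of a trajectory ensemble
#'
#' Computes the MSD curve used to classify migration as sub-diffusive
#' (\eqn{\alpha < 1}), diffusive (\eqn{\alpha = 1}) or super-diffusive
#' (\eqn{\alpha > 1}) via \eqn{MSD = \mu t^\alpha}.
#'
#' Two estimators are available:
#' * `mode = "ensemble"` (default): the ensemble average over cells of the
#'   squared displacement from each track's origin,
#'   \eqn{\langle |r(t) - r(0)|^2 \rangle_{cells}}. This is the estimator
#'   matching tracking practice of averaging displacement-from-origin curves
#'   over many cells, and it is the one that preserves anomalous scaling for
#'   non-ergodic (heavy-tailed waiting time) processes, whose time-averaged
#'   MSD scales linearly in lag regardless of \eqn{\alpha}.
#' * `mode = "time"`: the time-and-ensemble average over sliding start times,
#'   \eqn{\langle |r(t+\tau) - r(t)|^2 \rangle_{t, cells}}. Lower variance,
#'   but reports \eqn{\alpha \approx 1} for ageing processes.
#'
#' @param trajs a `trajectory_set` (see [simulate_ensemble()]) or data.frame
#'   with columns `cell`, `time`, `x` and optionally `y`. At least 64 frames
#'   per cell are required.
#' @param max_lag_fraction largest lag as a fraction of the track duration
#'   (default 1/4).
#' @param mode MSD estimator, see Details.
#' @return An object of class `"msd_curve"`: a data.frame with columns
#'   `lag` (s), `msd` (nm^2) and `n_obs` (number of displacement pairs
#'   averaged), including the trivial `lag = 0` row.
#' @seealso [fit_alpha()]
#' @export
msd <- function(trajs, max_lag_fraction = 0.25,
                mode = c("ensemble", "time")) {
  mode <- match.arg(mode)
  cells <- .traj_split(trajs)
  n_frames <- vapply(cells, function(c) nrow(c$pos), integer(1))
  if (any(n_frames < 64L)) {
    stop(sprintf(
      "MSD estimation needs >= 64 frames per cell (shortest track has %d)",
      min(n_frames)))
  }
  n <- min(n_frames)
  dt <- cells[[1L]]$dt
  k_max <- max(1L, floor(max_lag_fraction * (n - 1L)))

  if (mode == "ensemble") {
    sq <- vapply(cells, function(c) {
      d <- sweep(c$pos[seq_len(n), , drop = FALSE], 2L, c$pos[1L, ])
      rowSums(d^2)
    }, numeric(n))
    m <- rowMeans(sq)[seq_len(k_max + 1L)]
    n_obs <- rep(length(cells), k_max + 1L)
  } else {
    m <- numeric(k_max + 1L)
    n_obs <- integer(k_max + 1L)
    n_obs[1L] <- length(cells) * n
    for (k in seq_len(k_max)) {
      tot <- 0
      cnt <- 0L
      for (c in cells) {
        p <- c$pos
        d <- p[(k + 1L):n, , drop = FALSE] - p[seq_len(n - k), , drop = FALSE]
        tot <- tot + sum(d^2)
        cnt <- cnt + (n - k)
      }
      m[k + 1L] <- tot / cnt
      n_obs[k + 1L] <- cnt
    }
  }
  structure(
    data.frame(lag = (0:k_max) * dt, msd = m, n_obs = n_obs),
    mode = mode, n_cells = length(cells), frame_interval = dt,
    class = c("msd_curve", "data.frame"))
}

#' Fit the anomalous-diffusion exponent from an MSD curve
#'
#' Ordinary least squares of \eqn{\log MSD} on \eqn{\log \tau} over a lag
#' window: the slope is the diffusivity exponent \eqn{\alpha} and the
#' intercept \eqn{\log \mu}. The default window spans one decade of lags
#' starting at the first recorded (nonzero) lag, which avoids the noisy
#' large-lag region where few displacement pairs remain.
#'
#' @param msd an [msd()] curve, or a `trajectory_set` (in which case the
#'   ensemble MSD is computed first).
#' @param window numeric length-2 vector of lag limits (s), or `NULL` for
#'   the default first-decade window. At least 8 positive-MSD lags must fall
#'   in the window.
#' @return An object of class `"msd_fit"` with fields `alpha`, `mu`,
#'   `r_squared`, `window`, and the fitted curve; supports `coef()`,
#'   `print()`, `predict()` and `plot()`.
#' @examples
#' lags <- seq(10, 200, by = 10)
#' curve <- structure(data.frame(lag = c(0, lags), msd = c(0, 3 * lags^1.7),
#'                               n_obs = 1), class = c("msd_curve", "data.frame"))
#' coef(fit_alpha(curve))  # recovers alpha = 1.7, mu = 3
#' @export
fit_alpha <- function(msd, window = NULL) {
  if (inherits(msd, "trajectory_set") ||
      (is.data.frame(msd) && !inherits(msd, "msd_curve"))) {
    msd <- glassyclutch::msd(msd)
  }
  stopifnot(inherits(msd, "msd_curve"))
  pos <- msd$lag > 0
  if (is.null(window)) {
    first <- min(msd$lag[pos])
    window <- c(first, 10 * first)
  }
  in_win <- pos & msd$lag >= window[1L] & msd$lag <= window[2L]
  if (sum(in_win) < 8L) {
    stop(sprintf("only %d lags in the fit window [%g, %g] s; >= 8 required",
                 sum(in_win), window[1L], window[2L]))
  }
  if (any(msd$msd[in_win] <= 0)) {
    stop("MSD must be strictly positive over the fit window")
  }
  lx <- log(msd$lag[in_win])
  ly <- log(msd$msd[in_win])
  fit <- stats::lm.fit(cbind(1, lx), ly)
  alpha <- unname(fit$coefficients[2L])
  mu <- exp(unname(fit$coefficients[1L]))
  r2 <- 1 - sum(fit$residuals^2) / sum((ly - mean(ly))^2)
  structure(list(alpha = alpha, mu = mu, r_squared = r2,
                 window = window, curve = msd,
                 n_lags = sum(in_win)),
            class = "msd_fit")
}

#' @export
print.msd_fit <- function(x, ...) {
  cat(sprintf("MSD power-law fit: MSD = mu * t^alpha\n"))
  cat(sprintf("  alpha = %.4f   mu = %.4g nm^2/s^alpha   R^2 = %.4f\n",
              x$alpha, x$mu, x$r_squared))
  cat(sprintf("  window: lags %g-%g s (%d points, %s estimator)\n",
              x$window[1L], x$window[2L], x$n_lags,
              attr(x$curve, "mode") %||% "?"))
  invisible(x)
}

#' @export
coef.msd_fit <- function(object, ...) {
  c(alpha = object$alpha, mu = object$mu)
}

#' @export
predict.msd_fit <- function(object, lags = NULL, ...) {
  if (is.null(lags)) lags <- object$curve$lag[object$curve$lag > 0]
  object$mu * lags^object$alpha
}

#' @export
plot.msd_fit <- function(x, ...) {
  cv <- x$curve[x$curve$lag > 0, ]
  graphics::plot(cv$lag, cv$msd, log = "xy", xlab = "lag (s)",
                 ylab = expression(MSD ~ (nm^2)),
                 main = sprintf("alpha = %.3f", x$alpha), ...)
  graphics::lines(cv$lag, predict(x, cv$lag), col = 2, lwd = 2)
  graphics::abline(v = x$window, lty = 3, col = "grey50")
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Normalized velocity autocorrelation of a trajectory ensemble
#'
#' Frame-to-frame velocities \eqn{v_i = (r_{i+1} - r_i)/\Delta t} are
#' correlated over frame lags:
#' \eqn{C(k) = \langle v_i \cdot v_{i+k} \rangle / \langle |v_i|^2 \rangle},
#' averaged over start frames and cells. \eqn{C(0) = 1} by construction;
#' slower decay means more persistent migration.
#'
#' @param trajs a `trajectory_set` or compatible data.frame (>= 3 frames).
#' @param max_lag_frames largest frame lag (default: a quarter of the
#'   velocity frames).
#' @return A data.frame with columns `lag_frames`, `lag` (s), `vac`.
#' @export
velocity_autocorrelation <- function(trajs, max_lag_frames = NULL) {
  cells <- .traj_split(trajs)
  nv <- vapply(cells, function(c) nrow(c$pos) - 1L, integer(1))
  if (any(nv < 2L)) stop("velocity autocorrelation needs >= 3 frames per cell")
  dt <- cells[[1L]]$dt
  vels <- lapply(cells, function(c) diff(c$pos) / c$dt)
  norm <- mean(unlist(lapply(vels, function(v) rowSums(v^2))))
  if (norm == 0) stop("all velocities are zero: VAC normalization undefined")
  if (is.null(max_lag_frames)) max_lag_frames <- max(1L, floor(min(nv) / 4))
  ac <- vapply(0:max_lag_frames, function(k) {
    mean(unlist(lapply(vels, function(v) {
      n <- nrow(v)
      if (k >= n) return(numeric(0))
      rowSums(v[seq_len(n - k), , drop = FALSE] *
                v[(k + 1L):n, , drop = FALSE])
    })))
  }, numeric(1))
  data.frame(lag_frames = 0:max_lag_frames, lag = (0:max_lag_frames) * dt,
             vac = ac / norm)
}

#' Track straightness
#'
#' Ratio of net displacement to total path length,
#' \eqn{|r(T) - r(0)| / \sum_i |r_{i+1} - r_i|}: 1 for a perfectly straight
#' monotone path, near 0 for a wandering or out-and-back track.
#'
#' @param trajs a `trajectory_set` or compatible data.frame.
#' @return Named numeric vector of straightness values in `[0, 1]`, one per
#'   cell.
#' @export
track_straightness <- function(trajs) {
  df <- .as_traj_df(trajs)
  cells <- .traj_split(df, require_uniform = FALSE)
  out <- vapply(cells, function(c) {
    p <- c$pos
    path <- sum(sqrt(rowSums(diff(p)^2)))
    if (path == 0) {
      stop("zero total path length: straightness undefined")
    }
    net <- sqrt(sum((p[nrow(p), ] - p[1L, ])^2))
    net / path
  }, numeric(1))
  names(out) <- unique(df$cell)
  out
}

#' Segment a trajectory into trapping intervals and migration steps
#'
#' A trap is a maximal run of frames whose frame speed
#' \eqn{|r_{i+1} - r_i| / \Delta t} stays below `v_eps` for at least
#' `t_min`; the intervening segments are migration steps with net
#' displacement \eqn{D_s} and duration. Traps and steps partition each
#' track. Long, heavy-tailed trap times drive sub-diffusion; large,
#' heavy-tailed step sizes drive super-diffusion.
#'
#' @param trajs a `trajectory_set` or compatible data.frame with uniform
#'   frame spacing.
#' @param v_eps speed threshold, nm/s. Default `0.05 * v_u` when simulation
#'   parameters are attached to `trajs`; otherwise required.
#' @param t_min minimum trap duration, s. Default 3 frame intervals.
#' @return A list of class `"motion_segments"` with data.frames `traps`
#'   (`cell`, `t_start`, `t_end`, `duration`) and `steps` (`cell`,
#'   `displacement`, `duration`), plus the thresholds used as attributes.
#' @export
segment_motion <- function(trajs, v_eps = NULL, t_min = NULL) {
  cells <- .traj_split(trajs)
  dt <- cells[[1L]]$dt
  if (is.null(v_eps)) {
    p <- attr(trajs, "params")
    if (is.null(p)) {
      stop("'v_eps' is required when 'trajs' carries no simulation parameters")
    }
    v_eps <- 0.05 * p$v_u
  }
  if (is.null(t_min)) t_min <- 3 * dt
  ids <- unique(.as_traj_df(trajs)$cell)
  traps <- list()
  steps <- list()
  for (ci in seq_along(cells)) {
    c <- cells[[ci]]
    speed <- sqrt(rowSums(diff(c$pos)^2)) / c$dt
    slow <- speed < v_eps
    r <- rle(slow)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    is_trap <- r$values & (r$lengths * dt >= t_min)
    # merge consecutive non-trap runs (sub-threshold-but-short runs join steps)
    seg_id <- cumsum(c(TRUE, diff(is_trap) != 0) | is_trap)
    for (s in unique(seg_id)) {
      idx <- which(seg_id == s)
      i0 <- starts[idx[1L]]
      i1 <- ends[idx[length(idx)]]
      t0 <- c$times[i0]
      t1 <- c$times[i1 + 1L]
      if (is_trap[idx[1L]]) {
        traps[[length(traps) + 1L]] <-
          data.frame(cell = ids[ci], t_start = t0, t_end = t1,
                     duration = t1 - t0)
      } else {
        d <- sqrt(sum((c$pos[i1 + 1L, ] - c$pos[i0, ])^2))
        steps[[length(steps) + 1L]] <-
          data.frame(cell = ids[ci], displacement = d, duration = t1 - t0)
      }
    }
  }
  empty_tr <- data.frame(cell = integer(0), t_start = numeric(0),
                         t_end = numeric(0), duration = numeric(0))
  empty_st <- data.frame(cell = integer(0), displacement = numeric(0),
                         duration = numeric(0))
  structure(list(
    traps = if (length(traps)) do.call(rbind, traps) else empty_tr,
    steps = if (length(steps)) do.call(rbind, steps) else empty_st),
    v_eps = v_eps, t_min = t_min, class = "motion_segments")
}

#' @export
print.motion_segments <- function(x, ...) {
  cat(sprintf("Motion segmentation (v_eps = %g nm/s, t_min = %g s)\n",
              attr(x, "v_eps"), attr(x, "t_min")))
  cat(sprintf("  %d traps (mean duration %.4g s), %d steps (mean size %.4g nm)\n",
              nrow(x$traps),
              if (nrow(x$traps)) mean(x$traps$duration) else NA,
              nrow(x$steps),
              if (nrow(x$steps)) mean(x$steps$displacement) else NA))
  invisible(x)
}

#' Kurtosis number (fourth standardized moment)
#'
#' Pearson kurtosis \eqn{K = m_4 / m_2^2} with population moments: 3 for a
#' Gaussian, larger for heavy-tailed samples. The Pearson (not excess) form
#' is used so that ratios of kurtosis numbers are always positive and
#' well-defined.
#'
#' @param x numeric sample (>= 4 values, nonzero variance).
#' @return The kurtosis number (dimensionless).
#' @export
kurtosis_number <- function(x) {
  x <- x[!is.na(x)]
  if (length(x) < 4L) stop("kurtosis needs at least 4 samples")
  m <- mean(x)
  m2 <- mean((x - m)^2)
  if (m2 == 0) stop("zero variance: kurtosis undefined")
  mean((x - m)^4) / m2^2
}

#' Kurtosis ratio of trap times to step sizes
#'
#' \eqn{K_{trap} / K_{step}}: the relative tail weight of the trapping-time
#' distribution versus the step-size distribution. Large values (heavy trap
#' tails) accompany sub-diffusive migration; small values (heavy step tails)
#' accompany super-diffusive migration.
#'
#' @param traps trap durations (numeric vector) or a `"motion_segments"`
#'   object from [segment_motion()] (in which case `steps` is ignored).
#' @param steps step sizes (numeric vector).
#' @return The ratio; attribute `"low_sample"` is `TRUE` when fewer than 10
#'   traps or steps were available (with a warning).
#' @export
kurtosis_ratio <- function(traps, steps = NULL) {
  if (inherits(traps, "motion_segments")) {
    steps <- traps$steps$displacement
    traps <- traps$traps$duration
  }
  low <- length(traps) < 10L || length(steps) < 10L
  if (low) {
    warning(sprintf("fewer than 10 traps (%d) or steps (%d): ratio is noisy",
                    length(traps), length(steps)))
  }
  structure(kurtosis_number(traps) / kurtosis_number(steps),
            low_sample = low)
}
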