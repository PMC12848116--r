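#' Phase diagram of migration diffusivity over (beta, tau_s)
#'
#' Sweeps the glass coefficient \eqn{\beta} against the substrate
#' stress-relaxation timescale \eqn{\tau_s = \eta / k_a} (the viscosity axis
#' at fixed stiffness), simulating `reps` cells per grid cell and recording
#' the ensemble-fitted MSD exponent \eqn{\alpha} and the kurtosis ratio
#' \eqn{K_{trap}/K_{step}} of pooled trap times and step sizes. Anomalous
#' regimes (both \eqn{\alpha < 1} and \eqn{\alpha > 1} along the viscosity
#' axis) appear only for small \eqn{\beta}, where the off-time law is heavy
#' tailed.
#'
#' @param beta_grid glass coefficients to sweep.
#' @param tau_s_grid relaxation timescales (s) to sweep; viscosity is
#'   derived as `eta = tau_s * k_a` per grid cell.
#' @param reps simulated cells per grid cell (>= 3).
#' @param base_params template [clutch_params()]; `beta` and `tau_s` are
#'   overridden per grid cell.
#' @param seed integer seed; each grid cell uses a distinct derived seed, so
#'   the sweep is reproducible and cells are order-independent.
#' @param resume an earlier `phase_map` over the same grid: completed cells
#'   are reused instead of recomputed.
#' @return An object of class `"phase_map"`: lists of grid vectors and
#'   matrices `alpha`, `alpha_se` (Monte-Carlo SE from 4-block splits),
#'   `kurtosis_ratio`, `n_traps`, `n_steps`, `failed`.
#' @export
phase_diagram <- function(beta_grid, tau_s_grid, reps = 20,
                          base_params = clutch_params(), seed = 1,
                          resume = NULL) {
  if (!length(beta_grid) || !length(tau_s_grid)) stop("grids must be nonempty")
  if (reps < 3) stop("'reps' must be >= 3 per grid cell")
  nb <- length(beta_grid)
  nt <- length(tau_s_grid)
  mk <- function() matrix(NA_real_, nb, nt, dimnames = list(beta_grid, tau_s_grid))
  alpha <- mk(); alpha_se <- mk(); kr <- mk(); n_traps <- mk(); n_steps <- mk()
  failed <- matrix(FALSE, nb, nt, dimnames = list(beta_grid, tau_s_grid))
  reuse <- !is.null(resume) && inherits(resume, "phase_map") &&
    identical(resume$beta, beta_grid) && identical(resume$tau_s, tau_s_grid)

  for (i in seq_len(nb)) {
    for (j in seq_len(nt)) {
      if (reuse && !is.na(resume$alpha[i, j])) {
        alpha[i, j] <- resume$alpha[i, j]
        alpha_se[i, j] <- resume$alpha_se[i, j]
        kr[i, j] <- resume$kurtosis_ratio[i, j]
        n_traps[i, j] <- resume$n_traps[i, j]
        n_steps[i, j] <- resume$n_steps[i, j]
        next
      }
      cell_seed <- seed + 7919 * ((i - 1L) * nt + j)
      res <- tryCatch({
        p <- modify_params(base_params, beta = beta_grid[i],
                           tau_s = tau_s_grid[j])
        tr <- simulate_ensemble(p, n_cells = reps, seed = cell_seed)
        ft <- fit_alpha(msd(tr))
        seg <- segment_motion(tr)
        krv <- tryCatch(
          suppressWarnings(as.numeric(kurtosis_ratio(seg))),
          error = function(e) NA_real_)
        # Monte-Carlo SE of alpha from 4 disjoint sub-ensembles
        blocks <- split(unique(tr$cell),
                        rep(1:4, length.out = length(unique(tr$cell))))
        ba <- vapply(blocks, function(b) {
          tryCatch(fit_alpha(msd(tr[tr$cell %in% b, ]))$alpha,
                   error = function(e) NA_real_)
        }, numeric(1))
        list(alpha = ft$alpha,
             alpha_se = stats::sd(ba, na.rm = TRUE) / sqrt(sum(!is.na(ba))),
             kr = krv, n_tr = nrow(seg$traps), n_st = nrow(seg$steps))
      }, error = function(e) e)
      if (inherits(res, "error")) {
        failed[i, j] <- TRUE
        warning(sprintf("grid cell (beta = %g, tau_s = %g) failed: %s",
                        beta_grid[i], tau_s_grid[j], conditionMessage(res)))
      } else {
        alpha[i, j] <- res$alpha
        alpha_se[i, j] <- res$alpha_se
        kr[i, j] <- res$kr
        n_traps[i, j] <- res$n_tr
        n_steps[i, j] <- res$n_st
      }
    }
  }
  structure(list(beta = beta_grid, tau_s = tau_s_grid, alpha = alpha,
                 alpha_se = alpha_se, kurtosis_ratio = kr,
                 n_traps = n_traps, n_steps = n_steps, failed = failed,
                 reps = reps, seed = seed),
            class = "phase_map")
}

#' @export
print.phase_map <- function(x, ...) {
  cat(sprintf("Phase map: %d beta x %d tau_s grid, %d cells each\n",
              length(x$beta), length(x$tau_s), x$reps))
  cat("fitted alpha:\n")
  print(round(x$alpha, 3))
  cat("kurtosis ratio K_trap/K_step:\n")
  print(round(x$kurtosis_ratio, 2))
  invisible(x)
}

#' @export
plot.phase_map <- function(x, what = c("alpha", "kurtosis_ratio"), ...) {
  what <- match.arg(what)
  z <- x[[what]]
  graphics::image(x = seq_along(x$tau_s), y = seq_along(x$beta), z = t(z),
                  xaxt = "n", yaxt = "n", xlab = expression(tau[s] ~ (s)),
                  ylab = expression(beta),
                  main = if (what == "alpha") expression(alpha)
                         else expression(K[trap] / K[step]), ...)
  graphics::axis(1, at = seq_along(x$tau_s), labels = x$tau_s)
  graphics::axis(2, at = seq_along(x$beta), labels = x$beta)
  invisible(x)
}

#' @export
as.data.frame.phase_map <- function(x, ...) {
  g <- expand.grid(beta = x$beta, tau_s = x$tau_s)
  g$alpha <- as.vector(x$alpha)
  g$alpha_se <- as.vector(x$alpha_se)
  g$kurtosis_ratio <- as.vector(x$kurtosis_ratio)
  g$failed <- as.vector(x$failed)
  g
}

# ensemble summary used by the contrast/inhibition drivers
.condition_summary <- function(params, reps, seed, label) {
  tr <- simulate_ensemble(params, n_cells = reps, seed = seed)
  ft <- fit_alpha(msd(tr))
  seg <- segment_motion(tr)
  list(label = label,
       alpha = ft$alpha, mu = ft$mu, r_squared = ft$r_squared,
       straightness = track_straightness(tr),
       vac = velocity_autocorrelation(tr, max_lag_frames = 20L),
       trap_times = seg$traps$duration,
       step_sizes = seg$steps$displacement,
       k_trap = tryCatch(kurtosis_number(seg$traps$duration),
                         error = function(e) NA_real_),
       k_step = tryCatch(kurtosis_number(seg$steps$displacement),
                         error = function(e) NA_real_),
       trajectories = tr)
}

#' Fast- versus slow-relaxing substrate contrast
#'
#' Runs the glassy model on a fast-relaxing (\eqn{\tau_s} = `tau_s_fast`)
#' and a slow-relaxing (\eqn{\tau_s} = `tau_s_slow`) substrate and reports
#' the migration statistics side by side: fitted \eqn{\alpha}, track
#' straightness, velocity autocorrelation, and trap-time/step-size samples
#' with kurtosis numbers. The expected directions are: fast relaxation gives
#' higher \eqn{\alpha}, straighter tracks, slower VAC decay and larger
#' steps; slow relaxation gives longer traps.
#'
#' @param base_params template [clutch_params()].
#' @param reps cells per condition (>= 10).
#' @param seed integer seed.
#' @param tau_s_fast,tau_s_slow the two relaxation timescales, s.
#' @return An object of class `"relaxation_contrast"`: a list with
#'   `fast`/`slow` condition summaries and an `effects` data.frame of the
#'   directional comparisons.
#' @export
relaxation_contrast <- function(base_params = clutch_params(), reps = 100,
                                seed = 1, tau_s_fast = 10,
                                tau_s_slow = 1000) {
  if (reps < 10) stop("'reps' must be >= 10")
  fast <- .condition_summary(modify_params(base_params, tau_s = tau_s_fast),
                             reps, seed, "fast")
  slow <- .condition_summary(modify_params(base_params, tau_s = tau_s_slow),
                             reps, seed + 10007L, "slow")
  effects <- data.frame(
    metric = c("alpha", "mean straightness", "mean trap time",
               "mean step size", "K_trap/K_step", "VAC at small lags"),
    fast = c(fast$alpha, mean(fast$straightness),
             mean(fast$trap_times), mean(fast$step_sizes),
             fast$k_trap / fast$k_step,
             mean(fast$vac$vac[2:4])),
    slow = c(slow$alpha, mean(slow$straightness),
             mean(slow$trap_times), mean(slow$step_sizes),
             slow$k_trap / slow$k_step,
             mean(slow$vac$vac[2:4])))
  effects$direction <- ifelse(effects$fast > effects$slow,
                              "fast > slow", "slow >= fast")
  structure(list(fast = fast, slow = slow, effects = effects,
                 reps = reps, seed = seed),
            class = "relaxation_contrast")
}

#' @export
print.relaxation_contrast <- function(x, ...) {
  cat(sprintf(
    "Substrate relaxation contrast (%d cells/condition)\n", x$reps))
  cat(sprintf("  fast (tau_s small): alpha = %.3f;  slow (tau_s large): alpha = %.3f\n",
              x$fast$alpha, x$slow$alpha))
  print(transform(x$effects, fast = signif(fast, 4), slow = signif(slow, 4)),
        row.names = FALSE)
  invisible(x)
}

#' Actomyosin inhibition study
#'
#' Runs the requested inhibition scenarios (see [apply_scenario()]) on the
#' fast-relaxing substrate and reports fitted \eqn{\alpha}, straightness and
#' VAC per scenario. Reducing motor count (myosin inhibition) or
#' polymerization speed plus motors (actin inhibition) lowers the
#' motor-stall timescale and force generation, lengthening trapping and
#' pushing migration from super- toward sub-diffusive.
#'
#' @param base_params template [clutch_params()] (should be the
#'   fast-relaxing condition).
#' @param scenarios subset of `"control"`, `"myosin_inhibited"`,
#'   `"actin_inhibited"`.
#' @param reps cells per scenario.
#' @param seed integer seed.
#' @param myosin_factor,actin_factor scenario scaling factors, see
#'   [apply_scenario()].
#' @return An object of class `"inhibition_study"`: per-scenario summaries
#'   and a comparison data.frame.
#' @export
inhibition_study <- function(base_params = clutch_params(tau_s = 10),
                             scenarios = c("control", "myosin_inhibited",
                                           "actin_inhibited"),
                             reps = 100, seed = 1,
                             myosin_factor = 0.5, actin_factor = 0.5) {
  scenarios <- match.arg(scenarios, several.ok = TRUE)
  res <- list()
  for (k in seq_along(scenarios)) {
    p <- apply_scenario(base_params, scenarios[k],
                        myosin_factor = myosin_factor,
                        actin_factor = actin_factor)
    res[[scenarios[k]]] <- .condition_summary(p, reps, seed + 7907L * (k - 1L),
                                              scenarios[k])
  }
  comparison <- data.frame(
    scenario = scenarios,
    alpha = vapply(res, `[[`, numeric(1), "alpha"),
    straightness = vapply(res, function(r) mean(r$straightness), numeric(1)),
    mean_trap_time = vapply(res, function(r) mean(r$trap_times), numeric(1)),
    row.names = NULL)
  structure(list(conditions = res, comparison = comparison,
                 reps = reps, seed = seed),
            class = "inhibition_study")
}

#' @export
print.inhibition_study <- function(x, ...) {
  cat(sprintf("Actomyosin inhibition study (%d cells/scenario)\n", x$reps))
  print(transform(x$comparison, alpha = round(alpha, 3),
                  straightness = round(straightness, 3),
                  mean_trap_time = round(mean_trap_time, 1)),
        row.names = FALSE)
  invisible(x)
}
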