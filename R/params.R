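#' Whole-cell motor-clutch simulation parameters
#'
#' Assembles and validates the full parameter set for a simulated migrating
#' cell: per-end clutch ensemble, myosin motor ensemble, standard-linear-solid
#' substrate, glassy off-time law, and run controls. Units are fixed
#' throughout the package as seconds, nanometers, piconewtons, pN/nm and
#' pN s/nm.
#'
#' The shipped defaults are calibrated to the physiological timescales the
#' model is organized around rather than to any particular raw value set:
#' the motor-stall timescale \eqn{\tau_l = F_{motor} N_m / (V_u k_l)} is
#' ~10 s (so `k_l` defaults to `f_motor * n_motors / (v_u * 10)`), the
#' off-time law spans ~1–100 s for the default `beta`/`tau_min`, and the
#' substrate relaxation timescale \eqn{\tau_s = \eta / k_a} is set via
#' `tau_s` (10 s = fast-relaxing, 1000 s = slow-relaxing).
#'
#' @param n_clutches number of molecular clutches per cell end.
#' @param k_c clutch spring stiffness, pN/nm.
#' @param r_on clutch association rate, 1/s.
#' @param f_bond Bell characteristic rupture force, pN.
#' @param n_motors number of myosin motors per end.
#' @param f_motor single-motor stall force, pN.
#' @param v_u unloaded retrograde flow speed (also the actin polymerization
#'   speed scale used as the nondimensional length unit), nm/s.
#' @param k_l substrate long-term stiffness, pN/nm. Default targets
#'   \eqn{\tau_l = 10} s.
#' @param k_a substrate additional (Maxwell-arm) stiffness, pN/nm. The
#'   default `9 * k_l` gives a substrate that relaxes to 10% of its
#'   instantaneous stiffness, the strong stress relaxation characteristic
#'   of the ionically crosslinked hydrogels the model represents.
#' @param tau_s substrate stress-relaxation timescale \eqn{\eta / k_a},
#'   seconds. Exactly one of `tau_s` or `eta` may be given.
#' @param eta substrate viscosity, pN s/nm (alternative to `tau_s`).
#' @param beta glass coefficient of the off-time power law (> 1).
#' @param tau_min characteristic minimum dissociation time, s.
#' @param off_time_mode `"glassy"` (power-law off times) or `"constant"`
#'   (conventional model, point mass at `tau_min`).
#' @param tau_sampling when and at what level the off-time law is invoked:
#'   `"per_binding"` (default) draws an independent \eqn{\tau_{off}} per
#'   clutch at each binding event; `"per_episode"` treats the whole adhesion
#'   cluster of an end as occupying one glassy configuration at a time,
#'   with a shared \eqn{\tau_{off}} that renews at rate \eqn{1/\tau}
#'   (trap-model dynamics), so one heavy-tailed draw governs each grip
#'   episode.
#' @param tau_max optional truncation of the off-time law (default `Inf`).
#' @param duration simulated time T, s.
#' @param dt integration timestep, s. Default
#'   `min(tau_min/100, 1/(100*r_on), tau_s/10)`: it resolves the fastest
#'   kinetic scale and always satisfies the substrate stability bound
#'   `dt <= tau_s/10`.
#' @param record_interval trajectory sampling interval, s (>= `dt`). The
#'   default 10 s plays the role of an imaging frame interval.
#' @param burn_in equilibration time, s, simulated before recording starts
#'   so that recorded statistics do not carry the artificial all-unbound
#'   initial condition. Default 200 s.
#' @param dimensions 1 or 2 independent migration axes.
#' @param body_drag viscous drag coefficient of the cell body against its
#'   surroundings, pN s/nm; enters the center force balance as
#'   \eqn{T_R - T_L = \zeta V}, so a cell with no engaged adhesions
#'   generates no net motion. Only used with `force_balance = "center"`.
#' @param force_balance `"center"` (default): the two ends of an axis are
#'   coupled through quasi-static force equilibrium at the cell center, so
#'   the transmitted forces are equal and opposite and the cell velocity is
#'   solved each step from that constraint (capped at `v_u`, the speed of
#'   the actin machinery). `"per_end"`: each end's motor load is its own
#'   clutch force and the ends evolve independently.
#' @param center_velocity if `TRUE` (default), the migration velocity is the
#'   cell-center velocity \eqn{(V_r^{left} - V_r^{right})/2}; if `FALSE`, the
#'   bare retrograde-flow difference is used (rescales displacement only,
#'   never the MSD exponent).
#' @return An object of class `"clutch_params"` (a validated named list with
#'   derived fields `eta`, `tau_s`, `tau_l`, `f_stall`, `dt`).
#' @examples
#' p <- clutch_params(tau_s = 10)           # fast-relaxing substrate
#' p$tau_l                                  # motor-stall timescale ~10 s
#' clutch_params(tau_s = 1000, beta = 1.5)  # slow-relaxing, glassy
#' @export
clutch_params <- function(n_clutches = 45,
                          k_c = 0.8,
                          r_on = 1,
                          f_bond = 1.8,
                          n_motors = 50,
                          f_motor = 2,
                          v_u = 120,
                          k_l = f_motor * max(n_motors, 1) / (v_u * 10),
                          k_a = 9 * k_l,
                          tau_s = NULL,
                          eta = NULL,
                          beta = 1.5,
                          tau_min = 1,
                          off_time_mode = c("glassy", "constant"),
                          tau_sampling = c("per_binding", "per_episode"),
                          tau_max = Inf,
                          duration = 2000,
                          dt = NULL,
                          record_interval = 10,
                          burn_in = 200,
                          dimensions = 2,
                          body_drag = 0.1,
                          force_balance = c("center", "per_end"),
                          center_velocity = TRUE) {
  off_time_mode <- match.arg(off_time_mode)
  tau_sampling <- match.arg(tau_sampling)
  force_balance <- match.arg(force_balance)
  if (is.null(tau_s) && is.null(eta)) tau_s <- 10
  if (!is.null(tau_s) && !is.null(eta)) {
    stop("give either 'tau_s' or 'eta', not both (tau_s = eta / k_a)")
  }
  pos1 <- function(v, nm, allow_zero = FALSE) {
    if (!is.numeric(v) || length(v) != 1L || is.na(v) ||
        (if (allow_zero) v < 0 else v <= 0)) {
      stop(sprintf("'%s' must be a single %s number", nm,
                   if (allow_zero) "non-negative" else "positive"))
    }
    v
  }
  n_clutches <- as.integer(pos1(n_clutches, "n_clutches"))
  n_motors <- as.integer(pos1(n_motors, "n_motors", allow_zero = TRUE))
  r_on <- pos1(r_on, "r_on", allow_zero = TRUE)
  for (nm in c("k_c", "f_bond", "f_motor", "v_u", "k_l", "k_a",
               "tau_min", "duration", "record_interval")) {
    assign(nm, pos1(get(nm), nm))
  }
  if (is.null(eta)) {
    tau_s <- pos1(tau_s, "tau_s")
    eta <- tau_s * k_a
  } else {
    eta <- pos1(eta, "eta")
    tau_s <- eta / k_a
  }
  # the off-time constructor validates beta / tau_min / tau_max
  off_dist <- off_time_dist(beta = if (off_time_mode == "glassy") beta else 2,
                            tau_min = tau_min, mode = off_time_mode,
                            tau_max = tau_max)
  if (is.null(dt)) {
    dt <- min(tau_min / 100,
              if (r_on > 0) 1 / (100 * r_on) else Inf,
              tau_s / 10)
  }
  dt <- pos1(dt, "dt")
  if (dt > tau_s / 10) {
    stop(sprintf("dt = %g s violates the substrate stability bound tau_s/10 = %g s",
                 dt, tau_s / 10))
  }
  if (record_interval < dt) stop("'record_interval' must be >= dt")
  if (!is.numeric(burn_in) || length(burn_in) != 1L || is.na(burn_in) ||
      burn_in < 0) {
    stop("'burn_in' must be a single non-negative number")
  }
  if (!dimensions %in% c(1, 2)) stop("'dimensions' must be 1 or 2")
  # note: duration/record_interval >= 64 frames is required by the MSD layer,
  # which refuses shorter tracks; short diagnostic runs are allowed here
  structure(list(
    n_clutches = n_clutches, k_c = k_c, r_on = r_on, f_bond = f_bond,
    n_motors = n_motors, f_motor = f_motor, v_u = v_u,
    k_l = k_l, k_a = k_a, eta = eta, tau_s = tau_s,
    beta = beta, tau_min = tau_min, off_time_mode = off_time_mode,
    tau_sampling = tau_sampling, tau_max = tau_max,
    duration = duration, dt = dt, record_interval = record_interval,
    burn_in = burn_in,
    dimensions = as.integer(dimensions), body_drag = body_drag,
    force_balance = force_balance,
    center_velocity = center_velocity,
    # derived diagnostics
    f_stall = n_motors * f_motor,
    tau_l = if (n_motors > 0) f_motor * n_motors / (v_u * k_l) else 0
  ), class = "clutch_params")
}

#' @export
print.clutch_params <- function(x, ...) {
  cat("Motor-clutch cell parameters\n")
  cat(sprintf("  clutches/end: %d (k_c = %g pN/nm, r_on = %g /s, F_bond = %g pN)\n",
              x$n_clutches, x$k_c, x$r_on, x$f_bond))
  cat(sprintf("  motors/end:   %d x %g pN (F_stall = %g pN), V_u = %g nm/s\n",
              x$n_motors, x$f_motor, x$f_stall, x$v_u))
  cat(sprintf("  substrate:    k_a = %.4g, k_l = %.4g pN/nm, eta = %.4g pN s/nm\n",
              x$k_a, x$k_l, x$eta))
  cat(sprintf("  off times:    %s\n",
              if (x$off_time_mode == "constant")
                sprintf("constant tau_off = %g s", x$tau_min)
              else sprintf("glassy power law (beta = %g, tau_min = %g s)",
                           x$beta, x$tau_min)))
  cat(sprintf("  timescales:   tau_s = %.4g s, tau_l = %.4g s\n",
              x$tau_s, x$tau_l))
  cat(sprintf("  run:          T = %g s, dt = %g s, frame = %g s, %dD\n",
              x$duration, x$dt, x$record_interval, x$dimensions))
  invisible(x)
}

#' Derived timescale diagnostics
#'
#' The three timescales whose ordering organizes the migration phenotype:
#' the motor-stall timescale \eqn{\tau_l = F_{motor} N_m / (V_u k_l)}, the
#' substrate stress-relaxation timescale \eqn{\tau_s = \eta / k_a}, and the
#' span of the clutch dissociation timescale \eqn{\tau_{off}} (its 5th–95th
#' percentile under the configured off-time law).
#'
#' @param params a [clutch_params()] object.
#' @return Named list with `tau_l`, `tau_s`, `tau_off_range` (2-vector).
#' @export
timescales <- function(params) {
  stopifnot(inherits(params, "clutch_params"))
  d <- off_time_dist(beta = if (params$off_time_mode == "glassy") params$beta else 2,
                     tau_min = params$tau_min, mode = params$off_time_mode,
                     tau_max = params$tau_max)
  rng <- if (params$off_time_mode == "constant") {
    c(params$tau_min, params$tau_min)
  } else {
    qofftime(c(0.05, 0.95), d)
  }
  list(tau_l = params$tau_l, tau_s = params$tau_s, tau_off_range = rng)
}

#' Apply an actomyosin-inhibition scenario to a parameter set
#'
#' Scenario modifiers used by the in-silico drug studies:
#' * `"control"` — identity.
#' * `"myosin_inhibited"` — myosin II inhibition, modeled by scaling the
#'   motor count `n_motors` by `myosin_factor`.
#' * `"actin_inhibited"` — actin polymerization inhibition, modeled by
#'   scaling the polymerization/unloaded-flow speed `v_u` by `actin_factor`
#'   and the motor count by `myosin_factor` (depolymerization also weakens
#'   the scaffold myosin contracts against).
#'
#' Either inhibition lowers the motor-stall timescale
#' \eqn{\tau_l = F_{motor} N_m / (V_u k_l)} ... for myosin via \eqn{N_m};
#' actin inhibition lowers force generation at fixed \eqn{\tau_l} ratio,
#' shifting migration toward the trapped, sub-diffusive regime.
#'
#' @param params a [clutch_params()] object.
#' @param scenario one of `"control"`, `"myosin_inhibited"`,
#'   `"actin_inhibited"`.
#' @param myosin_factor multiplicative factor on `n_motors`, in (0, 1].
#' @param actin_factor multiplicative factor on `v_u`, in (0, 1].
#' @return A new `clutch_params` object; attribute `"scenario"` records the
#'   applied scenario.
#' @export
apply_scenario <- function(params, scenario = c("control", "myosin_inhibited",
                                                "actin_inhibited"),
                           myosin_factor = 0.5, actin_factor = 0.5) {
  stopifnot(inherits(params, "clutch_params"))
  scenario <- match.arg(scenario)
  for (f in c(myosin_factor, actin_factor)) {
    if (!is.numeric(f) || length(f) != 1L || is.na(f) || f <= 0 || f > 1) {
      stop("scenario factors must lie in (0, 1]")
    }
  }
  out <- params
  if (scenario == "myosin_inhibited") {
    out <- modify_params(params, n_motors = max(1L, round(params$n_motors * myosin_factor)))
  } else if (scenario == "actin_inhibited") {
    out <- modify_params(params,
                         n_motors = max(1L, round(params$n_motors * myosin_factor)),
                         v_u = params$v_u * actin_factor)
  }
  attr(out, "scenario") <- scenario
  out
}

#' Rebuild a parameter object with some fields replaced
#'
#' Revalidates and recomputes all derived quantities (`eta`, `tau_s`,
#' `tau_l`, `f_stall`, `dt` if it was left at its default).
#'
#' @param params a [clutch_params()] object.
#' @param ... named fields of [clutch_params()] to replace. `tau_s` and
#'   `eta` are mutually exclusive, as in the constructor.
#' @return A new `clutch_params` object.
#' @export
modify_params <- function(params, ...) {
  stopifnot(inherits(params, "clutch_params"))
  repl <- list(...)
  bad <- setdiff(names(repl), names(formals(clutch_params)))
  if (length(bad)) stop("unknown parameter field(s): ", paste(bad, collapse = ", "))
  keep <- c("n_clutches", "k_c", "r_on", "f_bond", "n_motors", "f_motor",
            "v_u", "k_l", "k_a", "beta", "tau_min", "off_time_mode",
            "tau_sampling", "tau_max",
            "duration", "record_interval", "burn_in", "dimensions",
            "body_drag", "force_balance", "center_velocity")
  args <- params[keep]
  # tau_s/eta pair: carry tau_s unless the caller supplies one of them
  if (!("tau_s" %in% names(repl)) && !("eta" %in% names(repl))) {
    args$tau_s <- params$tau_s
  }
  # dt: recompute default unless explicitly pinned
  if ("dt" %in% names(repl)) args$dt <- repl$dt
  args[names(repl)] <- repl
  do.call(clutch_params, args)
}
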