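#' Bell slip-bond dissociation rate
#'
#' Force-dependent unbinding rate of an adhesion clutch,
#' \deqn{r_{off} = \frac{1}{\tau_{off}} \exp\!\left(\frac{|F_c|}{F_{bond}}\right)}
#' where \eqn{F_c} is the clutch spring force and \eqn{F_{bond}} the
#' characteristic rupture force. Clutches are slip bonds under tension: the
#' magnitude of the force is used, so compression is never force-amplified
#' with the opposite sign.
#'
#' @param force clutch force(s) in pN (sign ignored).
#' @param tau_off dissociation time constant(s) in seconds (> 0).
#' @param f_bond characteristic rupture force in pN (> 0).
#' @return Dissociation rate(s) in 1/s, monotone increasing in `|force|`.
#' @examples
#' bell_off_rate(0, tau_off = 5, f_bond = 2)    # unloaded rate 1/tau_off
#' bell_off_rate(2, tau_off = 1, f_bond = 2)    # e-fold amplification
#' @export
bell_off_rate <- function(force, tau_off, f_bond) {
  if (any(!is.finite(tau_off) & !is.infinite(tau_off)) || any(tau_off <= 0)) {
    stop("'tau_off' must be positive")
  }
  if (any(!is.finite(f_bond)) || any(f_bond <= 0)) {
    stop("'f_bond' must be positive and finite")
  }
  exp(abs(force) / f_bond) / tau_off
}

#' Hill-type load-velocity relation for the myosin motor ensemble
#'
#' Retrograde actin flow speed under load:
#' \eqn{V_r = V_u (1 - F_{load}/F_{stall})} with
#' \eqn{F_{stall} = N_m F_{motor}}, clamped to \eqn{[0, V_u]}. With no motors
#' the ensemble generates no flow.
#'
#' @param f_load total load on the motor ensemble in pN (must be >= 0; the
#'   sign convention puts clutch tension as a positive load).
#' @param n_motors number of myosin motors (integer >= 0).
#' @param f_motor single-motor stall force in pN.
#' @param v_u unloaded retrograde flow speed in nm/s.
#' @return Retrograde flow speed in nm/s, in `[0, v_u]`.
#' @export
hill_velocity <- function(f_load, n_motors, f_motor, v_u) {
  if (any(f_load < 0)) {
    stop("'f_load' must be non-negative: upstream sign convention violated")
  }
  if (n_motors == 0) return(rep(0, length(f_load)))
  pmin(pmax(v_u * (1 - f_load / (n_motors * f_motor)), 0), v_u)
}

#' Standard-linear-solid substrate element
#'
#' State container for the three-element viscoelastic substrate: a long-term
#' spring \eqn{k_l} in parallel with a Maxwell arm (spring \eqn{k_a} in series
#' with a dashpot \eqn{\eta}). Displacement \eqn{x_s} and transmitted force
#' \eqn{F_s} obey
#' \deqn{(k_a + k_l)\,\eta\,\dot{x}_s + k_a k_l x_s = k_a F_s + \eta \dot{F}_s}
#' The instantaneous stiffness is \eqn{k_a + k_l}, the long-term stiffness
#' \eqn{k_l}, and the stress-relaxation timescale \eqn{\tau_s = \eta / k_a}.
#'
#' @param k_a additional (Maxwell-arm) stiffness, pN/nm.
#' @param k_l long-term stiffness, pN/nm.
#' @param eta dashpot viscosity, pN s/nm.
#' @param x_s initial substrate displacement, nm.
#' @param f_s initial transmitted force, pN.
#' @return An object of class `"sls_substrate"` with read-only derived
#'   field `tau_s`.
#' @export
sls_substrate <- function(k_a, k_l, eta, x_s = 0, f_s = 0) {
  for (nm in c("k_a", "k_l", "eta")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0) {
      stop(sprintf("'%s' must be a single positive finite number", nm))
    }
  }
  structure(list(k_a = k_a, k_l = k_l, eta = eta,
                 x_s = x_s, f_s = f_s, tau_s = eta / k_a),
            class = "sls_substrate")
}

#' @export
print.sls_substrate <- function(x, ...) {
  cat(sprintf(
    "SLS substrate: k_a = %g pN/nm, k_l = %g pN/nm, eta = %g pN s/nm (tau_s = %g s)\n",
    x$k_a, x$k_l, x$eta, x$tau_s))
  cat(sprintf("  state: x_s = %g nm, F_s = %g pN\n", x$x_s, x$f_s))
  invisible(x)
}

#' Advance the SLS substrate one timestep under a new applied force
#'
#' Semi-implicit (backward Euler in \eqn{x_s}, finite-difference in the force
#' forcing) update of the substrate ODE. The scheme is unconditionally stable
#' for this linear ODE; a conservative bound `dt <= tau_s/10` is still
#' enforced so that the relaxation dynamics are resolved, not merely stable.
#'
#' @param sub an [sls_substrate()] object holding the current state.
#' @param f_s_new total clutch force applied over this step, pN.
#' @param dt timestep, seconds (must satisfy `dt <= tau_s/10`).
#' @return The updated `sls_substrate` with new `x_s` and `f_s`.
#' @export
sls_step <- function(sub, f_s_new, dt) {
  stopifnot(inherits(sub, "sls_substrate"))
  if (dt > sub$tau_s / 10) {
    stop(sprintf(
      "dt = %g s violates the substrate stability bound dt <= tau_s/10 = %g s",
      dt, sub$tau_s / 10))
  }
  A <- (sub$k_a + sub$k_l) * sub$eta / dt
  B <- sub$k_a * sub$k_l
  x_new <- (A * sub$x_s + sub$k_a * f_s_new +
              (sub$eta / dt) * (f_s_new - sub$f_s)) / (A + B)
  sub$x_s <- x_new
  sub$f_s <- f_s_new
  sub
}

#' Stress relaxation of the SLS substrate at fixed displacement
#'
#' Holds the substrate at a fixed displacement `x_fixed` and integrates the
#' force response from an initial force `f0` (backward Euler at timestep
#' `dt`). The force relaxes exponentially toward the long-term value
#' \eqn{k_l x} with e-folding time \eqn{\tau_s = \eta / k_a}; this is the
#' stress-relaxation experiment that defines the substrate's fast/slow
#' character.
#'
#' @param sub an [sls_substrate()] object (its `x_s`/`f_s` state is ignored).
#' @param x_fixed imposed displacement, nm.
#' @param f0 initial force, pN. Defaults to the instantaneous elastic response
#'   `(k_a + k_l) * x_fixed`.
#' @param dt integration timestep, seconds.
#' @param t_end duration, seconds.
#' @return A data.frame with columns `time` (s) and `force` (pN); attribute
#'   `"efold_time"` holds the measured e-folding time of the force excess
#'   over its long-term value (linear interpolation between steps).
#' @export
sls_relaxation <- function(sub, x_fixed, f0 = NULL, dt = sub$tau_s / 100,
                           t_end = 6 * sub$tau_s) {
  stopifnot(inherits(sub, "sls_substrate"))
  if (is.null(f0)) f0 <- (sub$k_a + sub$k_l) * x_fixed
  n <- ceiling(t_end / dt)
  # fixed displacement: eta * dF/dt = k_a k_l x - k_a F  (backward Euler)
  f <- numeric(n + 1L)
  f[1L] <- f0
  r <- sub$eta / dt
  f_inf <- sub$k_l * x_fixed
  for (i in seq_len(n)) {
    f[i + 1L] <- (r * f[i] + sub$k_a * f_inf) / (r + sub$k_a)
  }
  times <- (0:n) * dt
  excess <- f - f_inf
  target <- excess[1L] / exp(1)
  efold <- NA_real_
  idx <- which(excess <= target)
  if (length(idx) > 0 && idx[1L] > 1L) {
    i <- idx[1L]
    # linear interpolation across the crossing
    efold <- times[i - 1L] + dt * (excess[i - 1L] - target) /
      (excess[i - 1L] - excess[i])
  }
  structure(data.frame(time = times, force = f), efold_time = efold)
}

#' Creep response of the SLS substrate under prescribed force
#'
#' Integrates substrate displacement under a (possibly time-varying) applied
#' force using [sls_step()]. Under a constant force \eqn{F}, the displacement
#' jumps instantaneously to \eqn{F/(k_a + k_l)} and creeps toward the
#' long-term value \eqn{F/k_l}.
#'
#' @param sub an [sls_substrate()] object giving parameters and initial state.
#' @param force a single number (constant force, pN) or a function of time
#'   returning the applied force.
#' @param dt timestep, seconds.
#' @param t_end duration, seconds.
#' @return A data.frame with columns `time`, `x_s`, `force`.
#' @export
sls_creep <- function(sub, force, dt = sub$tau_s / 100, t_end = 6 * sub$tau_s) {
  stopifnot(inherits(sub, "sls_substrate"))
  f_fun <- if (is.function(force)) force else function(t) force
  n <- ceiling(t_end / dt)
  out_x <- numeric(n + 1L)
  out_f <- numeric(n + 1L)
  out_x[1L] <- sub$x_s
  out_f[1L] <- sub$f_s
  for (i in seq_len(n)) {
    sub <- sls_step(sub, f_fun(i * dt), dt)
    out_x[i + 1L] <- sub$x_s
    out_f[i + 1L] <- sub$f_s
  }
  data.frame(time = (0:n) * dt, x_s = out_x, force = out_f)
}

#' One Monte Carlo kinetics step for a single clutch
#'
#' Binding/unbinding transition of one clutch over a timestep `dt` using
#' exact exponential survival probabilities: an unbound clutch binds with
#' probability \eqn{1 - e^{-r_{on} dt}}; a bound clutch unbinds with
#' probability \eqn{1 - e^{-r_{off} dt}}. At most one transition occurs per
#' step. On binding the clutch attaches at zero extension (`x_c = x_s`) and a
#' fresh \eqn{\tau_{off}} is drawn from `off_dist`. Uses R's RNG stream.
#'
#' This is the reference single-clutch implementation; the compiled
#' whole-cell engine applies the same update to every clutch each step.
#'
#' @param clutch a list with fields `bound` (logical), `x_c` (nm), `tau_off` (s).
#' @param r_on association rate, 1/s.
#' @param r_off dissociation rate, 1/s (as from [bell_off_rate()]).
#' @param dt timestep, s.
#' @param x_s current substrate displacement, nm.
#' @param off_dist an [off_time_dist()] used to refresh `tau_off` at binding.
#' @return The updated clutch list.
#' @export
clutch_kinetics_step <- function(clutch, r_on, r_off, dt, x_s, off_dist) {
  if (dt <= 0) stop("'dt' must be positive")
  if (!clutch$bound) {
    if (stats::runif(1) < -expm1(-r_on * dt)) {
      clutch$bound <- TRUE
      clutch$x_c <- x_s          # association at zero extension
      clutch$tau_off <- rofftime(1, off_dist)
    }
  } else {
    if (stats::runif(1) < -expm1(-r_off * dt)) {
      clutch$bound <- FALSE
      clutch$x_c <- x_s          # unbound clutch tracks the substrate, force-free
    }
  }
  clutch
}
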