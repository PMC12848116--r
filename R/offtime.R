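#' Power-law distribution of clutch dissociation time constants
#'
#' Constructs the glassy dissociation-time law used to assign a fresh
#' dissociation time constant \eqn{\tau_{off}} to an adhesion clutch each time
#' it binds. The density is a Pareto-type power law on
#' \eqn{[\tau_{min}, \infty)}:
#' \deqn{p(\tau) = \frac{\beta - 1}{\tau_{min}} \left(\frac{\tau}{\tau_{min}}\right)^{-\beta}}
#' where \eqn{\beta > 1} is the glass coefficient and \eqn{\tau_{min}} the
#' characteristic (minimum) dissociation time. Small \eqn{\beta} gives heavy
#' tails: the variance diverges for \eqn{\beta \le 3} and the mean for
#' \eqn{\beta \le 2}, which is the regime where adhesion kinetics become
#' glassy and migration turns anomalous. As \eqn{\beta \to \infty} the law
#' collapses onto \eqn{\tau_{min}}; the conventional constant-off-time model
#' is represented exactly by `mode = "constant"` (a point mass at
#' \eqn{\tau_{min}}), not by a large \eqn{\beta}.
#'
#' @param beta glass coefficient (dimensionless). Must be > 1 so the density
#'   is normalizable; ignored when `mode = "constant"`.
#' @param tau_min characteristic minimum dissociation time in seconds (> 0).
#' @param mode `"glassy"` for the power law, `"constant"` for the degenerate
#'   point mass at `tau_min` (the conventional motor-clutch assumption).
#' @param tau_max optional upper truncation (seconds) for numerical hygiene.
#'   Defaults to `Inf` (untruncated): truncation destroys the heavy tail that
#'   drives anomalous migration, so it is off unless explicitly requested.
#' @return An object of class `"off_time_dist"`.
#' @seealso [dofftime()], [pofftime()], [qofftime()], [rofftime()],
#'   [offtime_moments()]
#' @examples
#' d <- off_time_dist(beta = 1.5, tau_min = 1)
#' rofftime(5, d)
#' offtime_moments(d, 2)  # divergent variance in the glassy regime
#' @export
off_time_dist <- function(beta = 1.5, tau_min = 1,
                          mode = c("glassy", "constant"), tau_max = Inf) {
  mode <- match.arg(mode)
  if (!is.numeric(tau_min) || length(tau_min) != 1L || !is.finite(tau_min) ||
      tau_min <= 0) {
    stop("'tau_min' must be a single positive finite number (seconds)")
  }
  if (mode == "glassy") {
    if (!is.numeric(beta) || length(beta) != 1L || !is.finite(beta) ||
        beta <= 1) {
      stop("'beta' must be a single number > 1: the power law is only ",
           "normalizable on [tau_min, Inf) for beta > 1")
    }
  }
  if (!is.numeric(tau_max) || length(tau_max) != 1L || is.na(tau_max) ||
      tau_max <= tau_min) {
    stop("'tau_max' must be a number > tau_min (possibly Inf)")
  }
  structure(
    list(beta = if (mode == "glassy") beta else Inf,
         tau_min = tau_min, mode = mode, tau_max = tau_max),
    class = "off_time_dist"
  )
}

#' @export
print.off_time_dist <- function(x, ...) {
  if (x$mode == "constant") {
    cat(sprintf("Constant dissociation time: tau_off = %g s\n", x$tau_min))
  } else {
    cat(sprintf(
      "Glassy (power-law) dissociation time: beta = %g, tau_min = %g s%s\n",
      x$beta, x$tau_min,
      if (is.finite(x$tau_max)) sprintf(", truncated at %g s", x$tau_max) else ""
    ))
    m <- offtime_moments(x, 1L)
    v <- offtime_moments(x, 2L)
    cat(sprintf("  mean: %s   variance: %s\n",
                if (m$finite) sprintf("%g s", m$value) else "divergent",
                if (v$finite) sprintf("%g s^2", v$value) else "divergent"))
  }
  invisible(x)
}

# truncation normalizer: P(tau <= tau_max) under the untruncated law
.offtime_trunc_mass <- function(dist) {
  if (!is.finite(dist$tau_max)) return(1)
  1 - (dist$tau_max / dist$tau_min)^(1 - dist$beta)
}

.check_offtime <- function(dist) {
  if (!inherits(dist, "off_time_dist")) {
    stop("'dist' must be an object created by off_time_dist()")
  }
  invisible(dist)
}

#' Density of the dissociation-time power law
#'
#' @param tau vector of times (seconds).
#' @param dist an [off_time_dist()] object.
#' @return Density values (1/seconds); 0 below `tau_min`.
#' @export
dofftime <- function(tau, dist) {
  .check_offtime(dist)
  if (dist$mode == "constant") {
    stop("the constant-off-time mode is a point mass at tau_min and has no density")
  }
  b <- dist$beta
  tmin <- dist$tau_min
  out <- numeric(length(tau))
  ok <- !is.na(tau) & tau >= tmin & tau <= dist$tau_max
  out[ok] <- (b - 1) / tmin * (tau[ok] / tmin)^(-b) / .offtime_trunc_mass(dist)
  out[is.na(tau)] <- NA_real_
  out
}

#' Cumulative distribution of the dissociation-time power law
#'
#' `pofftime(q, dist)` is \eqn{1 - (q/\tau_{min})^{1-\beta}} for
#' \eqn{q \ge \tau_{min}}, 0 below.
#'
#' @param q vector of times (seconds).
#' @inheritParams dofftime
#' @return Probabilities in `[0, 1]`.
#' @export
pofftime <- function(q, dist) {
  .check_offtime(dist)
  out <- numeric(length(q))
  tmin <- dist$tau_min
  if (dist$mode == "constant") {
    out[q >= tmin] <- 1
  } else {
    ok <- !is.na(q) & q >= tmin
    out[ok] <- (1 - (q[ok] / tmin)^(1 - dist$beta)) / .offtime_trunc_mass(dist)
    out <- pmin(out, 1)
  }
  out[is.na(q)] <- NA_real_
  out
}

#' Quantile function (inverse CDF) of the dissociation-time power law
#'
#' @param p vector of probabilities.
#' @inheritParams dofftime
#' @export
qofftime <- function(p, dist) {
  .check_offtime(dist)
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("'p' must lie in [0, 1]")
  if (dist$mode == "constant") return(rep(dist$tau_min, length(p)))
  z <- .offtime_trunc_mass(dist)
  dist$tau_min * (1 - p * z)^(-1 / (dist$beta - 1))
}

#' Sample dissociation time constants
#'
#' Inverse-transform sampling: \eqn{\tau = \tau_{min} u^{-1/(\beta-1)}} with
#' \eqn{u \sim} uniform(0, 1]. Uses R's RNG stream, so draws are reproducible
#' under `set.seed()`. Output is always \eqn{\ge \tau_{min}}.
#'
#' @param n number of draws.
#' @inheritParams dofftime
#' @return Numeric vector of times (seconds).
#' @export
rofftime <- function(n, dist) {
  .check_offtime(dist)
  if (dist$mode == "constant") return(rep(dist$tau_min, n))
  # runif() is in [0, 1); map to (0, 1] so tau = tau_min at u = 1 and the
  # heavy tail (u -> 0) is never hit exactly at 0
  u <- 1 - stats::runif(n)
  if (is.finite(dist$tau_max)) {
    u <- 1 - (1 - u) * .offtime_trunc_mass(dist)
  }
  dist$tau_min * u^(-1 / (dist$beta - 1))
}

#' Moments of the dissociation-time power law
#'
#' Mean is \eqn{\tau_{min}(\beta-1)/(\beta-2)}, finite only for
#' \eqn{\beta > 2}; the variance is finite only for \eqn{\beta > 3}. In the
#' glassy regime (\eqn{\beta \le 3}) the variance diverges — this broken
#' central limit theorem is what makes the migration statistics non-Gaussian —
#' so the return value carries a finiteness flag rather than a number when
#' the moment does not exist.
#'
#' @param dist an [off_time_dist()] object.
#' @param order 1 for the mean, 2 for the variance.
#' @return A list with elements `value` (numeric or `NA` when divergent),
#'   `finite` (logical), and `order`.
#' @export
offtime_moments <- function(dist, order) {
  .check_offtime(dist)
  if (!order %in% c(1L, 2L)) stop("'order' must be 1 (mean) or 2 (variance)")
  if (dist$mode == "constant") {
    return(list(value = if (order == 1L) dist$tau_min else 0,
                finite = TRUE, order = as.integer(order)))
  }
  if (is.finite(dist$tau_max)) {
    # truncated law: all moments finite; integrate the closed forms
    z <- .offtime_trunc_mass(dist)
    b <- dist$beta; a <- dist$tau_min; m <- dist$tau_max
    raw <- function(k) {
      if (abs(b - (k + 1)) < 1e-12) {
        (b - 1) * a^k * log(m / a) / z
      } else {
        (b - 1) / (k + 1 - b) * (m^(k + 1 - b) - a^(k + 1 - b)) * a^(b - 1) / z
      }
    }
    mean_ <- raw(1)
    val <- if (order == 1L) mean_ else raw(2) - mean_^2
    return(list(value = val, finite = TRUE, order = as.integer(order)))
  }
  b <- dist$beta
  tmin <- dist$tau_min
  if (order == 1L) {
    if (b > 2) {
      list(value = tmin * (b - 1) / (b - 2), finite = TRUE, order = 1L)
    } else {
      list(value = NA_real_, finite = FALSE, order = 1L)
    }
  } else {
    if (b > 3) {
      m1 <- tmin * (b - 1) / (b - 2)
      m2 <- tmin^2 * (b - 1) / (b - 3)
      list(value = m2 - m1^2, finite = TRUE, order = 2L)
    } else {
      list(value = NA_real_, finite = FALSE, order = 2L)
    }
  }
}
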