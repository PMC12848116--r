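#' Reference random walks with known diffusivity exponents
#'
#' Generates synthetic 2D tracks whose anomalous-diffusion exponent
#' \eqn{\alpha} is known from theory, for validating the trajectory
#' statistics layer against inputs the simulator did not produce:
#'
#' * `"ballistic"` — straight constant-speed lines; \eqn{\alpha = 2}.
#' * `"brownian"` — i.i.d. Gaussian displacements per frame;
#'   \eqn{\alpha = 1}.
#' * `"ctrw"` — continuous-time random walk: Gaussian jumps separated by
#'   power-law waiting times with tail exponent \eqn{\gamma \in (0, 1)}
#'   (infinite mean wait); ensemble MSD scales as \eqn{t^\gamma}, so
#'   \eqn{\alpha = \gamma =} `target_alpha`. The sub-diffusive phenomenology
#'   of trapped migration.
#' * `"levy"` — Lévy walk: constant-speed flights with power-law durations,
#'   tail exponent \eqn{\gamma \in (1, 2)} (finite mean, infinite variance);
#'   MSD scales as \eqn{t^{3-\gamma}}, so \eqn{\alpha = 3 - \gamma =}
#'   `target_alpha`. The super-diffusive phenomenology of heavy-tailed steps.
#'
#' Heavy-tailed durations are drawn with minimum `frame_interval / 20` so
#' the recorded lags sit in the asymptotic scaling regime rather than the
#' short-time crossover.
#'
#' @param kind walk type, see above.
#' @param n_walkers number of independent tracks.
#' @param n_frames recorded frames per track (excluding frame 0).
#' @param frame_interval frame spacing, s.
#' @param seed integer seed (R RNG; the global RNG state is restored on
#'   exit).
#' @param speed ballistic/Lévy speed, nm/s.
#' @param step_sd per-axis Gaussian step s.d. for Brownian frames and CTRW
#'   jumps, nm.
#' @param target_alpha theoretical exponent for `"ctrw"` (in (0, 1)) and
#'   `"levy"` (in (1, 2)); ignored otherwise.
#' @return A `trajectory_set` with attributes `kind` and
#'   `theoretical_alpha`.
#' @examples
#' w <- reference_walks("brownian", n_walkers = 20, n_frames = 100, seed = 1)
#' attr(w, "theoretical_alpha")
#' @export
reference_walks <- function(kind = c("ballistic", "brownian", "ctrw", "levy"),
                            n_walkers = 200, n_frames = 500,
                            frame_interval = 10, seed = 1,
                            speed = 10, step_sd = 50, target_alpha = NULL) {
  kind <- match.arg(kind)
  if (n_walkers < 1 || n_frames < 2) {
    stop("need at least 1 walker and 2 frames")
  }
  old_seed <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  }
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv())
  })
  set.seed(seed)

  theo <- switch(kind,
    ballistic = 2,
    brownian = 1,
    ctrw = {
      if (is.null(target_alpha)) target_alpha <- 0.5
      if (target_alpha <= 0 || target_alpha >= 1) {
        stop("ctrw 'target_alpha' must lie in (0, 1): the waiting-time tail ",
             "exponent equals the MSD exponent only there")
      }
      target_alpha
    },
    levy = {
      if (is.null(target_alpha)) target_alpha <- 1.5
      if (target_alpha <= 1 || target_alpha >= 2) {
        stop("levy 'target_alpha' must lie in (1, 2): MSD ~ t^(3 - gamma) ",
             "requires a flight-duration tail exponent gamma in (1, 2)")
      }
      target_alpha
    })

  times <- (0:n_frames) * frame_interval
  t_end <- n_frames * frame_interval
  tau0 <- frame_interval / 20      # minimum heavy-tailed duration

  one <- function(w) {
    pos <- switch(kind,
      ballistic = {
        th <- stats::runif(1, 0, 2 * pi)
        cbind(x = speed * times * cos(th), y = speed * times * sin(th))
      },
      brownian = {
        dx <- stats::rnorm(n_frames, sd = step_sd)
        dy <- stats::rnorm(n_frames, sd = step_sd)
        cbind(x = c(0, cumsum(dx)), y = c(0, cumsum(dy)))
      },
      ctrw = {
        gamma <- theo
        ev_t <- numeric(0)
        t <- 0
        while (t <= t_end) {
          t <- t + tau0 * (1 - stats::runif(1))^(-1 / gamma)
          ev_t <- c(ev_t, t)
        }
        n_ev <- length(ev_t)
        jumps_x <- stats::rnorm(n_ev, sd = step_sd)
        jumps_y <- stats::rnorm(n_ev, sd = step_sd)
        # position is piecewise constant: number of completed jumps by t
        k <- findInterval(times, ev_t)
        cbind(x = c(0, cumsum(jumps_x))[k + 1L],
              y = c(0, cumsum(jumps_y))[k + 1L])
      },
      levy = {
        gamma <- 3 - theo
        durs <- numeric(0)
        tot <- 0
        while (tot <= t_end) {
          d <- tau0 * (1 - stats::runif(1))^(-1 / gamma)
          durs <- c(durs, d)
          tot <- tot + d
        }
        th <- stats::runif(length(durs), 0, 2 * pi)
        ends <- cumsum(durs)
        node_x <- c(0, cumsum(speed * durs * cos(th)))
        node_y <- c(0, cumsum(speed * durs * sin(th)))
        node_t <- c(0, ends)
        cbind(x = stats::approx(node_t, node_x, xout = times)$y,
              y = stats::approx(node_t, node_y, xout = times)$y)
      })
    data.frame(cell = w, time = times, x = pos[, 1L], y = pos[, 2L])
  }

  out <- do.call(rbind, lapply(seq_len(n_walkers), one))
  rownames(out) <- NULL
  structure(out, kind = kind, theoretical_alpha = theo, seed = seed,
            class = c("trajectory_set", "data.frame"))
}
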