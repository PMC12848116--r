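#' Simulate migration trajectories of motor-clutch cells
#'
#' `simulate_cell()` integrates one cell; `simulate_ensemble()` integrates
#' `n_cells` independent cells from deterministically derived per-cell RNG
#' streams. Each migration axis couples two opposing cell ends, each with its
#' own clutch ensemble, substrate element and motor ensemble; the migration
#' velocity along an axis is the retrograde-flow difference between the two
#' ends (halved for the cell center, see [clutch_params()]), and the 2D model
#' is two fully independent 1D axes. The position update is
#' \eqn{D(t + \delta t) = D(t) + V_m(t)\,\delta t}.
#'
#' Identical `(params, seed)` always reproduce bit-identical trajectories;
#' the engine uses its own counter-seeded RNG streams, so results do not
#' depend on R's RNG state and cells are order-independent.
#'
#' @param params a [clutch_params()] object.
#' @param seed integer seed (< 2^31).
#' @param n_cells number of independent cells.
#' @param diagnostics if `TRUE`, attach a per-frame trace of the first
#'   cell's first-axis end states (transmitted forces, retrograde flows,
#'   bound-clutch counts) as attribute `"diagnostics"`.
#' @return A `trajectory_set`: a data.frame with columns `cell`, `time` (s),
#'   `x` (nm) and, for 2D runs, `y` (nm), with attributes `params`, `seed`,
#'   and `force_residual` (the largest force-bookkeeping deviation
#'   \eqn{|F_s - \sum k_c (x_{c,i} - x_s)|} observed over the whole run).
#'   `simulate_cell()` returns a set with a single cell.
#' @examples
#' p <- clutch_params(tau_s = 10, duration = 1000, n_clutches = 10,
#'                    record_interval = 10)
#' tr <- simulate_cell(p, seed = 1)
#' head(tr)
#' @export
simulate_cell <- function(params, seed, diagnostics = FALSE) {
  simulate_ensemble(params, n_cells = 1L, seed = seed,
                    diagnostics = diagnostics)
}

#' @rdname simulate_cell
#' @export
simulate_ensemble <- function(params, n_cells, seed, diagnostics = FALSE) {
  stopifnot(inherits(params, "clutch_params"))
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("'seed' must be a single integer")
  }
  if (n_cells < 1) stop("'n_cells' must be >= 1")
  n_cells <- as.integer(n_cells)
  pieces <- vector("list", n_cells)
  resid <- 0
  diag_df <- NULL
  for (i in seq_len(n_cells)) {
    raw <- cpp_simulate_cell(unclass(params), as.double(seed),
                             as.double(i - 1L), params$dimensions,
                             params$duration, params$record_interval,
                             params$burn_in,
                             params$force_balance == "center",
                             isTRUE(diagnostics) && i == 1L)
    df <- data.frame(cell = i, time = raw$times, x = raw$pos[, 1L])
    if (params$dimensions == 2L) df$y <- raw$pos[, 2L]
    pieces[[i]] <- df
    resid <- max(resid, raw$force_residual)
    if (isTRUE(diagnostics) && i == 1L && nrow(raw$diag)) {
      diag_df <- data.frame(time = raw$times,
                            f_s_left = raw$diag[, 1L],
                            f_s_right = raw$diag[, 2L],
                            v_r_left = raw$diag[, 3L],
                            v_r_right = raw$diag[, 4L],
                            n_bound_left = raw$diag[, 5L],
                            n_bound_right = raw$diag[, 6L])
    }
  }
  out <- do.call(rbind, pieces)
  rownames(out) <- NULL
  out <- structure(out,
                   params = params, seed = seed, force_residual = resid,
                   class = c("trajectory_set", "data.frame"))
  if (!is.null(diag_df)) attr(out, "diagnostics") <- diag_df
  out
}

#' @export
print.trajectory_set <- function(x, ...) {
  n_cells <- length(unique(x$cell))
  n_frames <- sum(x$cell == x$cell[1L])
  cat(sprintf("Trajectory set: %d cell(s) x %d frames (%s)\n",
              n_cells, n_frames,
              if ("y" %in% names(x)) "2D" else "1D"))
  p <- attr(x, "params")
  if (!is.null(p)) {
    cat(sprintf("  %s model, tau_s = %g s, frame interval = %g s, seed = %s\n",
                p$off_time_mode, p$tau_s, p$record_interval,
                format(attr(x, "seed"))))
  }
  print.data.frame(utils::head(as.data.frame(x), 6L))
  if (nrow(x) > 6L) cat(sprintf("  ... %d more rows\n", nrow(x) - 6L))
  invisible(x)
}

#' Diagnostic simulation of a single cell end
#'
#' Runs one clutch-ensemble/substrate/motor module in isolation and records
#' its internal state: transmitted force \eqn{F_s}, retrograde flow
#' \eqn{V_r}, bound-clutch count and substrate displacement. Useful for
#' inspecting load-and-fail cycling, stall dynamics, and steady-state clutch
#' occupancy without the whole-cell layer.
#'
#' @param params a [clutch_params()] object.
#' @param seed integer seed.
#' @param duration simulated time, s (defaults to `params$duration`).
#' @param record_every record the state every this many timesteps.
#' @return A data.frame with columns `time`, `f_s` (pN), `v_r` (nm/s),
#'   `x_s` (nm), `n_bound`; attribute `force_residual` as in
#'   [simulate_cell()].
#' @export
simulate_end <- function(params, seed, duration = params$duration,
                         record_every = 1L) {
  stopifnot(inherits(params, "clutch_params"))
  raw <- cpp_simulate_end(unclass(params), as.double(seed), 0,
                          duration, as.integer(record_every))
  structure(
    data.frame(time = raw$times, f_s = raw$f_s, v_r = raw$v_r,
               x_s = raw$x_s, n_bound = raw$n_bound),
    force_residual = raw$force_residual)
}

# --- internal trajectory helpers used across the statistics layer ---------

# validate/coerce anything trajectory-like into a canonical data.frame with
# columns cell, time, x[, y]
.as_traj_df <- function(trajs) {
  df <- as.data.frame(trajs)
  if (!"cell" %in% names(df)) df$cell <- 1L
  need <- c("time", "x")
  if (!all(need %in% names(df))) {
    stop("trajectories need columns 'time' and 'x' (plus optional 'y', 'cell')")
  }
  df
}

# list of per-cell position matrices (frames x dims), checking uniform,
# strictly increasing frame times
.traj_split <- function(trajs, require_uniform = TRUE) {
  df <- .as_traj_df(trajs)
  dims <- if ("y" %in% names(df)) c("x", "y") else "x"
  fac <- factor(df$cell, levels = unique(df$cell))
  out <- lapply(split(df, fac), function(d) {
    if (is.unsorted(d$time, strictly = TRUE)) {
      stop("trajectory times must be strictly increasing within each cell")
    }
    dt <- diff(d$time)
    if (require_uniform && length(dt) > 1L &&
        max(abs(dt - dt[1L])) > 1e-8 * max(dt[1L], 1)) {
      stop("non-uniform frame spacing: resample the trajectory first")
    }
    list(pos = as.matrix(d[, dims, drop = FALSE]),
         times = d$time,
         dt = if (length(dt)) dt[1L] else NA_real_)
  })
  names(out) <- NULL
  out
}

#' Nondimensionalize a trajectory set
#'
#' Rescales times by the clutch association timescale \eqn{1/r_{on}} and
#' lengths by \eqn{v_p / r_{on}} (with the polymerization speed \eqn{v_p}
#' taken as the unloaded flow scale `v_u`), the natural units of the
#' motor-clutch module.
#'
#' @param trajs a `trajectory_set` from [simulate_ensemble()].
#' @param params parameters used to produce it (defaults to the attached
#'   attribute).
#' @return A `trajectory_set` in nondimensional units.
#' @export
nondimensionalize <- function(trajs, params = attr(trajs, "params")) {
  if (is.null(params)) stop("'params' required (none attached to 'trajs')")
  df <- .as_traj_df(trajs)
  df$time <- df$time * params$r_on
  len <- params$v_u / params$r_on
  df$x <- df$x / len
  if ("y" %in% names(df)) df$y <- df$y / len
  structure(df, params = params, seed = attr(trajs, "seed"),
            class = c("trajectory_set", "data.frame"))
}
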