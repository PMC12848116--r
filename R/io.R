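#' Read and write trajectory tables
#'
#' The canonical on-disk trajectory format is a plain CSV with header
#' `cell_id, t_s, x_nm, y_nm` (gzip-compressed transparently when the path
#' ends in `.gz`). Writing then reading reproduces the values to full
#' precision, and times are validated as strictly increasing within each
#' cell on read.
#'
#' @param trajs a `trajectory_set` or compatible data.frame. 1D sets are
#'   written with `y_nm = 0`.
#' @param path file path (`.csv` or `.csv.gz`).
#' @return `read_trajectories()` returns a `trajectory_set`;
#'   `write_trajectories()` returns `path` invisibly.
#' @export
write_trajectories <- function(trajs, path) {
  df <- .as_traj_df(trajs)
  out <- data.frame(cell_id = df$cell, t_s = df$time, x_nm = df$x,
                    y_nm = if ("y" %in% names(df)) df$y else 0)
  con <- if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
  on.exit(close(con))
  utils::write.csv(format(out, digits = 17, trim = TRUE, scientific = FALSE),
                   con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_trajectories
#' @export
read_trajectories <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("cell_id", "t_s", "x_nm", "y_nm")
  if (!all(need %in% names(df))) {
    stop("trajectory CSV must have header: ", paste(need, collapse = ", "))
  }
  for (cl in c("t_s", "x_nm", "y_nm")) {
    v <- suppressWarnings(as.numeric(df[[cl]]))
    bad <- which(is.na(v) & !is.na(df[[cl]]))
    if (length(bad)) {
      stop(sprintf("malformed value in column '%s' at data row %d of %s",
                   cl, bad[1L], path))
    }
    if (anyNA(v)) {
      stop(sprintf("missing value in column '%s' at data row %d of %s",
                   cl, which(is.na(v))[1L], path))
    }
    df[[cl]] <- v
  }
  out <- data.frame(cell = df$cell_id, time = df$t_s, x = df$x_nm,
                    y = df$y_nm)
  for (cl in split(seq_len(nrow(out)), factor(out$cell, unique(out$cell)))) {
    if (is.unsorted(out$time[cl], strictly = TRUE)) {
      stop(sprintf("times not strictly increasing for cell '%s' in %s",
                   out$cell[cl[1L]], path))
    }
  }
  structure(out, class = c("trajectory_set", "data.frame"))
}

#' Load a simulation configuration file
#'
#' Reads a YAML configuration with flat key-value sections and resolves it
#' into a validated [clutch_params()] object plus run/scenario/sweep
#' settings. All keys are optional (an empty config yields the shipped
#' defaults); unknown sections or keys are rejected with a descriptive
#' error, as are out-of-range values (e.g. `beta <= 1`, negative
#' stiffnesses).
#'
#' Recognized sections and keys:
#' * `clutches`: `n_clutches`, `k_c`, `r_on`, `f_bond`
#' * `motors`: `n_motors`, `f_motor`, `v_u`
#' * `substrate`: `k_a`, `k_l`, and `tau_s` or `eta` (mutually exclusive;
#'   `tau_s = eta / k_a`)
#' * `glassy`: `beta`, `tau_min`, `off_time_mode` (`glassy`/`constant`),
#'   `tau_max`
#' * `cell`: `dimensions`, `center_velocity`
#' * `run`: `duration`, `dt`, `record_interval`, `seed`, `n_cells`
#' * `scenario`: `name` (`control`/`myosin_inhibited`/`actin_inhibited`),
#'   `myosin_factor`, `actin_factor`
#' * `sweep`: `beta` (list), `tau_s` (list), `reps`
#'
#' @param path path to the YAML file.
#' @return A list of class `"clutch_config"` with elements `params` (a
#'   [clutch_params()], scenario already applied), `seed`, `n_cells`,
#'   `scenario`, `sweep`, and `timescales` (the resolved diagnostic
#'   timescales, see [timescales()]).
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg)) cfg <- list()
  if (!is.list(cfg)) stop("config must be a YAML mapping of sections")

  allowed <- list(
    clutches = c("n_clutches", "k_c", "r_on", "f_bond"),
    motors = c("n_motors", "f_motor", "v_u"),
    substrate = c("k_a", "k_l", "tau_s", "eta"),
    glassy = c("beta", "tau_min", "off_time_mode", "tau_max"),
    cell = c("dimensions", "center_velocity"),
    run = c("duration", "dt", "record_interval", "seed", "n_cells"),
    scenario = c("name", "myosin_factor", "actin_factor"),
    sweep = c("beta", "tau_s", "reps")
  )
  bad_sec <- setdiff(names(cfg), names(allowed))
  if (length(bad_sec)) {
    stop("unknown config section(s): ", paste(bad_sec, collapse = ", "))
  }
  for (sec in names(cfg)) {
    bad <- setdiff(names(cfg[[sec]]), allowed[[sec]])
    if (length(bad)) {
      stop(sprintf("unknown key(s) in section '%s': %s", sec,
                   paste(bad, collapse = ", ")))
    }
  }

  par_args <- c(as.list(cfg$clutches), as.list(cfg$motors),
                as.list(cfg$substrate), as.list(cfg$glassy),
                as.list(cfg$cell),
                as.list(cfg$run[intersect(names(cfg$run),
                                          c("duration", "dt",
                                            "record_interval"))]))
  if (is.null(par_args)) par_args <- list()
  # k_a defaults to k_l: if only k_l given, recompute both through the
  # constructor's own default chain
  params <- do.call(clutch_params, par_args)

  scen <- cfg$scenario$name %||% "control"
  params <- apply_scenario(params, scen,
                           myosin_factor = cfg$scenario$myosin_factor %||% 0.5,
                           actin_factor = cfg$scenario$actin_factor %||% 0.5)

  sweep <- NULL
  if (!is.null(cfg$sweep)) {
    sweep <- list(beta = as.numeric(unlist(cfg$sweep$beta %||% c(1.5, 3, 10))),
                  tau_s = as.numeric(unlist(cfg$sweep$tau_s %||%
                                              c(0.1, 1, 10, 100, 1000))),
                  reps = as.integer(cfg$sweep$reps %||% 20L))
  }

  structure(list(params = params,
                 seed = as.integer(cfg$run$seed %||% 1L),
                 n_cells = as.integer(cfg$run$n_cells %||% 100L),
                 scenario = scen,
                 sweep = sweep,
                 timescales = timescales(params)),
            class = "clutch_config")
}

#' @export
print.clutch_config <- function(x, ...) {
  cat(sprintf("Simulation configuration (scenario: %s, %d cells, seed %d)\n",
              x$scenario, x$n_cells, x$seed))
  ts <- x$timescales
  cat(sprintf("  timescales: tau_l = %.3g s, tau_s = %.3g s, tau_off 5-95%%: %.3g-%.3g s\n",
              ts$tau_l, ts$tau_s, ts$tau_off_range[1], ts$tau_off_range[2]))
  print(x$params)
  if (!is.null(x$sweep)) {
    cat(sprintf("  sweep: beta in {%s} x tau_s in {%s}, %d reps\n",
                paste(x$sweep$beta, collapse = ", "),
                paste(x$sweep$tau_s, collapse = ", "), x$sweep$reps))
  }
  invisible(x)
}
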