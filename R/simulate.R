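#' Sample per-cell ground-truth parameters
#'
#' Draws `n` cells from the lognormal population model under a scenario:
#' `k` lognormal around the scenario-adjusted geometric mean, `tau - t0`
#' lognormal, `t0` Gaussian truncated at zero, and a per-cell death threshold
#' lognormal around `theta_pop * theta_multiplier`. Fate follows the
#' threshold rule: a cell dies iff `2 k (tau - t0) >= theta_cell`, in which
#' case `death_time = tau`. Survivors whose `tau` exceeds the analysis
#' horizon are censored at the horizon.
#'
#' @param params a [population_params()] object.
#' @param scn a [scenario()] object.
#' @param n number of cells (>= 1).
#' @param seed optional integer seed.
#' @return Data frame with one row per cell: `cell_id`, `condition`,
#'   `k_true`, `t0_true`, `tau_true`, `theta_cell`, `fate`
#'   (`"died"`/`"survived"`), `death_time` (`NA` for survivors).
#' @export
sample_cells <- function(params, scn, n, seed = NULL) {
  stopifnot("n must be a positive count" = is.numeric(n) && n >= 1)
  n <- as.integer(n)
  if (!is.null(seed)) set.seed(seed)

  gm_k <- scenario_gm_k(params, scn)
  gm_dt <- params$gm_tau_minus_t0 * scn$tau_multiplier
  gm_theta <- params$theta_pop * scn$theta_multiplier

  k <- 10^(log10(gm_k) + params$sigma_k * stats::rnorm(n))
  dt <- 10^(log10(gm_dt) + params$sigma_tau * stats::rnorm(n))
  theta <- 10^(log10(gm_theta) + params$sigma_theta * stats::rnorm(n))
  t0 <- rnorm_trunc0(n, params$t0_mean, params$t0_sd)

  tau <- t0 + dt
  died <- 2 * k * (tau - t0) >= theta
  death_time <- ifelse(died, tau, NA_real_)
  # censor surviving cells at the analysis horizon
  tau <- ifelse(!died & tau > params$horizon, params$horizon, tau)

  data.frame(cell_id = sprintf("c%04d", seq_len(n)),
             condition = scn$label,
             k_true = k, t0_true = t0, tau_true = tau, theta_cell = theta,
             fate = ifelse(died, "died", "survived"),
             death_time = death_time,
             stringsAsFactors = FALSE)
}

# truncated-at-zero normal via rejection (truncation mass is tiny for the
# default 20 +/- 5 min lag)
rnorm_trunc0 <- function(n, mean, sd) {
  x <- stats::rnorm(n, mean, sd)
  bad <- which(x < 0)
  while (length(bad)) {
    x[bad] <- stats::rnorm(length(bad), mean, sd)
    bad <- bad[x[bad] < 0]
  }
  x
}

#' Render one cell's FRET-ratio trajectory
#'
#' Evaluates the phenomenological reporter model on the imaging grid:
#' `FR(t) = 0` before the lag `t0`, rises as `k (t - t0)^2` until `tau`, and
#' for survivors the derivative then decays exponentially with time constant
#' `decay_tc` so that FR plateaus (or, with `suppress_decay`, keeps rising at
#' the peak rate). Dying cells are truncated at `death_time`. Gaussian
#' measurement noise with SD `noise_sd` is added to every retained sample.
#'
#' @param cell a one-row data frame as produced by [sample_cells()].
#' @param params a [population_params()] object.
#' @param seed optional integer seed (the noise is the only random part).
#' @param suppress_decay plateau of the post-peak derivative instead of decay
#'   (proteasome-inhibition phenotype).
#' @return Data frame `cell_id`, `time_min`, `fret_ratio`.
#' @export
render_trajectory <- function(cell, params, seed = NULL,
                              suppress_decay = FALSE) {
  if (!is.null(seed)) set.seed(seed)
  tg <- seq(0, params$record_length, by = params$frame_interval)
  if (cell$fate == "died") tg <- tg[tg <= cell$death_time]
  fr <- model_fr(tg, cell$k_true, cell$t0_true, cell$tau_true,
                 decay_tc = params$decay_tc,
                 suppress_decay = suppress_decay)
  if (params$noise_sd > 0)
    fr <- fr + stats::rnorm(length(tg), 0, params$noise_sd)
  data.frame(cell_id = cell$cell_id, time_min = tg, fret_ratio = fr,
             stringsAsFactors = FALSE)
}

# noise-free reporter model; vectorised over t
model_fr <- function(t, k, t0, tau, decay_tc = 90, suppress_decay = FALSE) {
  fr <- numeric(length(t))
  rise <- t >= t0 & t <= tau
  fr[rise] <- k * (t[rise] - t0)^2
  post <- t > tau
  if (any(post)) {
    peak_fr <- k * (tau - t0)^2
    peak_d <- 2 * k * (tau - t0)
    if (suppress_decay) {
      fr[post] <- peak_fr + peak_d * (t[post] - tau)
    } else {
      fr[post] <- peak_fr +
        peak_d * decay_tc * (1 - exp(-(t[post] - tau) / decay_tc))
    }
  }
  fr
}

#' Generate a complete synthetic dataset
#'
#' Composes [sample_cells()] and [render_trajectory()] into a reproducible
#' trajectory set: per-cell ground truth plus long-format trajectories,
#' fully determined by `(params, scn, n, seed)`.
#'
#' @inheritParams sample_cells
#' @return An object of class `trajectory_set`: list with elements `cells`
#'   (ground-truth data frame), `trajectories` (long data frame
#'   `cell_id`, `time_min`, `fret_ratio`), `params`, `scenario`, `n`, `seed`.
#' @examples
#' p <- calibrate_population()
#' ts <- generate_dataset(p, scenario("TRAIL 25", "25"), n = 20, seed = 1)
#' table(ts$cells$fate)
#' @export
generate_dataset <- function(params, scn, n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  cells <- sample_cells(params, scn, n, seed = NULL)
  trajs <- lapply(seq_len(n), function(i)
    render_trajectory(cells[i, ], params, seed = NULL,
                      suppress_decay = scn$suppress_decay))
  structure(list(cells = cells, trajectories = do.call(rbind, trajs),
                 params = params, scenario = scn, n = n, seed = seed),
            class = "trajectory_set")
}

#' @export
print.trajectory_set <- function(x, ...) {
  cat(sprintf("Trajectory set: %d cells, scenario '%s'%s\n", x$n,
              x$scenario$label,
              if (is.null(x$seed)) "" else sprintf(", seed %d", x$seed)))
  print(table(fate = x$cells$fate))
  invisible(x)
}

#' Write / read a trajectory set as CSV
#'
#' `write_dataset()` writes `trajectories.csv` (`cell_id`, `time_min`,
#' `fret_ratio`) and `cells.csv` (`cell_id`, `condition`, `fate`,
#' `death_time_min`, plus ground-truth columns for synthetic data) into a
#' directory; `read_dataset()` reads them back into plain data frames.
#'
#' @param ts a `trajectory_set` (or a list with `cells` and `trajectories`).
#' @param dir output / input directory.
#' @return `write_dataset()` the directory, invisibly; `read_dataset()` a
#'   list with `trajectories` and `cells` data frames.
#' @export
write_dataset <- function(ts, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(ts$trajectories, file.path(dir, "trajectories.csv"),
                   row.names = FALSE)
  cells <- ts$cells
  names(cells)[names(cells) == "death_time"] <- "death_time_min"
  utils::write.csv(cells, file.path(dir, "cells.csv"), row.names = FALSE)
  invisible(dir)
}

#' @rdname write_dataset
#' @export
read_dataset <- function(dir) {
  trajs <- utils::read.csv(file.path(dir, "trajectories.csv"),
                           stringsAsFactors = FALSE)
  cells <- utils::read.csv(file.path(dir, "cells.csv"),
                           stringsAsFactors = FALSE)
  names(cells)[names(cells) == "death_time_min"] <- "death_time"
  list(trajectories = trajs, cells = cells)
}
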