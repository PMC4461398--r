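#' Fit the C8 activation model to a set of single-cell trajectories
#'
#' The central fitting routine: for every cell it preprocesses the
#' FRET-ratio trajectory (control subtraction, zero-phase smoothing,
#' baseline shift, smoothed derivative), locates the derivative maximum
#' `tau`, and fits the constrained one-sided quadratic
#' `FR(t) = k (t - t0)^2` on `[0, tau]` with secondary-maximum retry, F-test
#' fallback to the floor rate, and early-death discard rules.
#'
#' @param trajectories long-format data frame with columns `cell_id`,
#'   `time_min`, `fret_ratio`, or a `trajectory_set` from
#'   [generate_dataset()] (in which case `cells` is taken from it).
#' @param cells data frame with columns `cell_id`, `fate`
#'   (`"died"`/`"survived"`) and optionally `death_time` (min) and
#'   `condition`.
#' @param control optional control-mean data frame (`time_min`,
#'   `fret_ratio`) subtracted from every trajectory.
#' @param window smoothing window, frames.
#' @param horizon analysis-window end, min.
#' @param k_max,t0_min,t0_margin,r2_retry,alpha,k_floor,early_death
#'   fitting constants, see [fit_cell()].
#' @param keep_prep keep per-cell preprocessed series in the returned object
#'   (needed by `predict`/`residuals`/`simulate` methods).
#'
#' @return An object of class `c8_fit` with elements `fits` (one row per
#'   cell: identifiers, fate, fitted `k`, `t0`, `tau`, `r2`, `f_pvalue`,
#'   `fallback`, `max_c8`, `window_end_used`, `discarded`,
#'   `discard_reason`), `prep` (if kept), and `config`.
#' @examples
#' p <- calibrate_population()
#' ts <- generate_dataset(p, scenario("TRAIL 25", "25"), n = 10, seed = 1)
#' fit <- c8_fit(ts)
#' summary(fit)
#' @export
c8_fit <- function(trajectories, cells = NULL, control = NULL,
                   window = 11L, horizon = 600, k_max = 0.01, t0_min = -30,
                   t0_margin = 30, r2_retry = 0.5, alpha = 0.05,
                   k_floor = 1e-7, early_death = 70, keep_prep = TRUE) {
  if (inherits(trajectories, "trajectory_set")) {
    if (is.null(cells)) cells <- trajectories$cells
    trajectories <- trajectories$trajectories
  }
  need <- c("cell_id", "time_min", "fret_ratio")
  if (!all(need %in% names(trajectories)))
    stop("trajectories must have columns ", paste(need, collapse = ", "))
  if (is.null(cells) || !all(c("cell_id", "fate") %in% names(cells)))
    stop("cells must have columns cell_id and fate")
  if (!"death_time" %in% names(cells)) cells$death_time <- NA_real_
  if (!"condition" %in% names(cells)) cells$condition <- "all"

  traj_split <- split(trajectories[c("time_min", "fret_ratio")],
                      trajectories$cell_id)
  missing_traj <- setdiff(cells$cell_id, names(traj_split))
  if (length(missing_traj))
    stop("no trajectory for cell(s): ",
         paste(utils::head(missing_traj, 5), collapse = ", "))

  preps <- vector("list", nrow(cells))
  names(preps) <- cells$cell_id
  rows <- vector("list", nrow(cells))
  for (i in seq_len(nrow(cells))) {
    tr <- traj_split[[cells$cell_id[i]]]
    prep <- preprocess_cell(tr$time_min, tr$fret_ratio,
                            control_times = control$time_min,
                            control_fr = control$fret_ratio,
                            death_time = cells$death_time[i],
                            window = window, horizon = horizon)
    fit <- fit_cell(prep, k_max = k_max, t0_min = t0_min,
                    t0_margin = t0_margin, window = window,
                    r2_retry = r2_retry, alpha = alpha, k_floor = k_floor,
                    early_death = early_death)
    rows[[i]] <- cbind(cells[i, c("cell_id", "condition", "fate",
                                  "death_time")],
                       fit, row.names = NULL)
    preps[[i]] <- prep
  }
  fits <- do.call(rbind, rows)
  rownames(fits) <- NULL
  structure(list(fits = fits,
                 prep = if (keep_prep) preps else NULL,
                 config = list(window = window, horizon = horizon,
                               k_max = k_max, t0_min = t0_min,
                               t0_margin = t0_margin, r2_retry = r2_retry,
                               alpha = alpha, k_floor = k_floor,
                               early_death = early_death)),
            class = "c8_fit")
}

#' @export
print.c8_fit <- function(x, ...) {
  f <- x$fits
  kept <- f[!f$discarded, ]
  cat(sprintf("C8 activation model fit: %d cells (%d discarded, %d fallback)\n",
              nrow(f), sum(f$discarded), sum(kept$fallback)))
  if (nrow(kept)) {
    cat(sprintf("  geometric-mean k: %.3g a.u./min^2;  mean t0: %.1f min;  mean tau: %.0f min\n",
                10^mean(log10(kept$k)), mean(kept$t0[!kept$fallback]),
                mean(kept$tau)))
    cat(sprintf("  fraction r2 > 0.9: %.2f\n", mean(kept$r2 > 0.9)))
  }
  invisible(x)
}

#' @export
summary.c8_fit <- function(object, ...) {
  f <- object$fits
  kept <- f[!f$discarded, ]
  out <- list(
    n_cells = nrow(f),
    n_discarded = sum(f$discarded),
    n_fallback = sum(kept$fallback),
    fate_table = table(kept$fate),
    geomean_k = 10^mean(log10(kept$k)),
    mean_t0 = mean(kept$t0[!kept$fallback]),
    mean_tau = mean(kept$tau),
    frac_r2_09 = mean(kept$r2 > 0.9),
    quantiles_k = stats::quantile(kept$k, c(0.1, 0.5, 0.9)),
    conditions = unique(f$condition)
  )
  class(out) <- "summary.c8_fit"
  out
}

#' @export
print.summary.c8_fit <- function(x, ...) {
  cat(sprintf("Cells: %d (%d discarded, %d fallback)\n", x$n_cells,
              x$n_discarded, x$n_fallback))
  print(x$fate_table)
  cat(sprintf("GM k = %.3g a.u./min^2 (10-90%%: %.3g - %.3g)\n",
              x$geomean_k, x$quantiles_k[1], x$quantiles_k[3]))
  cat(sprintf("mean t0 = %.1f min; mean tau = %.0f min; r2>0.9: %.1f%%\n",
              x$mean_t0, x$mean_tau, 100 * x$frac_r2_09))
  invisible(x)
}

#' @export
coef.c8_fit <- function(object, ...) {
  f <- object$fits[!object$fits$discarded, ]
  m <- as.matrix(f[c("k", "t0", "tau", "max_c8")])
  rownames(m) <- f$cell_id
  m
}

#' Fitted model curves
#'
#' Evaluates each cell's fitted one-sided quadratic (plus its baseline
#' nuisance) on the fit window grid.
#'
#' @param object a `c8_fit` (fitted with `keep_prep = TRUE`).
#' @param cell_ids cells to evaluate (default: all non-discarded).
#' @param ... unused.
#' @return Long data frame `cell_id`, `time_min`, `fitted`.
#' @export
predict.c8_fit <- function(object, cell_ids = NULL, ...) {
  if (is.null(object$prep))
    stop("refit with keep_prep = TRUE to use predict()")
  f <- object$fits[!object$fits$discarded, ]
  if (!is.null(cell_ids)) f <- f[f$cell_id %in% cell_ids, ]
  out <- lapply(seq_len(nrow(f)), function(i) {
    prep <- object$prep[[f$cell_id[i]]]
    keep <- prep$times <= f$tau[i] + 1e-9
    data.frame(cell_id = f$cell_id[i], time_min = prep$times[keep],
               fitted = f$k[i] * pmax(prep$times[keep] - f$t0[i], 0)^2 +
                 f$baseline[i],
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' @export
residuals.c8_fit <- function(object, ...) {
  if (is.null(object$prep))
    stop("refit with keep_prep = TRUE to use residuals()")
  f <- object$fits[!object$fits$discarded, ]
  w <- object$config$window
  out <- lapply(seq_len(nrow(f)), function(i) {
    prep <- object$prep[[f$cell_id[i]]]
    keep <- prep$times <= f$tau[i] + 1e-9
    y <- suppressWarnings(smooth_zero_phase(prep$fr_sub[keep], w))
    y <- baseline_shift(as.numeric(y))
    m <- pmax(prep$times[keep] - f$t0[i], 0)^2
    if (length(m) >= w) m <- smooth_zero_phase(m, w)
    data.frame(cell_id = f$cell_id[i], time_min = prep$times[keep],
               residual = y - f$k[i] * m - f$baseline[i],
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Activity landscape plot
#'
#' Scatter of the fitted cells in the `(log10 k, tau)` landscape, coloured
#' by observed fate, with the analytic fate boundary
#' `tau = theta / (2 k) + t0_bar` overlaid when a threshold is supplied.
#'
#' @param x a `c8_fit`.
#' @param theta death threshold to draw the boundary (a.u. min^-1), or
#'   `NULL`.
#' @param t0_bar population mean lag for the boundary, min.
#' @param ... passed to [graphics::plot()].
#' @export
plot.c8_fit <- function(x, theta = NULL, t0_bar = 20, ...) {
  f <- x$fits[!x$fits$discarded, ]
  col <- ifelse(f$fate == "died", "#d9a514", "#3366cc")
  pch <- ifelse(f$fate == "died", 16, 4)
  graphics::plot(log10(f$k), f$tau, col = col, pch = pch,
                 xlab = expression(log[10] ~ k ~ "(a.u."~min^-2*")"),
                 ylab = expression(tau ~ "(min)"), ...)
  if (!is.null(theta)) {
    kk <- 10^seq(min(log10(f$k)), max(log10(f$k)), length.out = 200)
    graphics::lines(log10(kk), theta / (2 * kk) + t0_bar, col = "red",
                    lwd = 2)
  }
  graphics::legend("topright", legend = c("died", "survived"),
                   col = c("#d9a514", "#3366cc"), pch = c(16, 4), bty = "n")
  invisible(x)
}

#' Simulate reporter trajectories from fitted parameters
#'
#' Parametric resimulation: renders each non-discarded cell's fitted
#' `(k, t0, tau)` through the reporter model and adds Gaussian noise with
#' the SD estimated from the fit residuals. Useful for posterior-predictive
#' style checks of the model class.
#'
#' @param object a `c8_fit` (fitted with `keep_prep = TRUE`).
#' @param nsim number of replicate datasets.
#' @param seed optional seed.
#' @param ... unused.
#' @return A list of `nsim` long data frames (`cell_id`, `time_min`,
#'   `fret_ratio`).
#' @export
simulate.c8_fit <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  res <- residuals(object)
  noise_sd <- stats::sd(res$residual)
  f <- object$fits[!object$fits$discarded, ]
  one <- function() {
    out <- lapply(seq_len(nrow(f)), function(i) {
      prep <- object$prep[[f$cell_id[i]]]
      fr <- model_fr(prep$times, f$k[i], f$t0[i], f$tau[i])
      data.frame(cell_id = f$cell_id[i], time_min = prep$times,
                 fret_ratio = fr + stats::rnorm(length(prep$times), 0,
                                                noise_sd),
                 stringsAsFactors = FALSE)
    })
    do.call(rbind, out)
  }
  replicate(nsim, one(), simplify = FALSE)
}
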