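#' Constrained quadratic fit of one activation phase
#'
#' Least-squares fit of the one-sided quadratic reporter model
#' `FR(t) = k (t - t0)^2` for `t >= t0` (0 before) to the control-subtracted
#' series on the window `[0, end_time]`, under box constraints on `k` and
#' `t0`. Two implementation choices make the estimator consistent with the
#' preprocessing: the data are smoothed and min-shifted *within the window*,
#' and the model curve is passed through the identical zero-phase filter
#' inside the objective, so that noise-free data are recovered exactly; and a
#' free baseline nuisance `c >= 0` absorbs the overshoot of the minimum-shift
#' (the minimum of a noisy series lies below the true baseline), which would
#' otherwise bias `t0` downward. For fixed `t0` the conditional optimum in
#' `(k, c)` is linear least squares solved in closed form; `t0` is profiled
#' by a grid search refined with golden-section optimisation.
#'
#' @param times time grid, min.
#' @param fr control-subtracted FRET-ratio series (unsmoothed).
#' @param end_time fit end point `tau`, min.
#' @param k_max upper bound on `k` (a.u. min^-2).
#' @param t0_min lower bound on `t0`, min.
#' @param t0_margin `t0` upper bound is `end_time - t0_margin`, min.
#' @param window zero-phase smoothing window, frames.
#' @return List: `k`, `t0`, `baseline`, `r2`, `rss`, `n` (points in window),
#'   `ok` (`FALSE` when the window is unusable).
#' @export
fit_quadratic <- function(times, fr, end_time, k_max = 0.01, t0_min = -30,
                          t0_margin = 30, window = 11L) {
  keep <- times <= end_time + 1e-9
  tw <- times[keep]
  t0_max <- end_time - t0_margin
  if (sum(keep) < 4 || t0_max <= t0_min)
    return(list(k = NA_real_, t0 = NA_real_, baseline = NA_real_,
                r2 = -Inf, rss = NA_real_, n = sum(keep), ok = FALSE))
  y <- suppressWarnings(smooth_zero_phase(fr[keep], window))
  y <- baseline_shift(as.numeric(y))
  do_smooth <- length(y) >= window

  obj <- function(t0) {
    m <- pmax(tw - t0, 0)^2
    if (do_smooth) m <- smooth_zero_phase(m, window)
    b <- solve_k_baseline(m, y, k_max)
    sum((y - b[1] * m - b[2])^2)
  }
  grid <- seq(t0_min, t0_max,
              length.out = max(5L, ceiling((t0_max - t0_min) / 10) + 1L))
  vals <- vapply(grid, obj, numeric(1))
  i <- which.min(vals)
  lo <- grid[max(1L, i - 1L)]
  hi <- grid[min(length(grid), i + 1L)]
  opt <- stats::optimize(obj, c(lo, hi), tol = 1e-7)
  t0 <- if (opt$objective <= vals[i]) opt$minimum else grid[i]

  m <- pmax(tw - t0, 0)^2
  if (do_smooth) m <- smooth_zero_phase(m, window)
  b <- solve_k_baseline(m, y, k_max)
  rss <- sum((y - b[1] * m - b[2])^2)
  tss <- sum((y - mean(y))^2)
  r2 <- if (tss > 0) 1 - rss / tss else 0
  list(k = b[1], t0 = t0, baseline = b[2], r2 = r2, rss = rss,
       n = length(y), ok = TRUE)
}

# constrained LS for (k, c): interior solution if feasible, else the best of
# the boundary solutions k = 0, c = 0, k = k_max
solve_k_baseline <- function(m, y, k_max) {
  n <- length(y)
  sm <- sum(m); sy <- sum(y); smm <- sum(m * m); smy <- sum(m * y)
  den <- n * smm - sm * sm
  if (den > 0) {
    k <- (n * smy - sm * sy) / den
    cc <- (sy - k * sm) / n
    if (k >= 0 && k <= k_max && cc >= 0) return(c(k, cc))
  }
  cand <- list(
    c(if (smm > 0) min(max(smy / smm, 0), k_max) else 0, 0),
    c(0, max(sy / n, 0)),
    c(k_max, max((sy - k_max * sm) / n, 0))
  )
  rss <- vapply(cand, function(b) sum((y - b[1] * m - b[2])^2), numeric(1))
  cand[[which.min(rss)]]
}

#' F-test of the quadratic fit against a flat model
#'
#' Compares the fitted model to the best constant (`FR(t) = c`):
#' `F = ((RSS0 - RSS1) / df1) / (RSS1 / (n - p))` referred to
#' `F(df1, n - p)`, where `p` is the number of fitted parameters and
#' `df1 = p - 1`. Fits that are not significantly better than flat are later
#' assigned the floor activation rate.
#'
#' @param y the fitted data window (smoothed, min-shifted).
#' @param rss_model residual sum of squares of the quadratic fit.
#' @param n_params number of parameters of the full model (3: `k`, `t0`,
#'   baseline).
#' @return p-value.
#' @export
f_test_vs_flat <- function(y, rss_model, n_params = 3) {
  n <- length(y)
  if (n <= n_params) stop("too few points for the F-test")
  rss0 <- sum((y - mean(y))^2)
  if (rss_model >= rss0) return(1)
  if (rss_model <= .Machine$double.eps * rss0) return(0)
  df1 <- n_params - 1
  f <- ((rss0 - rss_model) / df1) / (rss_model / (n - n_params))
  stats::pf(f, df1, n - n_params, lower.tail = FALSE)
}

#' Fit one preprocessed cell with retry, significance test and discard rules
#'
#' Fits the quadratic model ending at the primary derivative maximum; if the
#' fit is poor (`r2 < r2_retry`) each secondary maximum is tried and the best
#' `r2` kept. The kept fit is tested against a flat model; non-significant
#' fits get the floor rate `k_floor` (fallback). Cells that died before
#' `early_death` minutes *and* could not be fitted are discarded (presumed
#' non-apoptotic loss).
#'
#' @param prep output of [preprocess_cell()].
#' @param k_max,t0_min,t0_margin,window passed to [fit_quadratic()].
#' @param r2_retry retry cutoff on `r2`.
#' @param alpha F-test significance cutoff.
#' @param k_floor fallback activation rate.
#' @param early_death early-death discard cutoff, min.
#' @return One-row data frame: `k`, `t0`, `tau`, `r2`, `f_pvalue`,
#'   `fallback`, `max_c8`, `window_end_used`, `discarded`, `discard_reason`,
#'   `baseline`, `n_points`.
#' @export
fit_cell <- function(prep, k_max = 0.01, t0_min = -30, t0_margin = 30,
                     window = 11L, r2_retry = 0.5, alpha = 0.05,
                     k_floor = 1e-7, early_death = 70) {
  ends <- prep$tau_primary
  labels <- "primary"
  best <- fit_quadratic(prep$times, prep$fr_sub, ends[1], k_max = k_max,
                        t0_min = t0_min, t0_margin = t0_margin,
                        window = window)
  best_end <- ends[1]
  best_label <- "primary"
  if (!isTRUE(best$ok) || best$r2 < r2_retry) {
    for (sec in prep$secondary_maxima) {
      alt <- fit_quadratic(prep$times, prep$fr_sub, sec, k_max = k_max,
                           t0_min = t0_min, t0_margin = t0_margin,
                           window = window)
      if (isTRUE(alt$ok) && alt$r2 > best$r2) {
        best <- alt; best_end <- sec; best_label <- "secondary"
      }
    }
  }

  fit_failed <- !isTRUE(best$ok) || best$r2 < r2_retry
  died_early <- !is.na(prep$death_time) && prep$death_time < early_death
  if (!isTRUE(best$ok) || (died_early && fit_failed)) {
    reason <- if (died_early) "early_death_unfit" else "no_valid_window"
    return(data.frame(k = NA_real_, t0 = NA_real_, tau = best_end,
                      r2 = if (is.finite(best$r2)) best$r2 else NA_real_,
                      f_pvalue = NA_real_, fallback = FALSE,
                      max_c8 = NA_real_, window_end_used = best_label,
                      discarded = TRUE, discard_reason = reason,
                      baseline = NA_real_, n_points = best$n,
                      stringsAsFactors = FALSE))
  }

  # significance against a flat model, on *unsmoothed* residuals: the
  # smoothed series has autocorrelated noise, which would grossly inflate
  # the F statistic and let flat cells escape the floor rate
  keep <- prep$times <= best_end + 1e-9
  y_raw <- baseline_shift(prep$fr_sub[keep])
  m_raw <- best$k * pmax(prep$times[keep] - best$t0, 0)^2
  resid <- y_raw - m_raw
  rss_raw <- sum((resid - mean(resid))^2)   # baseline nuisance re-profiled
  pval <- f_test_vs_flat(y_raw, rss_raw, n_params = 3)
  fallback <- pval >= alpha
  k <- if (fallback) k_floor else best$k
  data.frame(k = k, t0 = best$t0, tau = best_end, r2 = best$r2,
             f_pvalue = pval, fallback = fallback,
             max_c8 = 2 * k * (best_end - best$t0),
             window_end_used = best_label, discarded = FALSE,
             discard_reason = NA_character_, baseline = best$baseline,
             n_points = best$n, stringsAsFactors = FALSE)
}

#' Peak C8 activity of a fit
#'
#' The maximal instantaneous activity under the quadratic model,
#' `Max(C8) = 2 k (tau - t0)`, reached at the end of the activation phase.
#'
#' @param fit a fit result (list or one-row data frame with `k`, `tau`,
#'   `t0`), e.g. from [fit_cell()].
#' @return Peak activity, a.u. min^-1.
#' @export
max_c8 <- function(fit) {
  2 * fit$k * (fit$tau - fit$t0)
}
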