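#' Subtract the untreated-control trajectory
#'
#' Removes shared drift (e.g. slow reporter accumulation or imaging trends)
#' by subtracting the average FRET-ratio trajectory of untreated cells,
#' interpolated onto the cell's grid if needed.
#'
#' @param times,fr the cell's time grid (min) and FRET-ratio series.
#' @param control_times,control_fr the control-mean series. `NULL` control is
#'   treated as identically zero.
#' @return Numeric series of the same length as `fr`.
#' @export
subtract_control <- function(times, fr, control_times = NULL,
                             control_fr = NULL) {
  if (is.null(control_fr)) return(fr)
  if (is.null(control_times)) control_times <- times
  if (length(control_times) != length(control_fr))
    stop("control series and grid lengths differ")
  rng <- range(control_times)
  if (min(times) < rng[1] - 1e-9 || max(times) > rng[2] + 1e-9)
    stop("control grid does not cover the trajectory; cannot interpolate")
  ctl <- stats::approx(control_times, control_fr, xout = times)$y
  fr - ctl
}

#' Zero-phase moving-average smoothing
#'
#' Applies an odd-length boxcar kernel forward and backward (the net kernel
#' is triangular), giving zero phase shift: features such as the position of
#' a symmetric peak are not displaced. Edges are handled by odd reflection
#' (mirror about the end value), which preserves affine trends exactly at the
#' boundaries.
#'
#' @param x numeric series on a uniform grid.
#' @param window odd kernel length in frames (default 11, i.e. 55 min at a
#'   5-min frame interval).
#' @return Smoothed series of the same length. If `x` is shorter than
#'   `window` it is returned unsmoothed with attribute `unsmoothed = TRUE`
#'   and a warning.
#' @export
smooth_zero_phase <- function(x, window = 11L) {
  window <- as.integer(window)
  stopifnot("window must be odd" = window %% 2L == 1L, window >= 1L)
  n <- length(x)
  if (n < window) {
    warning("series shorter than smoothing window; returned unsmoothed")
    attr(x, "unsmoothed") <- TRUE
    return(x)
  }
  if (window == 1L) return(x)
  p <- window
  xp <- c(2 * x[1] - x[(p + 1):2], x, 2 * x[n] - x[(n - 1):(n - p)])
  ker <- rep(1 / window, window)
  y <- stats::filter(stats::filter(xp, ker, sides = 2), ker, sides = 2)
  as.numeric(y[(p + 1):(p + n)])
}

#' Shift a series so its minimum is zero
#'
#' @param x numeric series (non-empty).
#' @return `x - min(x)`.
#' @export
baseline_shift <- function(x) {
  stopifnot(length(x) > 0)
  x - min(x)
}

#' Smoothed finite-difference derivative
#'
#' Central differences on interior points (exact for quadratics), one-sided
#' differences at the ends, divided by the frame interval, then smoothed with
#' the same zero-phase filter as the trajectory.
#'
#' @param x numeric series on a uniform grid.
#' @param dt frame interval, min.
#' @param window smoothing window in frames; `1` disables smoothing.
#' @return Derivative series, a.u. min^-1, same length as `x`.
#' @export
compute_derivative <- function(x, dt = 5, window = 11L) {
  n <- length(x)
  if (n < 3) stop("need at least 3 points for a derivative")
  d <- numeric(n)
  d[1] <- (x[2] - x[1]) / dt
  d[n] <- (x[n] - x[n - 1]) / dt
  d[2:(n - 1)] <- (x[3:n] - x[1:(n - 2)]) / (2 * dt)
  if (window > 1L && n >= window) d <- smooth_zero_phase(d, window)
  d
}

#' Locate the derivative maximum and secondary maxima
#'
#' The time of the maximal FRET-ratio derivative, `tau`, marks the end of
#' the C8 activation phase and is the fitting end point. Secondary local
#' maxima (used as fallback end points when the primary fit is poor) are
#' returned sorted by descending derivative value.
#'
#' @param times time grid, min.
#' @param dfr derivative series.
#' @param horizon analysis-window end for surviving cells, min.
#' @param death_time death time for dying cells (`NA` for survivors); the
#'   window of a dying cell extends to its death.
#' @return List with `tau_primary` (min) and `secondary_maxima`
#'   (numeric vector of times, possibly empty).
#' @export
locate_tau <- function(times, dfr, horizon = 600, death_time = NA) {
  window_end <- if (is.na(death_time)) horizon else death_time
  keep <- times <= window_end + 1e-9
  if (!any(keep)) stop("empty analysis window")
  tw <- times[keep]
  dw <- dfr[keep]
  # ties (e.g. an exactly flat derivative) resolve to the latest time, so
  # degenerate cells keep a full-length fitting window
  i_max <- max(which(dw == max(dw)))
  n <- length(dw)
  loc <- logical(n)
  if (n >= 3) {
    mid <- 2:(n - 1)
    loc[mid] <- dw[mid] >= dw[mid - 1] & dw[mid] > dw[mid + 1]
  }
  # boundary points count as maxima when the series rises into them
  if (n >= 2) {
    loc[1] <- dw[1] > dw[2]
    loc[n] <- dw[n] > dw[n - 1]
  }
  loc[i_max] <- FALSE
  sec <- tw[loc][order(dw[loc], decreasing = TRUE)]
  list(tau_primary = tw[i_max], secondary_maxima = sec)
}

#' Preprocess one trajectory
#'
#' Fixed pipeline order: control subtraction, zero-phase smoothing, baseline
#' shift to zero minimum, smoothed finite-difference derivative, and location
#' of the derivative maximum within the analysis window.
#'
#' @inheritParams subtract_control
#' @param death_time death time (min) for dying cells, `NA` otherwise.
#' @param window smoothing window, frames.
#' @param horizon analysis-window end, min.
#' @return List: `times`, `fr_sub` (control-subtracted, unsmoothed),
#'   `fr_corrected` (subtracted, smoothed, min-shifted), `dfr`,
#'   `tau_primary`, `secondary_maxima`, `death_time`.
#' @export
preprocess_cell <- function(times, fr, control_times = NULL,
                            control_fr = NULL, death_time = NA,
                            window = 11L, horizon = 600) {
  o <- order(times)
  times <- times[o]; fr <- fr[o]
  dt <- diff(times)
  if (length(dt) && (any(dt <= 0) || diff(range(dt)) > 1e-6))
    stop("time grid must be strictly increasing and uniform")
  fr_sub <- subtract_control(times, fr, control_times, control_fr)
  fr_sm <- smooth_zero_phase(fr_sub, window)
  fr_corr <- baseline_shift(fr_sm)
  dfr <- compute_derivative(fr_corr, dt = if (length(dt)) dt[1] else 1,
                            window = window)
  tau <- locate_tau(times, dfr, horizon = horizon, death_time = death_time)
  list(times = times, fr_sub = fr_sub, fr_corrected = fr_corr, dfr = dfr,
       tau_primary = tau$tau_primary,
       secondary_maxima = tau$secondary_maxima,
       death_time = death_time)
}
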