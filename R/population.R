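#' Population parameters for the trajectory simulator
#'
#' Bundles the lognormal population model of initiator-caspase (C8)
#' activation. Per cell, the activation rate `k` (a.u. min^-2), the activation
#' duration `tau - t0` (min) and the death threshold `theta_cell`
#' (a.u. min^-1) are independent lognormals; the lag `t0` is Gaussian
#' truncated at zero. Peak activity is `Max(C8) = 2 k (tau - t0)` and a cell
#' dies iff its peak reaches its own threshold.
#'
#' @param theta_pop population (geometric-mean) death threshold, a.u. min^-1.
#' @param sigma_theta SD of per-cell log10 threshold, decades.
#' @param gm_k_by_dose named numeric vector: geometric mean of `k`
#'   (a.u. min^-2) per condition label (TRAIL ng/ml as a string).
#' @param sigma_k SD of log10 k across cells, decades.
#' @param gm_tau_minus_t0 geometric mean of `tau - t0`, min.
#' @param sigma_tau SD of log10(tau - t0), decades.
#' @param t0_mean,t0_sd lag-time distribution, min (truncated at 0).
#' @param noise_sd additive Gaussian measurement noise on the FRET ratio, a.u.
#' @param decay_tc time constant of the post-peak decay of survivor C8
#'   activity, min.
#' @param frame_interval imaging interval, min.
#' @param horizon analysis window, min (must be a multiple of
#'   `frame_interval`).
#' @param record_length full recording length, min.
#'
#' @return An object of class `population_params`.
#' @seealso [calibrate_population()] for the anchored default parameter set.
#' @export
population_params <- function(theta_pop = 2.63e-3,
                              sigma_theta = 0.347,
                              gm_k_by_dose = c("25" = theta_pop / 480),
                              sigma_k = 0.576,
                              gm_tau_minus_t0 = 240,
                              sigma_tau = 0.0995,
                              t0_mean = 20, t0_sd = 5,
                              noise_sd = 0.01,
                              decay_tc = 90,
                              frame_interval = 5,
                              horizon = 600,
                              record_length = 1320) {
  p <- list(theta_pop = theta_pop, sigma_theta = sigma_theta,
            gm_k_by_dose = gm_k_by_dose, sigma_k = sigma_k,
            gm_tau_minus_t0 = gm_tau_minus_t0, sigma_tau = sigma_tau,
            t0_mean = t0_mean, t0_sd = t0_sd, noise_sd = noise_sd,
            decay_tc = decay_tc, frame_interval = frame_interval,
            horizon = horizon, record_length = record_length)
  class(p) <- "population_params"
  validate_population_params(p)
  p
}

validate_population_params <- function(p) {
  stopifnot(
    "all SDs must be >= 0" =
      all(c(p$sigma_theta, p$sigma_k, p$sigma_tau, p$t0_sd, p$noise_sd) >= 0),
    "geometric means must be > 0" =
      p$theta_pop > 0 && all(p$gm_k_by_dose > 0) && p$gm_tau_minus_t0 > 0,
    "frame_interval must be > 0" = p$frame_interval > 0,
    "horizon must be a multiple of frame_interval" =
      abs(p$horizon / p$frame_interval -
            round(p$horizon / p$frame_interval)) < 1e-9,
    "gm_k_by_dose must be named" = !is.null(names(p$gm_k_by_dose)),
    "decay_tc must be > 0" = p$decay_tc > 0
  )
  invisible(p)
}

#' @export
print.population_params <- function(x, ...) {
  cat("Population parameters (lognormal C8 activation model)\n")
  cat(sprintf("  theta_pop     : %.3g a.u./min (sigma_theta %.3f dec)\n",
              x$theta_pop, x$sigma_theta))
  cat(sprintf("  GM(tau - t0)  : %g min (sigma_tau %.3f dec)\n",
              x$gm_tau_minus_t0, x$sigma_tau))
  cat(sprintf("  sigma_k       : %.3f dec; lag t0 ~ N(%g, %g^2) min\n",
              x$sigma_k, x$t0_mean, x$t0_sd))
  cat(sprintf("  noise_sd %.3g a.u.; frame %g min; window %g of %g min\n",
              x$noise_sd, x$frame_interval, x$horizon, x$record_length))
  cat("  GM k by dose (a.u./min^2):\n")
  print(signif(x$gm_k_by_dose, 3))
  invisible(x)
}

#' Calibrate the population model to printed dose-response anchors
#'
#' Solves, in closed form, for the population spread parameters and the
#' per-dose geometric-mean activation rates such that the lognormal model
#' reproduces a set of printed population anchors: the dying fractions at
#' three doses, the fold span of the geometric-mean rate between the dose
#' extremes, the best-fixed-threshold classification accuracy at the
#' half-killing dose, and the population threshold itself.
#'
#' Writing `M = log10(2 k (tau - t0)) ~ N(mu_M(dose), sigma_M^2)` and
#' `L = log10(theta_cell) ~ N(log10(theta_pop), sigma_theta^2)` (independent),
#' the dying fraction at a dose is `Phi((mu_M - mu_L) / sigma_tot)` with
#' `sigma_tot^2 = sigma_M^2 + sigma_theta^2`, and the accuracy of the best
#' fixed threshold at the half-killing dose is
#' `1 - arctan(sigma_theta / sigma_M) / pi`. The anchors therefore identify
#' `sigma_tot` (from the kill fractions at the extremes and the fold span),
#' the split `sigma_theta / sigma_M` (from the accuracy), and `mu_M` at each
#' anchored dose (from its kill fraction). `sigma_M` is further partitioned
#' into `sigma_k` and `sigma_tau`, with `sigma_tau` fixed from the observed
#' 2-3-fold population spread of `tau`. Geometric-mean rates at intermediate
#' doses are log-linearly interpolated in log dose.
#'
#' @param anchors named list of printed constants:
#'   `kill_mid` (dying fraction at `dose_mid`), `kill_top`/`kill_bot` (dying
#'   fractions at `dose_top`/`dose_bot`), `k_fold` (GM-k fold change from
#'   `dose_bot` to `dose_top`), `accuracy` (best-threshold accuracy at
#'   `dose_mid`), `theta_pop` (a.u. min^-1), `gm_tau_minus_t0` (min).
#' @param doses numeric vector of condition doses (ng/ml) to tabulate in
#'   `gm_k_by_dose`.
#' @param ... further arguments passed to [population_params()]
#'   (e.g. `noise_sd`).
#'
#' @return A `population_params` object whose `gm_k_by_dose` is named by dose.
#' @examples
#' p <- calibrate_population()
#' p$gm_k_by_dose[["500"]]  # ~5e-5 a.u./min^2 at saturating TRAIL
#' @export
calibrate_population <- function(anchors = default_anchors(),
                                 doses = c(1, 2.5, 5, 10, 25, 50,
                                           100, 250, 500),
                                 ...) {
  a <- utils::modifyList(default_anchors(), as.list(anchors))
  if (!(a$kill_bot < a$kill_mid && a$kill_mid < a$kill_top))
    stop("infeasible anchors: kill fractions must increase with dose")
  if (a$k_fold <= 1)
    stop("infeasible anchors: k_fold must exceed 1")
  if (!(a$accuracy > 0.5 && a$accuracy < 1))
    stop("infeasible anchors: accuracy must lie in (0.5, 1)")

  z_top <- stats::qnorm(a$kill_top)
  z_bot <- stats::qnorm(a$kill_bot)
  sigma_tot <- log10(a$k_fold) / (z_top - z_bot)

  ratio <- tan(pi * (1 - a$accuracy))       # sigma_theta / sigma_M
  sigma_m <- sigma_tot / sqrt(1 + ratio^2)
  sigma_theta <- ratio * sigma_m

  # tau spread: 2-3-fold across the population, read as the +/- 2 SD range
  sigma_tau <- log10(2.5) / 4
  if (sigma_tau >= sigma_m)
    stop("infeasible anchors: accuracy implies sigma_M below the tau spread")
  sigma_k <- sqrt(sigma_m^2 - sigma_tau^2)

  mu_l <- log10(a$theta_pop)
  anchor_doses <- c(a$dose_bot, a$dose_mid, a$dose_top)
  mu_m_anchor <- mu_l + stats::qnorm(c(a$kill_bot, a$kill_mid, a$kill_top)) *
    sigma_tot
  mu_m <- stats::approx(log10(anchor_doses), mu_m_anchor, xout = log10(doses),
                        rule = 2)$y
  gm_k <- 10^mu_m / (2 * a$gm_tau_minus_t0)
  names(gm_k) <- vapply(doses, as.character, character(1))

  population_params(theta_pop = a$theta_pop, sigma_theta = sigma_theta,
                    gm_k_by_dose = gm_k, sigma_k = sigma_k,
                    gm_tau_minus_t0 = a$gm_tau_minus_t0,
                    sigma_tau = sigma_tau, ...)
}

#' Default calibration anchors
#'
#' Printed population constants of the TRAIL dose ladder in parental HeLa
#' cells: 50% killing at 25 ng/ml, 4% at 1 ng/ml, 92% at 500 ng/ml, a
#' 140-fold span of geometric-mean k between the extremes, 83% best-threshold
#' accuracy at the half-killing dose, a population threshold of 2.63e-3
#' a.u. min^-1, and a 240-min geometric-mean activation phase.
#'
#' @return Named list of anchors, see [calibrate_population()].
#' @export
default_anchors <- function() {
  list(kill_mid = 0.50, dose_mid = 25,
       kill_top = 0.92, dose_top = 500,
       kill_bot = 0.04, dose_bot = 1,
       k_fold = 140,
       accuracy = 0.83,
       theta_pop = 2.63e-3,
       gm_tau_minus_t0 = 240)
}

#' Define a treatment scenario
#'
#' A scenario names a condition and maps it onto the population model: the
#' dose selects the geometric-mean activation rate, and multipliers encode
#' perturbations: receptor clustering raises `k` severalfold, proteasome
#' inhibition (bortezomib) extends `tau` and suppresses the post-peak decay,
#' FLIP overexpression lowers `k`, and Bcl-2-family perturbations shift the
#' death threshold (inhibitor ABT-263 down, overexpression up).
#'
#' @param label condition name.
#' @param dose_key key into `gm_k_by_dose` of the population parameters.
#' @param k_multiplier,tau_multiplier,theta_multiplier positive multipliers
#'   applied to the geometric means of `k`, `tau - t0` and `theta`.
#' @param suppress_decay if `TRUE`, survivor C8 activity plateaus after `tau`
#'   instead of decaying.
#' @return An object of class `c8_scenario`.
#' @examples
#' scenario("TRAIL 25", "25")
#' scenario("mapa + anti-Fc", "25", k_multiplier = 5)
#' scenario("TRAIL 5 + bortezomib", "5", tau_multiplier = 1.5,
#'          suppress_decay = TRUE)
#' @export
scenario <- function(label, dose_key, k_multiplier = 1, tau_multiplier = 1,
                     theta_multiplier = 1, suppress_decay = FALSE) {
  stopifnot("multipliers must be > 0" =
              all(c(k_multiplier, tau_multiplier, theta_multiplier) > 0))
  structure(list(label = label, dose_key = as.character(dose_key),
                 k_multiplier = k_multiplier,
                 tau_multiplier = tau_multiplier,
                 theta_multiplier = theta_multiplier,
                 suppress_decay = isTRUE(suppress_decay)),
            class = "c8_scenario")
}

#' @export
print.c8_scenario <- function(x, ...) {
  cat(sprintf("Scenario '%s': dose key %s, k x%g, tau x%g, theta x%g%s\n",
              x$label, x$dose_key, x$k_multiplier, x$tau_multiplier,
              x$theta_multiplier,
              if (x$suppress_decay) ", decay suppressed" else ""))
  invisible(x)
}

#' Closed-form dying fraction for a scenario
#'
#' The fraction of cells whose peak activity `2 k (tau - t0)` exceeds their
#' own threshold, under the independent-lognormal population model:
#' `Phi((mu_M - mu_L) / sigma_tot)`.
#'
#' @param params a `population_params` object.
#' @param scn a `c8_scenario` object.
#' @return Dying fraction in `[0, 1]`.
#' @export
kill_fraction <- function(params, scn) {
  gm_k <- scenario_gm_k(params, scn)
  mu_m <- log10(2 * gm_k * params$gm_tau_minus_t0 * scn$tau_multiplier)
  mu_l <- log10(params$theta_pop * scn$theta_multiplier)
  sigma_tot <- sqrt(params$sigma_k^2 + params$sigma_tau^2 +
                      params$sigma_theta^2)
  stats::pnorm((mu_m - mu_l) / sigma_tot)
}

scenario_gm_k <- function(params, scn) {
  if (!scn$dose_key %in% names(params$gm_k_by_dose))
    stop(sprintf("unknown dose key '%s'", scn$dose_key))
  unname(params$gm_k_by_dose[[scn$dose_key]] * scn$k_multiplier)
}
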