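#' Estimate the death threshold by misclassification minimisation
#'
#' The threshold `theta` on peak C8 activity is the value minimising the
#' error count `E(theta) = #(dead with Max < theta) + #(alive with
#' Max >= theta)` (Heaviside convention: a cell exactly at the threshold is
#' classified as dying). `E` is piecewise constant between consecutive
#' unique peak values, so the exact minimiser is found by scanning the
#' midpoints of the sorted unique values plus one candidate below the
#' minimum and one above the maximum; ties are broken towards the smallest
#' candidate.
#'
#' @param max_values per-cell peak activity `Max(C8)`, a.u. min^-1.
#' @param fates character vector, `"died"`/`"survived"`.
#' @param n_boot bootstrap replicates for the SEM of the accuracy
#'   (0 disables).
#' @param seed optional seed for the bootstrap.
#' @return Object of class `c8_threshold`: `theta_hat`, `error_count`,
#'   `accuracy`, `n_cells`, `candidate_grid`, `sem_accuracy`, `degenerate`.
#' @examples
#' estimate_theta(c(3, 4, 5, 1, 2, 2.5) * 1e-3,
#'                rep(c("died", "survived"), each = 3))
#' @export
estimate_theta <- function(max_values, fates, n_boot = 0, seed = NULL) {
  stopifnot(length(max_values) == length(fates),
            all(fates %in% c("died", "survived")))
  ok <- is.finite(max_values)
  max_values <- max_values[ok]; fates <- fates[ok]
  n <- length(max_values)
  if (n < 2) stop("need at least 2 cells")
  dead <- fates == "died"
  degenerate <- !(any(dead) && any(!dead))

  grid <- theta_candidate_grid(max_values)
  errs <- error_curve(grid, max_values, dead)
  i <- which.min(errs)                 # first minimum = smallest theta
  theta_hat <- grid[i]
  err <- errs[i]

  sem <- NA_real_
  if (n_boot >= 2) {
    if (!is.null(seed)) set.seed(seed)
    acc <- replicate(n_boot, {
      j <- sample.int(n, n, replace = TRUE)
      g <- theta_candidate_grid(max_values[j])
      1 - min(error_curve(g, max_values[j], dead[j])) / n
    })
    sem <- stats::sd(acc)
  }
  structure(list(theta_hat = theta_hat, error_count = err,
                 accuracy = 1 - err / n, n_cells = n,
                 candidate_grid = grid, sem_accuracy = sem,
                 degenerate = degenerate),
            class = "c8_threshold")
}

theta_candidate_grid <- function(max_values) {
  u <- sort(unique(max_values))
  if (length(u) == 1) {
    step <- max(abs(u) * 0.5, 1e-12)
    return(c(u - step, u + step))
  }
  mids <- (u[-1] + u[-length(u)]) / 2
  c(u[1] - (u[2] - u[1]) / 2, mids,
    u[length(u)] + (u[length(u)] - u[length(u) - 1]) / 2)
}

# E(theta) for each candidate; predicted dead iff Max >= theta
error_curve <- function(grid, max_values, dead) {
  vapply(grid, function(th) {
    pred_dead <- max_values >= th
    sum(dead & !pred_dead) + sum(!dead & pred_dead)
  }, integer(1))
}

#' @export
print.c8_threshold <- function(x, ...) {
  cat(sprintf("Death threshold: theta = %.4g a.u./min\n", x$theta_hat))
  cat(sprintf("  misclassified %d of %d cells (accuracy %.1f%%%s)%s\n",
              x$error_count, x$n_cells, 100 * x$accuracy,
              if (is.na(x$sem_accuracy)) ""
              else sprintf(" +/- %.1f", 100 * x$sem_accuracy),
              if (x$degenerate) " [degenerate: single fate]" else ""))
  invisible(x)
}

#' Classification accuracy at a fixed threshold
#'
#' `1 - E(theta)/n` with the same Heaviside convention as
#' [estimate_theta()] (dead iff `Max >= theta`).
#'
#' @inheritParams estimate_theta
#' @param theta threshold, a.u. min^-1 (> 0).
#' @return Fraction of correctly classified cells.
#' @export
accuracy_at <- function(theta, max_values, fates) {
  stopifnot(theta > 0, length(max_values) == length(fates),
            length(max_values) > 0)
  dead <- fates == "died"
  1 - error_curve(theta, max_values, dead) / length(max_values)
}

#' Classify cells by the analytic fate boundary
#'
#' In the `(k, tau)` landscape the threshold corresponds to the boundary
#' `tau = theta / (2 k) + t0_bar`; a cell is predicted to die iff it falls
#' on or above the boundary, i.e. `2 k (tau - t0_bar) >= theta`. Cells with
#' `k <= 0` are predicted to survive.
#'
#' @param k,tau fitted per-cell activation rate and derivative-maximum time.
#' @param theta death threshold, a.u. min^-1.
#' @param t0_bar population mean lag, min.
#' @return Character vector `"died"`/`"survived"`.
#' @examples
#' classify_by_boundary(5e-5, 100, theta = 2.63e-3, t0_bar = 20)  # died
#' @export
classify_by_boundary <- function(k, tau, theta, t0_bar = 20) {
  stopifnot(theta > 0)
  ifelse(k > 0 & 2 * k * (tau - t0_bar) >= theta, "died", "survived")
}

#' Linear maximum-margin comparator classifier
#'
#' Purely data-driven benchmark for the analytic fate boundary: a linear
#' support-vector machine on the standardised features
#' `(log10 k, tau)` with regularisation constant 1, reporting training
#' accuracy and the boundary line in feature space.
#'
#' @param k,tau fitted per-cell parameters.
#' @param fates observed fates, `"died"`/`"survived"`.
#' @param cost regularisation constant.
#' @return List: `accuracy`, `predicted`, `weights` and `intercept` of the
#'   boundary in standardised feature space (`w1*z1 + w2*z2 + b = 0`),
#'   `center`/`scale` of the standardisation, and the underlying `model`.
#' @export
fit_linear_margin_classifier <- function(k, tau, fates, cost = 1) {
  stopifnot(length(k) == length(tau), length(k) == length(fates))
  if (length(unique(fates)) < 2)
    stop("degenerate input: both fates must be present")
  x <- cbind(log10k = log10(k), tau = tau)
  ctr <- colMeans(x)
  scl <- apply(x, 2, stats::sd)
  scl[scl == 0] <- 1
  z <- scale(x, center = ctr, scale = scl)
  y <- factor(fates, levels = c("survived", "died"))
  m <- e1071::svm(z, y, kernel = "linear", cost = cost, scale = FALSE)
  pred <- as.character(stats::predict(m, z))
  w <- colSums(m$coefs[, 1] * m$SV)
  list(accuracy = mean(pred == fates), predicted = pred,
       weights = w, intercept = -m$rho,
       center = ctr, scale = scl, model = m)
}

#' Bootstrap standard error of a dataset statistic
#'
#' Cell-level resampling with replacement: the SD of the statistic across
#' `n_boot` bootstrap datasets, the single-dataset analogue of a
#' replicate-experiment SEM.
#'
#' @param statistic function of a data frame returning a scalar.
#' @param dataset data frame with one row per cell.
#' @param n_boot number of bootstrap replicates (>= 2).
#' @param seed optional seed.
#' @return Standard error (scalar).
#' @export
bootstrap_sem <- function(statistic, dataset, n_boot = 1000, seed = NULL) {
  stopifnot(n_boot >= 2, is.function(statistic))
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(dataset)
  stats::sd(replicate(n_boot,
                      statistic(dataset[sample.int(n, n, replace = TRUE), ,
                                        drop = FALSE])))
}
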