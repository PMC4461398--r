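#' Population summary of one condition
#'
#' Statistics over the non-discarded cells of a condition, with fallback
#' (floor-rate) cells included: the floor is part of the population
#' statistic, as the mean of `log10 k` over *all* fitted cells is what the
#' dose-response relation uses.
#'
#' @param fits the `fits` data frame of a [c8_fit()] (or any data frame with
#'   `condition`, `fate`, `k`, `tau`, `discarded`).
#' @param condition condition label to summarise (`NULL`: use all rows).
#' @return One-row data frame: `condition`, `n_cells`, `geomean_k`,
#'   `mean_log10_k`, `sem_log10_k`, `mean_tau`, `sem_tau`,
#'   `surviving_fraction`, `sem_surviving`.
#' @export
summarize_condition <- function(fits, condition = NULL) {
  if (inherits(fits, "c8_fit")) fits <- fits$fits
  f <- fits[!fits$discarded, ]
  if (!is.null(condition)) f <- f[f$condition == condition, ]
  if (!nrow(f)) stop("no non-discarded cells in condition")
  n <- nrow(f)
  lk <- log10(f$k)
  surv <- mean(f$fate == "survived")
  data.frame(condition = if (is.null(condition)) "all" else condition,
             n_cells = n,
             geomean_k = 10^mean(lk),
             mean_log10_k = mean(lk),
             sem_log10_k = stats::sd(lk) / sqrt(n),
             mean_tau = mean(f$tau),
             sem_tau = stats::sd(f$tau) / sqrt(n),
             surviving_fraction = surv,
             sem_surviving = sqrt(surv * (1 - surv) / n),
             stringsAsFactors = FALSE)
}

#' Logistic dose-response of survival on the mean activation rate
#'
#' Least-squares fit of the two-parameter logistic
#' `S(x) = 1 / (1 + exp(-s (x - m)))` to the surviving fraction versus the
#' condition mean of `log10 k`. Asymptotes are fixed at 0 and 1 because
#' survival is a fraction by construction; the slope is negative when
#' survival falls with increasing rate.
#'
#' @param mean_log10_k per-condition mean of `log10 k` (decades), or a data
#'   frame of [summarize_condition()] rows.
#' @param surviving_fraction per-condition surviving fraction.
#' @return List of class `c8_logistic`: `midpoint` (decades), `slope`
#'   (decades^-1), `r2`, `identifiable` (`FALSE` when the data do not span
#'   the transition), `fitted`.
#' @export
fit_logistic_survival <- function(mean_log10_k, surviving_fraction = NULL) {
  if (is.data.frame(mean_log10_k)) {
    surviving_fraction <- mean_log10_k$surviving_fraction
    mean_log10_k <- mean_log10_k$mean_log10_k
  }
  x <- mean_log10_k; y <- surviving_fraction
  stopifnot(length(x) == length(y), all(y >= 0 & y <= 1))
  if (length(x) < 4) stop("need at least 4 conditions")
  identifiable <- (max(y) - min(y)) >= 0.2
  # starts: midpoint where survival crosses 1/2, slope from the y range
  m0 <- x[which.min(abs(y - 0.5))]
  s0 <- -4 / max(diff(range(x)), 0.1)
  obj <- function(p) sum((y - stats::plogis(p[2] * (x - p[1])))^2)
  opt <- stats::optim(c(m0, s0), obj, method = "Nelder-Mead",
                      control = list(maxit = 2000, reltol = 1e-12))
  fitted <- stats::plogis(opt$par[2] * (x - opt$par[1]))
  tss <- sum((y - mean(y))^2)
  r2 <- if (tss > 0) 1 - opt$value / tss else 0
  structure(list(midpoint = opt$par[1], slope = opt$par[2], r2 = r2,
                 identifiable = identifiable, fitted = fitted),
            class = "c8_logistic")
}

#' @export
print.c8_logistic <- function(x, ...) {
  cat(sprintf("Logistic survival vs mean log10(k): midpoint %.3f dec, slope %.2f dec^-1, r2 %.3f%s\n",
              x$midpoint, x$slope, x$r2,
              if (!x$identifiable) " [poorly identifiable: no transition in range]" else ""))
  invisible(x)
}

#' Rank association between an expression proxy and a per-cell statistic
#'
#' Spearman rank correlation with p-value (exact for small untied samples,
#' large-sample approximation otherwise, as implemented by
#' [stats::cor.test()]), plus an optional Wilcoxon rank-sum comparison when
#' a binary grouping is supplied (e.g. died vs survived expression levels).
#'
#' @param levels per-cell expression proxy (e.g. FLIP or Bcl-2 reporter
#'   level).
#' @param values per-cell statistic (e.g. fitted `k`).
#' @param group optional binary grouping; when given, `levels` are compared
#'   between the two groups by a rank-sum test.
#' @return List: `rho`, `p_value`, and (with `group`) `wilcox_p`.
#' @export
rank_association <- function(levels, values, group = NULL) {
  ok <- is.finite(levels) & is.finite(values)
  levels <- levels[ok]; values <- values[ok]
  stopifnot("need at least 5 pairs" = length(levels) >= 5)
  if (stats::sd(levels) == 0 || stats::sd(values) == 0)
    stop("constant input: rank correlation undefined")
  ct <- suppressWarnings(stats::cor.test(levels, values,
                                         method = "spearman"))
  out <- list(rho = unname(ct$estimate), p_value = ct$p.value)
  if (!is.null(group)) {
    g <- factor(group[ok])
    if (nlevels(g) != 2) stop("group must be binary")
    out$wilcox_p <- suppressWarnings(
      stats::wilcox.test(levels ~ g)$p.value)
  }
  out
}
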