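# shared fixtures, built in code

# calibrated population, computed once per test run
calib <- calibrate_population()

scn25 <- scenario("TRAIL 25", "25")

# noise-free one-sided quadratic on a uniform grid
quad_series <- function(k, t0, t_end, dt = 5, tmax = t_end) {
  tg <- seq(0, tmax, by = dt)
  list(times = tg, fr = ifelse(tg < t0, 0, k * (tg - t0)^2))
}

# exhaustive independent scan of the misclassification curve: cumulative
# counts over the sorted values (a different algorithm than the package's
# per-candidate counting)
brute_force_theta <- function(max_values, fates) {
  o <- order(max_values)
  m <- max_values[o]
  dead <- (fates == "died")[o]
  n <- length(m)
  # E for thresholds below min, in each gap, above max
  cd <- cumsum(dead)          # dead with Max < theta for theta just above m[i]
  ca <- cumsum(!dead)
  e_below <- sum(!dead)       # everyone predicted dead
  e_gap <- cd + (sum(!dead) - ca)
  min(c(e_below, e_gap))
}
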