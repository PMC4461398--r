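# constrained quadratic fitting, F-test fallback, retry and discard rules

test_that("noise-free quadratic data are recovered exactly", {
  q <- quad_series(2e-5, 20, 300)
  f <- fit_quadratic(q$times, q$fr, end_time = 300)
  expect_equal(f$k, 2e-5, tolerance = 1e-8)
  expect_equal(f$t0, 20, tolerance = 1e-6)
  expect_gt(f$r2, 1 - 1e-10)
})

test_that("flat data degrade gracefully and the F-test sends them to the floor", {
  tg <- seq(0, 300, 5)
  f <- fit_quadratic(tg, rep(0, length(tg)), end_time = 300)
  expect_equal(f$r2, 0)         # TSS = 0 handled as r2 = 0
  prep <- preprocess_cell(tg, rep(0.3, length(tg)), horizon = 600)
  fc <- fit_cell(prep)
  expect_true(fc$fallback)
  expect_equal(fc$k, 1e-7)
  expect_equal(fc$max_c8, 2 * 1e-7 * (fc$tau - fc$t0))
})

test_that("noisy rate recovery is within 10% at the reference rate", {
  set.seed(31)
  errs <- replicate(100, {
    tg <- seq(0, 245, 5)   # 50 frames
    y <- ifelse(tg < 20, 0, 5e-5 * (tg - 20)^2) + rnorm(length(tg), 0, 0.01)
    fit_quadratic(tg, y, end_time = 245)$k / 5e-5 - 1
  })
  expect_lt(median(abs(errs)), 0.1)
})

test_that("fit constraints are never violated", {
  set.seed(32)
  for (r in 1:20) {
    tg <- seq(0, 400, 5)
    y <- ifelse(tg < 20, 0, 10^runif(1, -6, -4) * (tg - 20)^2) +
      rnorm(length(tg), 0, 0.02)
    f <- fit_quadratic(tg, y, end_time = 400)
    expect_gte(f$k, 0); expect_lte(f$k, 0.01)
    expect_gte(f$t0, -30); expect_lte(f$t0, 400 - 30)
  }
})

test_that("the F statistic against the flat model has the nominal null level", {
  # correctly specified case: fixed design, free (k, baseline), iid noise
  set.seed(33)
  tg <- seq(0, 300, 5)
  m <- pmax(tg - 100, 0)^2
  pvals <- replicate(2000, {
    y <- rnorm(length(tg))
    rss <- sum(lm.fit(cbind(m, 1), y)$residuals^2)
    f_test_vs_flat(y, rss, n_params = 2)  # t0 fixed: 2 free parameters
  })
  rej <- mean(pvals < 0.05)
  se <- sqrt(0.05 * 0.95 / 2000)
  expect_lt(abs(rej - 0.05), 4 * se)
  # and p is roughly uniform
  expect_gt(ks.test(pvals, "punif")$p.value, 1e-4)
})

test_that("F-test boundary cases", {
  y <- c(1, 2, 3, 2, 1, 2, 3)
  rss0 <- sum((y - mean(y))^2)
  expect_equal(f_test_vs_flat(y, rss0), 1)        # no improvement
  expect_lt(f_test_vs_flat(y, rss0 * 1e-18), 1e-10)
  # strong signal: p far below any cutoff
  q <- quad_series(5e-5, 20, 300)
  set.seed(34)
  y2 <- q$fr + rnorm(length(q$fr), 0, 0.01 * diff(range(q$fr)))
  f <- fit_quadratic(q$times, y2, end_time = 300, window = 1)
  expect_lt(f_test_vs_flat(baseline_shift(y2), f$rss), 1e-6)
})

test_that("poor primary fits are retried on a secondary maximum", {
  tg <- seq(0, 365, 5)
  fr <- 0.35 * exp(-((tg - 150) / 30)^2) +
    ifelse(tg >= 300, 1e-4 * (tg - 300)^2, 0)
  prep <- preprocess_cell(tg, fr, death_time = 365, horizon = 600)
  expect_equal(prep$tau_primary, 365)  # boundary maximum of the late phase
  fc <- fit_cell(prep)
  expect_equal(fc$window_end_used, "secondary")
  expect_gt(fc$r2, 0.9)
  expect_false(fc$discarded)
})

test_that("early deaths are discarded only when the fit also fails", {
  # early death, clean quadratic: kept
  tg <- seq(0, 60, 5)
  fr <- ifelse(tg < 10, 0, 2e-3 * (tg - 10)^2)
  prep <- preprocess_cell(tg, fr, death_time = 60, horizon = 600)
  fc <- fit_cell(prep)
  expect_false(fc$discarded)
  # early death, garbage signal: discarded with a reason
  set.seed(35)
  fr2 <- c(0, 0.4, 0, 0.4, 0, 0.4, 0, 0.4, 0, 0.4, 0, 0.4, 0)
  prep2 <- preprocess_cell(seq(0, 60, 5), fr2, death_time = 60,
                           horizon = 600)
  fc2 <- fit_cell(prep2)
  expect_true(fc2$discarded)
  expect_match(fc2$discard_reason, "early_death")
})

test_that("peak activity is the analytic derivative of the fitted model", {
  expect_equal(max_c8(list(k = 1e-4, tau = 60, t0 = 20)), 8e-3)
  expect_equal(max_c8(list(k = 5e-5, tau = 46.3, t0 = 20)), 2.63e-3)
  # a floor-rate cell stays below the reference threshold
  expect_lt(max_c8(list(k = 1e-7, tau = 600, t0 = 20)), 2.63e-3)
  cells <- sample_cells(calib, scn25, 100, seed = 36)
  ts <- generate_dataset(calib, scn25, 30, seed = 36)
  fit <- c8_fit(ts, keep_prep = FALSE)
  f <- fit$fits[!fit$fits$discarded, ]
  expect_equal(f$max_c8, 2 * f$k * (f$tau - f$t0))
})

test_that("fit summary methods report the population quantities", {
  ts <- generate_dataset(calib, scn25, 25, seed = 37)
  fit <- c8_fit(ts)
  s <- summary(fit)
  expect_s3_class(s, "summary.c8_fit")
  expect_equal(s$n_cells, 25)
  expect_output(print(fit), "C8 activation model fit")
  cf <- coef(fit)
  expect_true(all(c("k", "t0", "tau", "max_c8") %in% colnames(cf)))
  pr <- predict(fit, cell_ids = rownames(cf)[1])
  expect_true(all(diff(pr$time_min) == 5))
  res <- residuals(fit)
  expect_lt(sd(res$residual), 3 * calib$noise_sd)
  sim <- simulate(fit, nsim = 1, seed = 1)
  expect_named(sim[[1]], c("cell_id", "time_min", "fret_ratio"))
})
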