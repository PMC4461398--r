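# threshold estimation, boundary classification, comparator classifier

test_that("separable peak activities give a zero-error midpoint threshold", {
  mx <- c(3, 4, 5, 1, 2, 2.5) * 1e-3
  ft <- rep(c("died", "survived"), each = 3)
  th <- estimate_theta(mx, ft)
  expect_equal(th$theta_hat, 2.75e-3)
  expect_equal(th$error_count, 0)
  expect_equal(th$accuracy, 1)
  expect_false(th$degenerate)
})

test_that("interleaved values resolve to the lowest optimal midpoint", {
  mx <- c(2, 4, 1, 3) * 1e-3
  ft <- c("died", "died", "survived", "survived")
  th <- estimate_theta(mx, ft)
  expect_equal(th$error_count, 1)
  expect_equal(th$accuracy, 0.75)
  expect_equal(th$theta_hat, 1.5e-3)
})

test_that("single-fate input is flagged degenerate", {
  th <- estimate_theta(c(1, 2, 3) * 1e-3, rep("died", 3))
  expect_true(th$degenerate)
  expect_equal(th$accuracy, 1)
})

test_that("estimate_theta matches exhaustive brute force on random instances", {
  set.seed(41)
  for (r in 1:100) {
    n <- sample(5:200, 1)
    mx <- 10^runif(n, -4, -2)
    ft <- sample(c("died", "survived"), n, replace = TRUE)
    if (length(unique(ft)) < 2) ft[1:2] <- c("died", "survived")
    est <- estimate_theta(mx, ft)
    expect_identical(est$error_count, brute_force_theta(mx, ft))
    # a 1e4-point uniform scan never beats the exact candidate grid
    grid <- seq(min(mx) / 2, max(mx) * 1.5, length.out = 1e4)
    dead <- ft == "died"
    e_grid <- vapply(grid, function(t) sum(dead & mx < t) +
                       sum(!dead & mx >= t), numeric(1))
    expect_gte(min(e_grid), est$error_count)
  }
})

test_that("the error curve is piecewise constant between unique values", {
  set.seed(42)
  mx <- 10^runif(60, -4, -2)
  ft <- sample(c("died", "survived"), 60, replace = TRUE)
  dead <- ft == "died"
  u <- sort(unique(mx))
  for (i in sample(length(u) - 1, 10)) {
    probes <- u[i] + diff(u[c(i, i + 1)]) * c(0.1, 0.5, 0.9)
    errs <- vapply(probes, function(t) sum(dead & mx < t) +
                     sum(!dead & mx >= t), numeric(1))
    expect_true(all(errs == errs[1]))
  }
})

test_that("accuracy_at applies the dead-iff-at-or-above convention", {
  mx <- c(3, 4, 5, 1, 2, 2.5) * 1e-3
  ft <- rep(c("died", "survived"), each = 3)
  expect_equal(accuracy_at(2.8e-3, mx, ft), 1)
  # threshold below every value: everyone predicted dead
  expect_equal(accuracy_at(1e-6, mx, rep("died", 6)), 1)
  expect_equal(accuracy_at(1e-6, mx, rep("survived", 6)), 0)
  # a cell exactly at the threshold counts as dying
  expect_equal(accuracy_at(3e-3, c(3e-3), c("died")), 1)
})

test_that("boundary classification follows the analytic fate line", {
  # well above the line
  expect_equal(classify_by_boundary(5e-5, 100, theta = 2.63e-3,
                                    t0_bar = 20), "died")
  # floor-rate cell: boundary lies far beyond the recording
  expect_equal(classify_by_boundary(1e-7, 600, theta = 2.63e-3,
                                    t0_bar = 20), "survived")
  # exactly on the line: dying by convention
  k <- 5e-5; tau <- 2.63e-3 / (2 * k) + 20
  expect_equal(classify_by_boundary(k, tau, theta = 2.63e-3, t0_bar = 20),
               "died")
  expect_equal(classify_by_boundary(0, 600, theta = 2.63e-3), "survived")
})

test_that("threshold and boundary classifiers agree when lags are uniform", {
  set.seed(43)
  k <- 10^rnorm(200, log10(5.5e-6), 0.5)
  tau <- 20 + 240 * 10^rnorm(200, 0, 0.1)
  mx <- 2 * k * (tau - 20)
  ft <- ifelse(mx >= 2.63e-3 * 10^rnorm(200, 0, 0.3), "died", "survived")
  th <- estimate_theta(mx, ft)
  expect_identical(classify_by_boundary(k, tau, th$theta_hat, t0_bar = 20),
                   ifelse(mx >= th$theta_hat, "died", "survived"))
})

test_that("the linear max-margin comparator behaves at the extremes", {
  set.seed(44)
  # separable clouds
  k <- c(10^rnorm(50, -6.5, 0.2), 10^rnorm(50, -4.5, 0.2))
  tau <- c(rnorm(50, 150, 10), rnorm(50, 350, 10))
  ft <- rep(c("survived", "died"), each = 50)
  svm <- fit_linear_margin_classifier(k, tau, ft)
  expect_equal(svm$accuracy, 1)
  expect_length(svm$weights, 2)
  # permuted labels: accuracy near the majority-class frequency
  ft2 <- sample(rep(c("survived", "died"), c(300, 200)))
  k2 <- 10^rnorm(500, -5.5, 0.5); tau2 <- rnorm(500, 250, 50)
  svm2 <- fit_linear_margin_classifier(k2, tau2, ft2)
  expect_lt(abs(svm2$accuracy - 0.6), 0.05)
  expect_error(fit_linear_margin_classifier(k2, tau2,
                                            rep("died", 500)),
               "degenerate")
})

test_that("bootstrap SEM behaves on known statistics", {
  d <- data.frame(x = rnorm(100))
  expect_equal(bootstrap_sem(function(d) 1, d, n_boot = 50, seed = 1), 0)
  sem <- bootstrap_sem(function(d) mean(d$x), d, n_boot = 400, seed = 2)
  expect_equal(sem, sd(d$x) / 10, tolerance = 0.2)
  # accuracy of a separable threshold problem is bootstrap-invariant
  sep <- data.frame(mx = c(3, 4, 5, 1, 2, 2.5) * 1e-3,
                    ft = rep(c("died", "survived"), each = 3))
  sem2 <- bootstrap_sem(function(d) {
    if (length(unique(d$ft)) < 2) return(1)
    estimate_theta(d$mx, d$ft)$accuracy
  }, sep, n_boot = 100, seed = 3)
  expect_equal(sem2, 0)
})

test_that("accuracy degrades monotonically with threshold heterogeneity", {
  accs <- sapply(c(0.1, 0.35, 1.0), function(sth) {
    p <- population_params(sigma_theta = sth)
    cells <- sample_cells(p, scenario("25", "25"), 10000, seed = 45)
    mx <- 2 * cells$k_true * (cells$tau_true - cells$t0_true)
    estimate_theta(mx, cells$fate)$accuracy
  })
  expect_true(all(diff(accs) < 0))
})
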