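# synthetic trajectory generator

test_that("fate follows the threshold rule exactly", {
  cells <- sample_cells(calib, scn25, 500, seed = 1)
  died <- 2 * cells$k_true * (cells$tau_true - cells$t0_true) >=
    cells$theta_cell
  expect_identical(cells$fate, ifelse(died, "died", "survived"))
  expect_true(all(cells$death_time[cells$fate == "died"] ==
                    cells$tau_true[cells$fate == "died"]))
  expect_true(all(is.na(cells$death_time[cells$fate == "survived"])))
  expect_true(all(cells$tau_true > cells$t0_true))
  expect_true(all(cells$t0_true >= 0))
  # survivors censored at the horizon
  expect_true(all(cells$tau_true[cells$fate == "survived"] <=
                    calib$horizon))
})

test_that("degenerate spreads give all-die / all-survive populations", {
  p0 <- population_params(sigma_theta = 0, sigma_k = 0, sigma_tau = 0,
                          t0_sd = 0,
                          gm_k_by_dose = c(hi = 2 * 2.63e-3 / 480,
                                           lo = 0.5 * 2.63e-3 / 480))
  all_die <- sample_cells(p0, scenario("hi", "hi"), 50, seed = 2)
  expect_true(all(all_die$fate == "died"))
  all_live <- sample_cells(p0, scenario("lo", "lo"), 50, seed = 2)
  expect_true(all(all_live$fate == "survived"))
})

test_that("Monte-Carlo kill fraction matches the closed form within 3 SE", {
  for (key in c("1", "25", "500")) {
    scn <- scenario(key, key)
    cells <- sample_cells(calib, scn, 10000, seed = 11)
    p_cf <- kill_fraction(calib, scn)
    se <- sqrt(p_cf * (1 - p_cf) / 10000)
    expect_lt(abs(mean(cells$fate == "died") - p_cf), 3 * se)
  }
})

test_that("kill fraction is monotone in the scenario knobs", {
  frac <- function(scn) mean(sample_cells(calib, scn, 10000,
                                          seed = 5)$fate == "died")
  k_ladder <- sapply(c(1, 3, 9), function(m)
    frac(scenario("x", "25", k_multiplier = m)))
  expect_true(all(diff(k_ladder) > 0))
  tau_ladder <- sapply(c(1, 1.5, 2.25), function(m)
    frac(scenario("x", "25", tau_multiplier = m)))
  expect_true(all(diff(tau_ladder) > 0))
  theta_ladder <- sapply(c(0.5, 1, 2), function(m)
    frac(scenario("x", "25", theta_multiplier = m)))
  expect_true(all(diff(theta_ladder) < 0))
})

test_that("the reporter model evaluates the quadratic and its tails", {
  p0 <- population_params(noise_sd = 0)
  cell <- data.frame(cell_id = "c1", k_true = 2e-5, t0_true = 20,
                     tau_true = 300, theta_cell = 1, fate = "survived",
                     death_time = NA_real_)
  tr <- render_trajectory(cell, p0)
  expect_equal(tr$fret_ratio[tr$time_min == 120], 2e-5 * 100^2)
  expect_true(all(tr$fret_ratio[tr$time_min < 20] == 0))
  # survivor derivative decays to < 1% of its peak by tau + 5 time constants
  d <- diff(tr$fret_ratio) / 5
  t_mid <- tr$time_min[-1] - 2.5
  peak <- 2 * 2e-5 * 280
  late <- d[which.min(abs(t_mid - (300 + 5 * p0$decay_tc)))]
  expect_lt(late / peak, 0.01)
  # suppressed decay keeps the peak slope
  tr2 <- render_trajectory(cell, p0, suppress_decay = TRUE)
  d2 <- diff(tr2$fret_ratio) / 5
  expect_equal(unname(d2[length(d2)]), peak, tolerance = 1e-9)
})

test_that("dying trajectories are truncated on the frame grid", {
  p0 <- population_params(noise_sd = 0)
  cell <- data.frame(cell_id = "c1", k_true = 5e-5, t0_true = 20,
                     tau_true = 250, theta_cell = 1e-9, fate = "died",
                     death_time = 250)
  tr <- render_trajectory(cell, p0)
  expect_equal(max(tr$time_min), 250)
  cell$tau_true <- cell$death_time <- 252
  tr <- render_trajectory(cell, p0)
  expect_equal(max(tr$time_min), 250)  # last full frame before death
})

test_that("a seed fully determines the dataset, down to the CSV bytes", {
  ts1 <- generate_dataset(calib, scn25, 25, seed = 77)
  ts2 <- generate_dataset(calib, scn25, 25, seed = 77)
  expect_identical(ts1$cells, ts2$cells)
  expect_identical(ts1$trajectories, ts2$trajectories)
  d1 <- file.path(tempdir(), "ds1"); d2 <- file.path(tempdir(), "ds2")
  write_dataset(ts1, d1); write_dataset(ts2, d2)
  for (f in c("trajectories.csv", "cells.csv"))
    expect_identical(readBin(file.path(d1, f), "raw", 1e6),
                     readBin(file.path(d2, f), "raw", 1e6))
  rt <- read_dataset(d1)
  expect_equal(nrow(rt$cells), 25)
  expect_true(all(c("cell_id", "time_min", "fret_ratio") %in%
                    names(rt$trajectories)))
})
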