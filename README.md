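# c8fate

Single-cell analysis of initiator-caspase (caspase-8/10, "C8") activation
dynamics during death-receptor-induced apoptosis, for researchers studying
fractional killing by TRAIL and other DR4/5 agonists with live-cell FRET
reporters.

Only a fraction of a clonal population dies at any agonist dose, and which
cells die is predicted by two numbers extracted from each cell's FRET-ratio
trajectory FR(t): the rate *k* and duration *τ* of the C8 activation phase.
The package implements the phenomenological model

```
FR(t)   = k (t − t0)²            activation phase, lag t0
dFR/dt  = 2k (t − t0)            instantaneous C8 activity
Max(C8) = 2k (τ − t0)            peak activity, at t = τ
cell dies  ⇔  Max(C8) ≥ θ        death threshold θ
```

so the life/death boundary in the (k, τ) landscape is the hyperbola
τ = θ/2k + t̄0. The toolchain covers:

* **Preprocessing** — control subtraction, 55-min zero-phase smoothing,
  baseline shift, smoothed finite-difference derivative, location of the
  derivative maximum τ (`preprocess_cell()` and friends).
* **Per-cell fitting** — constrained least squares for (k, t0) with
  secondary-maximum retry, F-test fallback to a floor rate, and early-death
  discard rules; `c8_fit()` returns a classed object with `print`,
  `summary`, `coef`, `predict`, `plot`, `residuals` and `simulate` methods.
* **Fate threshold** — `estimate_theta()` minimises the live/dead
  misclassification count exactly over the midpoint candidate grid;
  `classify_by_boundary()` applies the analytic boundary;
  `fit_linear_margin_classifier()` provides the linear-SVM benchmark.
* **Population statistics** — geometric-mean rates, surviving fractions,
  logistic dose–response on mean log10(k), Spearman/Wilcoxon rank
  associations (`summarize_condition()`, `fit_logistic_survival()`,
  `rank_association()`).
* **Calibrated simulator** — `calibrate_population()` solves a lognormal
  population model, in closed form, from printed dose-response anchors
  (50% kill at 25 ng/ml, 4→92% kill over a 140-fold rate span, 83%
  threshold accuracy, θ = 2.63×10⁻³ a.u. min⁻¹);
  `generate_dataset()` renders reproducible per-cell trajectories with
  death-time truncation, survivor decay and measurement noise.
* **Pipeline** — `run_pipeline()` ties the stages into one reproducible
  run (CSV/JSON artifacts plus a manifest) from a `c8_config()` or a
  YAML/JSON file.

## Worked example

```r
library(c8fate)

params <- calibrate_population()
ts  <- generate_dataset(params, scenario("TRAIL 25", "25"), n = 300, seed = 1)
fit <- c8_fit(ts)
fit
#> C8 activation model fit: 300 cells (0 discarded, 1 fallback)
#>   geometric-mean k: 5.67e-06 a.u./min^2;  mean t0: 19.3 min;  mean tau: 261 min
#>   fraction r2 > 0.9: 0.97

kept <- fit$fits[!fit$fits$discarded, ]
estimate_theta(kept$max_c8, kept$fate, n_boot = 200, seed = 1)
#> Death threshold: theta = 0.001917 a.u./min
#>   misclassified 50 of 300 cells (accuracy 83.3% +/- 1.9)

plot(fit, theta = 0.001917)   # (k, tau) landscape with the fate boundary
```

These are the population quantities the method is designed to recover: the
fitted geometric-mean rate (5.7×10⁻⁶ a.u. min⁻², against a calibrated
5.5×10⁻⁶ at this half-killing dose), the mean lag (19.3 min, truth 20),
the fraction of well-fitted trajectories (97% with r² > 0.9) and the
threshold accuracy (83%). A single-dose threshold estimate is noisy by
nature (here 1.9×10⁻³ against a ground truth of 2.63×10⁻³ a.u. min⁻¹);
pooling a 10–500 ng/ml dose ladder, as the acceptance script does,
recovers θ within a few percent.

## Documentation

The methods vignette (`vignettes/c8fate-methods.Rmd`) describes the model
and its assumptions, the calibration algebra, the estimator design
(operator-consistent smoothing and the baseline nuisance), numerical
choices and tie rules, and what the synthetic-data tests do and do not
demonstrate about real imaging data.
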