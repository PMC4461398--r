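Package: c8fate
Title: Initiator-Caspase Activation Dynamics and Cell-Fate Thresholds
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for analysing single-cell FRET-reporter trajectories of
    initiator caspase (caspase-8/10) activation during death-receptor-induced
    apoptosis. Fits the phenomenological quadratic model FR(t) = k*(t - t0)^2
    per cell under box constraints, locates the time of maximal activity (tau)
    from the zero-phase-smoothed derivative, estimates the live/dead activity
    threshold theta by minimising the misclassification error, classifies
    cells by the fate boundary tau = theta/(2k) + t0, and summarises
    populations (geometric-mean activation rates, surviving fractions,
    logistic dose-response, rank associations). Includes a calibrated
    lognormal population simulator of TRAIL dose-ladder experiments for
    testing and parameter-recovery studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    e1071,
    jsonlite,
    yaml
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
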