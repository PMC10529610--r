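Package: hgfbms
Title: Hierarchical Gaussian Filter Models of Sensorimotor Learning with
    Bayesian Model Selection
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Trial-by-trial computational modelling of sensorimotor
    learning: binary hierarchical Gaussian filters (3 and 4 levels),
    Rescorla-Wagner and Sutton K1 associative learners, subject-level
    maximum-a-posteriori inversion with Laplace log-model evidence,
    random-effects Bayesian model selection with protected exceedance
    probabilities, and group-level parameter statistics. Includes
    generators for size-weight-illusion lifting and bounce-interception
    experiment designs, synthetic grip-force and gaze traces, and the
    preprocessing chain (zero-phase Butterworth smoothing, five-point
    central-difference peak grip-force rate, dispersion-based gaze
    fixation detection, outlier screening, and binary coding of inputs
    and responses) needed to take raw signals to model-ready series.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    signal,
    jsonlite,
    stats,
    utils,
    graphics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
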