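Package: cardiomvd
Title: Coronary Microvascular Function and Cardiac Performance from Preclinical MRI
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis chain for quantifying coronary microvascular endothelial
    function and global cardiac performance in small-animal cardiac MRI studies.
    Implements variable-flip-angle (VFA/DESPOT1) T1 mapping of the myocardium,
    inversion of dynamic single-flip-angle scans after nitric-oxide-synthase
    inhibition into a percent T1-change time course and its area under the
    curve (cumulative delta-T1, an index of endothelial NO-dependent function),
    piecewise-linear-regression decomposition of the left-ventricular
    time-volume curve into ejection/filling rates and phase durations,
    eight-sector circumferential and radial myocardial strain indices from
    tracked point trajectories, Doppler coronary flow reserve, and
    glucose-tolerance-test area under the curve, together with a
    digital-phantom simulator that emulates control and high-fat-diet mouse
    cohorts for validation, and group comparison with normality and
    variance-homogeneity gated test selection.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    graphics,
    jsonlite,
    car,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
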