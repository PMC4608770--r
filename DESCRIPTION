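Package: painsig
Title: Pain Intensity Recognition from Biopotential Feature Patterns
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for automated recognition of heat-pain intensity from
    multichannel biopotential recordings (facial and trapezius surface
    electromyography, skin conductance level, electrocardiography). The
    package simulates protocol-structured recordings (randomized phasic heat
    stimuli at four calibrated intensities plus baseline), preprocesses them
    (Butterworth filtering, empirical-mode-decomposition denoising,
    Hilbert-envelope burst detection, QRS/RR extraction, 5.5 s windowing),
    extracts a 159-dimensional feature space spanning amplitude, frequency,
    stationarity, entropy, linearity, variability and similarity groups,
    performs two-stage feature selection (static/correlation pruning followed
    by SVM-wrapped forward selection), and trains and evaluates RBF-kernel
    support vector machines with exponential grid search, reporting accuracy,
    per-class sensitivity and specificity, and Cramer's V effect size.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    e1071,
    jsonlite,
    yaml,
    S4Vectors,
    SummarizedExperiment,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    knitr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
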