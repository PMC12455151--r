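Package: uncflow
Title: Spatial-Cueing EEG Analysis with Oscillatory Power, Beamforming and Nonlinear Effective Connectivity
Version: 0.1.0
Authors@R: person("UNCFlow", "Developers", email = "uncflow@example.org", role = c("aut", "cre"))
Description: A tested, reproducible pipeline for analysing spatial-cueing
    (Posner-type) EEG experiments that manipulate target uncertainty.
    Provides behavioural signal-detection analysis (d-prime, repeated-measures
    ANOVA, planned contrasts), Morlet wavelet time-frequency decomposition
    with baseline correction, cluster-based permutation statistics over
    electrode neighbourhood graphs, LCMV and DICS beamforming on synthetic
    leadfields, and a neural-network estimator of linear and nonlinear
    directed (effective) connectivity from multivariate autoregressive
    models, with time-shifted surrogate significance testing. A synthetic
    data generator with fully known ground truth makes every stage testable
    without external recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    jsonlite,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
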