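Package: svbalance
Title: Instantaneous Sympatho-Vagal Balance from Heartbeat Point Processes and Electrodermal Activity
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Point-process modelling of heartbeat dynamics with an
    inverse-Gaussian interval distribution and Laguerre-expanded
    Volterra kernels, yielding instantaneous time-domain, spectral (LF,
    HF) and bispectral (LL, LH, HH) vagal markers; a spectral
    sympathetic index (EDAsymp) from the time-frequency plane of
    electrodermal activity together with a sparse non-negative
    deconvolution of tonic and phasic skin-conductance components;
    fusion of the two modalities into instantaneous sympatho-vagal
    indices with Daubechies-wavelet tonic/phasic decomposition; and a
    downstream statistical and classification layer (robust summaries,
    exact paired Wilcoxon tests, nonlinear SVM with recursive feature
    elimination under leave-one-subject-out validation). Includes a
    synthetic-signal generator (IPFM heartbeats, Bateman-kernel skin
    conductance responses) providing ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    tools,
    jsonlite,
    splines
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
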