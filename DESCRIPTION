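Package: ctqa
Title: Quantitative CT Number Evaluation with a Polyenergetic Phantom Simulator
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantitative evaluation of CT numbers in multi-energy
    phantom studies. Computes theoretical linear attenuation coefficients (LAC)
    from elemental compositions via the mass-attenuation mixture rule, extracts
    circular-ROI statistics from reconstructed image stacks, and estimates
    accuracy, precision (coefficient of variation), size dependence, and
    background-noise metrics with percentile-bootstrap confidence intervals.
    Includes a polyenergetic parallel-beam CT simulator of a nested two-size
    multi-energy phantom with stylized single-energy, dual-energy, and
    photon-counting acquisition models (beam hardening, water correction,
    basis-material decomposition, virtual monoenergetic image synthesis), plus
    a fast statistical ROI-sample generator for estimator validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    jsonlite,
    yaml,
    RNifti,
    rlang,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    ggplot2,
    withr
Config/testthat/edition: 3
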