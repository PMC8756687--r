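Package: crcabc
Title: Colorectal Cancer Natural-History Microsimulation and Incremental
    Mixture ABC Calibration
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates individual colorectal cancer natural histories
    (adenoma initiation, Richards growth, transition to preclinical cancer,
    Weibull sojourn time, clinical detection) and calibrates the model to
    tolerance-interval summary targets with an Incremental Mixture
    Approximate Bayesian Computation (IMABC) engine. Supports sequential
    "warm start" recalibration when new calibration targets arrive, and
    provides posterior-comparison metrics (credible-interval overlap,
    density area overlap, standardized mean difference, Hellinger distance)
    and mean-sojourn-time summaries to quantify how new evidence shifts the
    calibrated posterior. Includes size-dependent screening-test sensitivity
    models and a synthetic-study fixtures generator for end-to-end
    calibration experiments.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    ggplot2,
    generics,
    jsonlite,
    mvtnorm,
    Rcpp,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
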