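Package: screenperm
Title: Calibrated Permutation Testing for Low-MOI Single-Cell CRISPR Screens
Version: 0.1.0
Authors@R:
    person("screenperm", "developers", email = "maintainers@screenperm.dev",
           role = c("aut", "cre"))
Description: Association testing for low multiplicity-of-infection
    single-cell CRISPR screens. Tests each perturbation-gene pair by
    permuting a negative binomial GLM score statistic, with a spectral
    fast path for sparse binary treatments, adaptive two-stage
    permutation, skew-normal tail approximation of the permutation null,
    and shared without-replacement resamples across pairs. Includes a
    calibration-check framework built on non-targeting guide RNAs,
    pairwise quality control based on effective sample size, fully
    specified synthetic-data generators (signal-free null screens,
    positive-control screens, and confounded simulation studies), and
    diagnostic analyses of sparsity, confounding, and model
    misspecification.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Matrix,
    Rcpp,
    jsonlite,
    methods,
    stats,
    utils,
    parallel
LinkingTo: Rcpp, BH
Suggests:
    testthat (>= 3.0.0),
    MASS,
    statmod
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
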