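Package: fastwater
Title: Fast-Water Construction and Validation Toolkit for Molecular Dynamics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools to build and validate "fast water" variants of 3-site
    water models for molecular dynamics: exact hydrogen-mass repartitioning
    and total-mass rescaling with GROMACS topology editing, time-step/mass
    equivalence and ideal transport-scaling predictions, maximum-likelihood
    Poisson crash-rate estimation from censored replica outcomes with
    exponential mass-dependence fits and iso-stability contours, NPT-aware
    trajectory unwrapping with generalized-least-squares self-diffusion
    estimation and Yeh-Hummer finite-size extrapolation, rigid-body
    equipartition diagnostics, and sampling-efficiency statistics for
    collective-variable time series (autocorrelation times, dihedral order
    parameters, block-average errors, histogram free energies, and
    replica-based Kolmogorov-Smirnov comparisons). Includes synthetic
    generators (censored crash records, Brownian particles under fluctuating
    periodic boxes, Langevin dihedral dynamics) with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
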