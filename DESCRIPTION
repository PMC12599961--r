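Package: lascal
Title: Regional Left-Atrial Stiffness Calibration by Emulation, History
    Matching and Ensemble MCMC
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A reduced-order five-region model of passive left-atrial
    mechanics (Guccione membranes with pericardial and mitral-annulus
    boundary conditions and backward-displacement unloading) together
    with the Bayesian calibration machinery used to estimate regional
    myocardial stiffness from end-systolic volume and regional
    displacement observations: Gaussian-process emulation with
    cross-validated accuracy metrics, Sobol/Saltelli global sensitivity
    analysis, multi-wave history matching with an implausibility
    measure, affine-invariant ensemble MCMC, and downstream linear
    mixed-effects and paired-t analyses of regional deformation.
    Includes a synthetic-study generator for verification with known
    ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    MASS,
    lhs,
    lme4,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
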