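Package: kinedmd
Title: Ethomic Fingerprints and Progression Biomarkers from Full-Body Kinematics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for turning full-body motion-capture recordings of natural
    behaviour into "ethomic fingerprints" (workspace volume, hip orbit area,
    extremity velocities, joint angular-velocity statistics, autocorrelation
    widths, duty cycles and more), screening them between groups, predicting
    clinical scales (6MWD, NSAA, PUL, MyoGrip) with Gaussian-process regression
    under nested leave-one-subject-out cross-validation with wrapper feature
    selection, and fitting a constrained monotone tanh disease-progression
    biomarker over age by Bayesian optimization. Ships a synthetic-cohort
    simulator emulating Duchenne muscular dystrophy and control movement
    statistics so the whole pipeline is testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    lhs,
    MASS,
    stats,
    utils,
    xml2,
    yaml
Suggests:
    kernlab,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
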