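Package: tleFingerprint
Title: Connectome Fingerprinting for Temporal Lobe Epilepsy Outcome
    Prediction
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Builds and evaluates a functional and structural connectome
    fingerprint of unilateral mesial temporal lobe epilepsy. Provides
    age-normative correction of connectome edges against a healthy control
    cohort, conversion of connectomes to a seizure-focus-oriented frame,
    reduction to lobe-averaged weighted-degree connectivity profiles over a
    priori nodes of interest, bootstrap expansion of a seizure-free model
    group into a fingerprint with Euclidean and Mahalanobis distance
    scoring, and the statistical evaluation of scored cohorts
    (outcome-group comparisons, ROC prediction of unfavourable outcome, a
    random-node permutation null, and a clinical covariate screen).
    Includes a synthetic cohort generator with known ground truth so the
    whole pipeline can be exercised end to end without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    graphics,
    tools,
    jsonlite,
    pROC
Suggests:
    testthat (>= 3.0.0),
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'connectome-build.R'
    'core-io.R'
    'evaluation.R'
    'fingerprint.R'
    'pipeline.R'
    'profile.R'
    'simulate.R'
    'tleFingerprint-package.R'
    'utils.R'
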