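Package: gaitResponder
Title: Predicting Response to Hip-Strengthening Exercise in Knee
    Osteoarthritis from Gait Waveforms and Patient-Reported Outcomes
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Implements a reusable pipeline for predicting which patients
    with mild-to-moderate knee osteoarthritis respond to a six-week
    hip-strengthening exercise intervention. Joint-angle gait waveforms
    (hip, knee and ankle in the sagittal and frontal planes) are low-pass
    filtered, segmented into strides, time-normalized to stance (60%) and
    swing (40%) phases, averaged over ten consecutive strides and
    concatenated into a 600-point gait signature per subject. The cohort
    signature matrix is standardized and reduced by principal component
    analysis; principal component scores are combined with baseline Knee
    injury and Osteoarthritis Outcome Score (KOOS) subscales as candidate
    predictors. Intervention patients are subgrouped into Non-, Low- and
    High-Responders by per-patient Cohen's d of KOOS change; predictors
    are chosen by sequential forward selection under repeated 10-fold
    cross-validated linear discriminant error, capped at one less than the
    smallest subgroup, and the best cumulative-entry discriminant model is
    reported with Wilks' Lambda, Bartlett chi-squared, Box's M, Lilliefors
    screening and the structure matrix. New cohorts (post-intervention,
    long-term follow-up, pain-free controls) are projected into the fitted
    discriminant subspace and centroid stability is assessed. A synthetic
    cohort generator with the study's group structure makes every stage
    testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    signal,
    S4Vectors,
    SummarizedExperiment,
    Rcpp,
    jsonlite
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    MASS,
    nortest,
    optparse,
    withr,
    yaml
Config/testthat/edition: 3
biocViews: StatisticalMethod, Classification, DimensionReduction
RoxygenNote: 7.3.3
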