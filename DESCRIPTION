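Package: pupilmanifold
Title: Dimensionality Reduction and Time-Course Inference for Phasic Pupillometry
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing phasic pupil-size traces as coordinates on a
    low-dimensional "pupillary manifold". Provides long-format data import and
    preprocessing (artifact gap interpolation, per-subject z-scoring, baseline
    correction, epoching), temporal principal components analysis with a
    deterministic sign convention and variance-threshold component selection,
    a factor-analytic extension (eigenvalue-scaled loadings, varimax and promax
    rotation, oblique regression scores, Tucker congruence), per-timepoint
    mixed-model and Jeffreys-Zellner-Siow Bayes-factor time-course tests with
    false-discovery-rate and cluster-based permutation control, and a synthetic
    trace generator built from three physiologically motivated basis components
    (parasympathetic activation, parasympathetic inhibition, sympathetic
    activation) for end-to-end recovery validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    lme4,
    stats,
    utils,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
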