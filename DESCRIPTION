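Package: threatmvpa
Title: Multivariate Decoding of Threat Representations in Auditory fMRI
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A tested pipeline for detecting stimulus-invariant threat
    encoding in auditory cortex with functional MRI and skin conductance.
    Provides a synthetic-data generator for factorial fear-conditioning
    designs (4D BOLD volumes with planted multivoxel patterns and
    model-based skin-conductance traces), single-trial beta-series
    estimation by a least-squares-all general linear model with a canonical
    haemodynamic response function, imbalance-aware linear support vector
    machine decoding with permutation-based chance correction, neutral-
    condition subsampling for bias matching, cross-classification between
    simple and complex sounds, spherical searchlight mapping with sign-flip
    max-statistic group inference, model-based anticipatory arousal
    estimation from skin conductance, and factorial mixed-effects contrasts
    with containment degrees of freedom.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    lme4
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
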