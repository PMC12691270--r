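Package: siristrat
Title: SIRI-Based Survival Risk Stratification for Oropharyngeal Cancer
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for building interpretable prognostic models from the
    systemic inflammation response index (SIRI) and routine clinical
    covariates in oropharyngeal head and neck cancer. Implements a random
    survival forest workflow together with a forest-derived cutoff discovery
    algorithm: splitting rules harvested from the forest are compared, via
    kernel density estimation, against the covariate distribution, and local
    maxima of the density difference yield candidate cutoffs which are
    filtered by a minimum group-occupancy rule. Discretized covariates feed a
    depth- and size-constrained survival decision tree whose leaves are merged
    into three ordered risk groups. Includes a synthetic cohort generator
    with planted threshold effects, random-forest imputation, Harrell's
    concordance index, permutation variable importance, time-dependent AUC,
    Kaplan-Meier / log-rank / Cox machinery with Holm-Bonferroni correction,
    calibration and recalibration, and an end-to-end pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    survival,
    ranger,
    stats,
    utils,
    jsonlite
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
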