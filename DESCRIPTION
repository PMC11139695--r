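Package: dietclust
Title: Dietary Pattern Discovery and Hypertension Association Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Derives dietary patterns from ordinal diet-history questionnaire
    data (food intake frequencies, dietary behaviors, cooking methods) by
    nonlinear dimension reduction (UMAP) and K-means clustering with principled
    cluster-number selection (elbow, silhouette, density-peak count),
    characterizes clusters with weighted trend scores, and quantifies the
    association between patterns and incident hypertension via crude and
    covariate-adjusted logistic odds-ratio models with likelihood-ratio tests,
    age-caliper matched sensitivity analyses, and DASH diet-score comparisons.
    Includes a synthetic cohort generator with planted patterns so the whole
    pipeline is testable without access to restricted cohort data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    graphics,
    MASS,
    cluster,
    yaml,
    jsonlite,
    tools,
    Rcpp
LinkingTo: Rcpp
Suggests:
    mclust,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
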