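Package: mdscore
Title: Metabolic Dysbiosis Score Construction and Survival Evaluation
Version: 0.1.0
Authors@R:
    person("MDS", "Maintainers", email = "maintainers@mdscore.dev", role = c("aut", "cre"))
Description: Builds and evaluates a metabolic dysbiosis score (MDS) for
    critically ill patients from fecal metabolite concentration panels.
    Provides per-metabolite ROC analysis with Youden-optimal cutpoints and
    stratified bootstrap stability, binarization into a patient-by-metabolite
    point matrix, ridge-importance-ordered iterative score assembly with
    parsimony model selection, and survival evaluation via Kaplan-Meier
    curves, log-rank tests, restricted mean survival time at a fixed horizon,
    and Cox proportional hazards models with Schoenfeld diagnostics.
    Includes cohort preparation utilities (stratified splitting, sparse
    metabolite filtering, predictive-mean-matching imputation, group
    comparison statistics), taxonomic profile summaries (Shannon diversity,
    Bray-Curtis dissimilarity, pathobiont domination flags), and a synthetic
    cohort generator so the full pipeline is testable without patient data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    survival,
    glmnet,
    vegan,
    optparse,
    withr
Config/testthat/edition: 3
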