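Package: SubtypeConcord
Title: Consensus-Set Breast Cancer Subtype Predictors and Concordance Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Molecular subtyping of breast cancer expression profiles into the
    four intrinsic subtypes (basal-like, HER2-enriched, luminal A, luminal B)
    with three predictor families: nearest-centroid single sample predictors
    (SSP) over intrinsic gene lists, subtype classification models (SCM) based
    on a three-component Gaussian mixture over ER and HER2 module scores with a
    proliferation-based luminal A/B split, and rule-based predictors following
    the St. Gallen surrogate intrinsic subtype definitions (STG). Provides
    robust percentile scaling for cross-dataset standardization (including
    pooled scaling for cohorts with skewed subtype composition), probeset
    collapsing, signed-average module scores, semi-supervised consensus-set
    construction from predictor panels, supervised training of predictor suites
    on consensus sets, Cohen's kappa concordance analysis (overall and
    subtype-specific, with qualitative agreement bands), grouped concordance
    aggregation, a synthetic compendium generator with known subtype ground
    truth and batch effects, and a manifest-driven pipeline runner.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    jsonlite,
    mclust,
    S4Vectors,
    SummarizedExperiment
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
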