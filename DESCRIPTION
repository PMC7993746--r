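Package: mpscore
Title: Molecular Prognostic Score Construction and Survival Evaluation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds and applies molecular prognostic score (mPS) gene panels
    for tumor cohorts with overall-survival follow-up. Provides a synthetic
    cohort generator with planted differential-expression and
    proportional-hazards structure, a median-split survival screen combined
    with moderated-t differential expression, random-forest feature selection
    over binarized gene scores, a small feed-forward neural network whose
    input-layer weights define per-gene score weights, weighted-sum scoring
    with threshold stratification, and survival evaluation via Kaplan-Meier
    curves, Cox proportional-hazards models, Harrell's concordance index, and
    a points-based nomogram with bootstrap calibration. Ships the published
    21-gene clear cell renal cell carcinoma panel as a fixture.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    survival,
    randomForest,
    limma,
    jsonlite,
    withr
Suggests:
    testthat (>= 3.0.0),
    optparse,
    knitr
Config/testthat/edition: 3
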