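Package: fasdscreen
Title: Multimodal Screening Classifiers and Value-of-Information Analysis
    for Fetal Alcohol Spectrum Disorder
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Classification pipeline for screening children and youth for
    fetal alcohol spectrum disorder (FASD) from multimodal assessments:
    saccadic eye-movement tasks (prosaccade, antisaccade, memory-guided
    saccade), free viewing of natural videos, psychometric test scores,
    and diffusion tensor imaging of the corpus callosum.  Implements
    support-vector-machine recursive feature elimination with
    leave-one-out selection, a topographic ICA representation of
    attentional eye traces with a two-layer L1-regularized logistic
    classifier, probability-level fusion across assessments,
    cross-assessment multilinear regression, stratified-bootstrap
    classifier comparison, and a value-of-information model of annual
    screening economics.  A synthetic-cohort generator reproduces the
    demographic, missingness, and effect-size structure the analysis
    assumes, so every stage is testable without access to clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    S4Vectors,
    SummarizedExperiment,
    e1071,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    glmnet,
    withr,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
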