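Package: swbtrace
Title: Predicting Subjective Well-Being from Digital Traces
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A tested pipeline for predicting the two subjective well-being
    scales SWLS and WHO-5 from digital traces (private-message streams, phone
    app-usage logs and profile metadata). Implements scale normalization and
    discretization with screening-cutoff selection validated against
    depression, anxiety and stress questionnaires; linguistic feature families
    (sentiment proportions over time windows, TfIDF word features with
    ANOVA-based selection on a heldout cohort, lexicon-category features);
    supervision-regularized consensus word clustering over embeddings;
    circadian app-usage and activity features; and a value-stratified 10-fold
    train/dev/test cross-validation harness with recursive feature elimination
    for regression and classification. A synthetic-cohort generator with
    planted effects makes every stage testable without access to private data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    glmnet,
    randomForest,
    rpart,
    nnet,
    igraph,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    mclust
Config/testthat/edition: 3
RoxygenNote: 7.3.3
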