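Package: aisglm
Title: Aggregated Influence Scores for Short-Text Regression and Classification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Summarises short-text documents (e.g. tweets) into a single
    continuous predictor, the aggregated influence score (AIS). Per-term
    univariate generalized linear models -- hurdle negative-binomial,
    negative-binomial or Poisson for a count outcome, logistic for a binary
    topic label -- yield relative-risk or odds-ratio weights; the
    frequency-weighted mean, median and sum of those weights per document
    give the AIS-mean, AIS-median and AIS-sum. The scores are then used as
    the sole predictor in popularity (retweet count) models and topic
    classifiers, with model diagnostics: hanging rootograms, the
    expected-zeros difference, Kruskal-Wallis tests and ROC/AUC analysis
    with Youden-optimal cutoffs. Includes text cleaning, document-term
    matrix construction with sparse-term filtering, and a seeded synthetic
    corpus generator with planted term effects for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    MASS,
    pROC,
    jsonlite,
    stats,
    utils,
    graphics,
    methods
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
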