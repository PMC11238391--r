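Package: screensim
Title: Simulation of Active-Learning Literature Screening with Noisy Labels
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to study screening prioritization for evidence synthesis.
    Simulates active-learning title-abstract screening (TF-IDF features with a
    multinomial naive Bayes ranker) on labeled bibliographic corpora, scores the
    simulated screening order with work saved over sampling (WSS@95), relevant
    records found (RRF@10), time to discovery (TD/ATD) and recall curves,
    quantifies inter-rater agreement with Cohen's kappa, and generates synthetic
    corpora with correlated noisy raters and nested three-stage adjudication so
    the degradation of screening performance under label noise can be measured
    without access to the original datasets.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    methods,
    readr,
    rlang,
    stats,
    tibble,
    utils,
    withr
Suggests:
    e1071,
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
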