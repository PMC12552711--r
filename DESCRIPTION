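Package: psychollm
Title: Semantic Structure and Score Prediction for Psychological Questionnaires
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying how the semantic similarity structure of
    questionnaire items, computed from text embeddings, aligns with the
    empirical correlation structure of item responses. Provides Top-K
    semantic-empirical alignment metrics, matrix-level correlation tests,
    minimum-residual factor analysis applied to similarity and correlation
    matrices with Tucker-congruence agreement scoring, and PsychoLLM, a
    self-supervised neighbor-weighting predictor that imputes Likert
    responses to unseen items or whole unseen questionnaires from scores on
    their semantically nearest items. Includes leave-one-item-out,
    leave-one-subscale-out and cross-questionnaire evaluation protocols, a
    latent-trait Likert response simulator with controllable
    semantic-to-correlation coupling, and a small command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    randomForest,
    testthat (>= 3.0.0),
    vegan
Config/testthat/edition: 3
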