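Package: thetanav
Title: Hidden Markov and Mixed-Model Feature Engineering for Navigation EEG
    Classification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Feature engineering and classification for frontal-midline
    theta-power EEG recorded during virtual spatial navigation. Extracts
    per-subject features from theta time series via Gaussian hidden Markov
    models (Baum-Welch estimation, Viterbi decoding, AIC state-count
    profiles) and via a random-intercept/random-slope linear mixed model of
    peak heights on peak curvatures; computes behavioural features (idle
    time, path length, total angle shift, average speed) from navigation
    trajectories; evaluates learner versus non-learner classification with
    six classifier configurations under leave-one-out cross-validation and
    AUROC; and aggregates local surrogate (LIME-style) explanations into
    top-k feature rankings. Includes a synthetic-cohort generator so the
    whole pipeline is testable without any recorded data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    class,
    dplyr,
    e1071,
    generics,
    ggplot2,
    glmnet,
    jsonlite,
    lme4,
    purrr,
    ranger,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    optparse,
    pROC,
    testthat (>= 3.0.0),
    withr
LinkingTo:
    Rcpp
Config/testthat/edition: 3
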