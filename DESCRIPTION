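Package: peersway
Title: Social Influence Scoring and Time-Resolved EEG Decoding of Peer
    Feedback
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: An end-to-end pipeline for studying susceptibility to social
    influence in peer-feedback face-evaluation experiments.  Generates and
    validates interleaved test/post-test trial schedules with quota-controlled
    feedback conditions; computes social-influence scores with sequential
    outlier filtering and a no-feedback positive control; scores the Perceived
    Vulnerability to Disease questionnaire with Cronbach's alpha and greedy
    alpha-maximising item pruning; preprocesses EEG epochs (average reference,
    baseline correction, amplitude rejection, neighbour interpolation);
    performs per-timepoint multivariate decoding with stratified k-fold
    cross-validation, ROC-AUC sensitivity and temporal generalization;
    applies cluster-mass Monte-Carlo permutation inference to decoding
    time-courses and to brain-behaviour correlation series; fits
    random-intercept mixed models compared by BIC-approximated Bayes factors;
    and ships a calibrated synthetic-cohort generator so every stage is
    testable without external data.
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
    purrr,
    Rcpp,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    lme4,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
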