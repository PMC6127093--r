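# peersway

Tools for studying **susceptibility to social influence** in
peer-feedback face-evaluation experiments, with a focus on how perceived
vulnerability to disease relates to both the behavioural and the neural
response to peer disagreement.

In the task this package models, participants rate the trustworthiness of
faces on a 1–8 scale, see a peer-group rating that agrees with them or
deviates by ±2 (moderate) or ±3 (strong) points, and later re-rate the
same faces. The analysis chain is:

* **Design** — interleaved test/post-test block schedules with
  quota-exact feedback conditions (online scale: 48 faces; laboratory
  scale: 480 faces) and scale-edge-safe adaptive feedback assignment.
* **Behaviour** — the social-influence score per condition
  `s_c · mean(post − test)`, sign-flipped (`s_c = −1`) for
  negative-valence conditions so positive always means movement toward
  the peer rating; sequential ±2 SD outlier filters and a no-feedback
  positive control.
* **Questionnaire** — Perceived Vulnerability to Disease scoring
  (Perceived Infectability and Germ Aversion subscales, reverse-keyed
  items), Cronbach's alpha, and greedy alpha-maximizing item pruning.
* **EEG** — epoch preprocessing (average reference, baseline correction,
  ±100 µV rejection, neighbour interpolation) and time-resolved
  multivariate decoding: at each sample an L2-regularized logistic
  classifier on the 64-channel pattern, stratified 10-fold
  cross-validation, out-of-fold ROC-AUC, and train×test temporal
  generalization matrices whose diagonal reproduces the canonical
  time-course exactly.
* **Inference** — cluster-mass Monte-Carlo permutation tests: one-tailed
  t-tests against AUC = 0.5, clusters of ≥ 2 adjacent sub-threshold
  samples scored by summed AUC, subject-level sign-flip null
  (`*p < 0.01`); and brain–behaviour correlation clusters (runs of
  Pearson r ≥ 0.40, score-permutation null, `*p < 0.05`).
* **Models** — random-intercept linear mixed models of influence scores
  (ML, profiled likelihood, written from first principles and
  cross-checked against lme4), BIC-approximated Bayes factors
  `BF10 = exp((BIC₀ − BIC₁)/2)`, and the combination index
  `z(mean stage AUC) + z(PVD score)`.
* **Synthetic cohorts** — a generative model in which one latent
  vulnerability trait drives rating adjustment, questionnaire responses
  and the gain of two planted spatiotemporal EEG components
  (fronto-central 200–400 ms; occipito-parietal/right-frontal
  400–900 ms), so the entire pipeline is testable and power-checkable
  without any recorded data.

## Worked example

Simulate a 17-subject laboratory cohort and run the full chain:

```r
library(peersway)

params <- cohort_params(n_subjects = 17)          # paper-like preset
cohort <- simulate_cohort(params, design_config("lab"), seed = 42)

scores <- influence_scores(cohort$trials)
pvd    <- score_pvd(cohort$pvd)

times <- cohort$epochs[[1]]$times
auc <- t(sapply(cohort$epochs, function(ep)
  decode_timecourse(ep, disagreement_vs_agreement(), k = 10, seed = 42)$auc))

permutation_null_decoding(auc, n_perm = 1000, seed = 43, times = times)
#>   start end start_ms end_ms  mass mean_stat p_star significant
#> 1    45  58      240    370  8.34     0.596  0.046       FALSE
#> 2    63 109      420    880 29.92     0.637  0.001        TRUE

permutation_null_correlation(auc, pvd$z_pi, n_perm = 2000, seed = 44,
                             times = times)
#>   start end start_ms end_ms mass mean_stat p_star significant
#> 1    47  56      260    350  7.2     0.720 0.0365        TRUE
#> 2    65 108      440    870 35.7     0.811 0.0005        TRUE

models <- model_set(long_score_table(scores, pvd), "z_pi")
tidy(models$type1)
#>   term             estimate     se      t    df        p
#> 1 (Intercept)        0.864  0.0327 26.4      15 5.39e-14
#> 2 valence            0.0216 0.0369  0.585    47 5.61e- 1
#> 3 strength           0.260  0.0369  7.05     47 6.95e- 9
#> 4 z_pi               0.380  0.0337 11.3      15 1.02e- 8
#> 5 valence:strength   0.0353 0.0737  0.479    47 6.34e- 1
```

Reading the output: decoding separates disagreement from agreement
feedback in two temporal stages; the long sustained cluster (420–880 ms)
clears the `*p < 0.01` mass criterion, while the short early cluster has
too little summed AUC under the length-sensitive literal mass (it reaches
significance in the correlation analysis, whose threshold is
`*p < 0.05`). Decoding sensitivity correlates with the z-scored Perceived
Infectability score in both stage windows, and the mixed model recovers a
positive `z_pi` effect on social-influence scores (here β = 0.38,
t(15) = 11.3) with stronger adjustment after strong than moderate
disagreement (β = 0.26). `autoplot()` methods exist for decoding
time-courses and generalization matrices, and `plot_group_timecourse()`
overlays clusters on the group mean.

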