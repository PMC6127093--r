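---
title: "Models and methods behind peersway"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind peersway}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(peersway)
```

`peersway` implements an end-to-end analysis of susceptibility to social
influence in peer-feedback face-evaluation experiments: behavioural
scoring, questionnaire scoring, time-resolved multivariate EEG decoding,
cluster-mass permutation inference, and mixed-model evidence comparison —
plus a calibrated synthetic-cohort generator so that every stage can be
exercised and validated without access to any recorded dataset. This
vignette explains the models and the numerical choices, in the order data
flow through the pipeline.

## The task and its design

Participants rate the trustworthiness of unfamiliar faces on an integer
1–8 scale, see a (fictive) peer-group rating, and later re-rate the same
faces. The session is organised as interleaved pairs of blocks: a test
block of 8 new faces, then a post-test block replaying the same 8 faces in
a permuted order. Feedback falls into six conditions: agreement (peer
rating equals the participant's), four disagreement types crossing valence
(peer rating above or below) with strength (2 or 3 scale points), and
no-feedback control trials. Two presets are built in: an online-scale
design (6 block pairs, 48 faces; 12 agreement, 6 of each disagreement
type, 12 no-feedback) and a laboratory-scale design ten times larger
(60 block pairs, 480 faces), matched to EEG recording standards.

Because a +3 deviation from a rating of 7 would leave the scale,
conditions cannot be bound to trial positions in advance.
`generate_schedule()` therefore lays out blocks, faces and a
quota-exact *planned* condition sequence, and `assign_feedback()` draws
the actual condition per trial, uniformly among the condition types that
still have remaining quota *and* are feasible for the observed rating. If
no feasible type has quota left, the feasible type with the largest quota
deficit is assigned and the deviation is counted on the returned object —
totals stay as close to quota as the rating stream allows, and an
out-of-range fictive rating is never produced. Whether the original
experiments pre-assigned or adapted conditions is not decidable from the
design description alone; the adaptive scheme is this package's choice
because it is the only one that degrades gracefully at the scale edges.

## Behavioural scoring

The mean rating change of a condition is the mean of (post-test − test)
over its trials. The social-influence score flips the sign for
negative-valence conditions, so a positive score always means movement
*toward* the peer rating. For participant-level filtering the four
condition scores are aggregated by their unweighted mean — the conditions
have equal trial counts, so this matches any reasonable reading of a
single "disagreement score".

Outlier filtering (`qc_filter()`) is sequential and deliberately
non-iterative: first exclude participants outside mean ± 2 SD on the
overall disagreement score, then recompute mean and SD of the no-feedback
rating change on the survivors and exclude outside ± 2 SD again. A stage
with zero SD is degenerate and excludes nobody. Re-running a stage on its
own survivors with the original thresholds excludes nobody, which is the
idempotence property the tests check. The no-feedback trials also feed a
positive control (`nofeedback_bias_test()`): a one-sample t-test of the
mean change against zero, with an infinite-t sentinel when the sample has
zero variance but a nonzero mean.

## Questionnaire scoring

The Perceived Vulnerability to Disease questionnaire has 15 Likert items:
Perceived Infectability (items 2, 5, 6, 8, 10, 12, 14) and Germ Aversion
(items 1, 3, 4, 7, 9, 11, 13, 15), with items 3, 5, 11, 12, 13 and 14
reverse-scored as `(L + 1) − r`. The administration scale is configurable
and defaults to 7 points, the standard for this instrument. Internal
consistency is plain Cronbach's alpha,
`k/(k−1) · (1 − Σ s²ᵢ / s²_total)`. Note that raw alpha is *not*
invariant under heterogeneous per-item rescaling (only under a common
positive affine rescaling); since subscale items share one response
format, the raw formula is the right one here.

When a subscale is incoherent in a given sample, `maximize_alpha()`
prunes it greedily: at each step it removes the single item whose removal
most increases alpha, stopping at a target alpha (default 0.7), when no
removal helps, or at two items. Ties break toward the lowest item index.
Greedy one-at-a-time removal — not exhaustive subset search — is what
"sequentially removing detrimental items" means operationally, and the
returned trajectory is non-decreasing by construction. The four-item
"maximized" Germ Aversion score (items 1, 3, 7, 13) is available directly
from `score_pvd(..., maximize_ga = TRUE)`.

## EEG preprocessing

Epochs are stored as a trials × channels × samples array (`epoch_set`)
with a millisecond time axis (−200…1000 ms; 500 Hz in recording-standard
form, 100 Hz in desk-scale form) and an idealized spherical 10-10 montage
of 64 electrodes. Four operations cover the epoch-domain steps the
analysis needs, in this order: `average_reference()` (channel mean
removed per trial and sample; idempotent), `baseline_correct()`
(pre-stimulus window mean removed per trial and channel),
`reject_epochs()` (a trial is discarded if any sample on any channel
exceeds ±100 µV — the threshold is configurable), and
`interpolate_channel()` (inverse-distance-weighted mean of the k = 4
nearest montage neighbours; weights sum to one, so constant fields are
reproduced exactly). A channel qualifies for interpolation when it
exceeds the threshold in more than 25 % of all epochs
(`detect_bad_channels()`); this operationalizes "contributing to the
rejection of more than a quarter of epochs" in its simplest faithful
form. Spherical-spline interpolation was deliberately not implemented:
for whole-channel replacement on an idealized montage, distance-weighted
averaging is transparent, testable, and accurate to the local field
gradient, which is the error bound the tests assert. Continuous-data
filtering and ocular ICA are out of scope; the synthetic generator emits
band-limited epochs directly.

## Time-resolved decoding

`decode_timecourse()` asks, independently at every sample, how well the
64-channel voltage pattern separates two classes of trials. The
classifier family is a documented package choice: L2-regularized logistic
regression on z-standardized features (standardization estimated on the
training folds only, unit ridge penalty on the standardized scale), which
gives the class probabilities that ROC analysis needs and is the linear
default of EEG multivariate decoding. Trials are split once per call into
10 stratified folds (per-fold class counts within one trial of the global
proportions); the same fold assignment is reused at every timepoint and —
crucially — in `temporal_generalization()`, whose entry (t, t′) scores
the t-trained models on features from t′. Because folds, scalers and fits
are shared, the generalization diagonal reproduces the canonical
time-course *bit for bit*, which the acceptance suite checks with
`identical()`. Out-of-fold probabilities are pooled over trials and
summarized by `auc_score()`, the Mann–Whitney rank statistic with midrank
ties — tested against an exhaustive pairwise-concordance oracle.
Standardizing inside the training folds makes the whole time-course
invariant to a global positive rescaling of the data, and degenerate
(zero-variance) features are neutralized by the scaler rather than
crashing the fit. The per-timepoint × per-fold refitting loop is the
pipeline's hot spot and is implemented in C++ (RcppArmadillo IRLS); R
wrappers own all randomness, so a seed fixes the result exactly.

Contrasts are declared with `contrast_spec()` as a pair of disjoint
predicates over the trial table (class A coded 0, class B coded 1);
`disagreement_vs_agreement()` is the canonical one.
`label_adjustment()` classifies disagreement trials as adjusted
"towards" the peer rating (sign of the rating change matches the sign of
the disagreement), "away" (opposite sign), or "none" (no change —
excluded from towards/away contrasts, since a zero change carries no
direction). `median_split()` divides participants into high/low scorer
groups, sending exact ties with the median to the low group so the split
is deterministic.

## Cluster-mass permutation inference

Per-timepoint group inference uses one-sample one-tailed t-tests of AUC
against 0.5. Clusters are maximal runs of at least two adjacent
sub-threshold samples (the "adjacent dyads" rule: an isolated significant
sample is never a cluster), scored by the sum of the group-mean AUC over
the run. The null distribution of the maximum cluster mass is built by
flipping the sign of (AUC − 0.5) independently per subject — the standard
exchangeable null for a one-sample test — recomputing tests, clusters and
the max mass on each of 1000 permutations (the sign-flip algebra is fully
vectorized, since squared deviations are flip-invariant). A cluster's
`p_star` is the fraction of permutations reaching its mass, floored at
1/n_perm, and significance defaults to `p_star < 0.01`. The literal mass
(summed AUC) rewards cluster length as well as strength; a `centered`
option sums (AUC − 0.5) instead for users who want a pure effect-size
mass. The default stays literal because that is the procedure the
pipeline documents, and under the null either choice is exactly
calibrated — which the acceptance suite verifies empirically
(family-wise error within binomial tolerance of 0.05 over 200 null
simulations).

The brain–behaviour procedure (`permutation_null_correlation()`)
correlates, across subjects, each timepoint's AUC with a per-subject
score. Observed clusters are runs of at least two samples with Pearson
r ≥ 0.40 — the positive tail only, matching the directional hypothesis —
with mass Σr; the null permutes the score vector across subjects
(10 000 times at full scale), recomputing the r series and max mass.
Permutations resample the summary time-series, not the classifiers:
re-running thousands of cross-validated decoders inside the permutation
loop is neither implied by the procedure nor computationally sensible,
and the exchangeability argument applies to the subject-level summaries.

## Mixed models and evidence comparison

Social-influence scores are modelled as
`score ~ valence * strength + (1 | participant)` with deviation coding
(−0.5/+0.5), fitted by maximum likelihood. The fit is implemented
directly (`fit_random_intercept()`): the likelihood is profiled over the
variance ratio θ = σ²_b/σ²_e, where the block structure of the
random-intercept covariance gives a closed-form GLS solution and residual
variance for each θ, and the one-dimensional profile is maximized
numerically (on a log(1+θ) scale, boundary at θ = 0 checked explicitly).
The test suite cross-checks the log-likelihood and coefficients against a
brute-force θ grid and against `lme4::lmer` under ML. Degrees of freedom
follow the inner–outer convention: within-subject terms against
`n_obs − n_fixed − n_groups + 1`, between-subject covariates against
`n_groups − n_between − 1`, reproducing the df pattern of nested-design
reports (e.g. t(780) within / t(259) between for 261 participants × 4
conditions with one covariate).

Model evidence uses the Schwarz approximation
`BF10 = exp((BIC_base − BIC_alt)/2)`. Exact default-prior (JZS) Bayes
factors for mixed models require bespoke quadrature and a random-effect
prior scale that is not identifiable from the analysis description; the
BIC approximation is therefore substituted and labelled as such. Its
reliable output is the *ordering* of models — which enrichment beats the
baseline — not the magnitude of any particular Bayes factor, and the
tests only assert orderings (noise covariates lose on median; planted
main effects favour the main-effect model; planted interactions favour
the interaction model). `model_set()` packages the baseline, the
covariate-as-main-effect ("type 1") and the fully interacting ("type 2")
fits with their comparisons. `combination_index()` implements the joint
predictor: z-scored mean AUC over the two processing-stage windows
(200–400 and 400–900 ms) plus the z-scored questionnaire score.

## The synthetic cohort

One latent standard-normal vulnerability trait `v` per subject drives all
three data modalities:

* **Behaviour** — reliance on peer feedback `w = plogis(a + b·v)` with
  `a = −1.1, b = 0.8` (mean reliance ≈ 0.27, rising with vulnerability);
  initial ratings `round(clip(N(4.2, 1.5)))` — the anchor for typical
  trustworthiness ratings on this scale; post ratings
  `round(clip(test + w·(fictive − test) + N(0, 0.8)))`, with rounding and
  clipping applied after noise because on-screen ratings are integers.
* **Questionnaire** — each item loads on `v` (loading 1.4 for Perceived
  Infectability items, 0.75 for Germ Aversion; reverse-marked items
  generated sign-inverted) with unit unique noise, discretized to the
  7-point scale. These loadings were calibrated once so that, at n = 300,
  PI alpha lands in the 0.85–0.95 band and the z-PI score correlates
  above 0.9 with `v`; an optional `ga_noise_items` argument zeroes chosen
  GA loadings to emulate an incoherent subscale for pruning studies.
* **EEG** — each feedback epoch is the sum of two fixed spatiotemporal
  templates scaled by condition amplitude and subject gain
  `g = 1 + 0.45·v + N(0, 0.15)`: an early fronto-central component
  (Gaussian, peak 300 ms, support 200–400 ms) and a late sustained
  occipito-parietal/right-frontal component (400–900 ms, relative
  amplitude 1.35 to equalize the two stages' whitened discriminability).
  Agreement trials carry no component; moderate disagreement has
  amplitude 7 µV and strong 10 µV, so strength scales the neural
  response. Noise is spatially correlated Gaussian (exponential
  covariance, length scale 0.6 on the unit sphere) with AR(1) temporal
  structure (φ = 0.9), SD 10 µV per channel. Temporal profiles are
  exactly zero before stimulus onset, so noiseless baselines are exactly
  silent.

Amplitudes and links were calibrated once so that a desk-scale run
(17 subjects, the laboratory trial counts, 100 Hz) finishes a full
pipeline replicate in well under a minute while keeping detection power
for all three planted effects comfortably above one half; they are
versioned constants in `cohort_params()`, not tuning knobs. What the
generator does *not* emulate: biophysical source mixing, ocular and
muscle artifacts, drifts and line noise, non-Gaussian single-trial
variability, learning or fatigue across blocks, and item-level
questionnaire idiosyncrasies. Passing the recovery suite therefore shows
that the pipeline detects the statistical structure it assumes, under
that structure — it does not certify performance on recorded data.

## Problem sizes and reproducibility

The validation suite uses these scales, chosen as the package's own
desk-scale conditions: decoding-cluster and correlation-cluster
calibration on 200 null simulations of 17 subjects × 100 timepoints (200
and 500 permutations respectively); parameter recovery over 20 full
replicates at 100 Hz with 1000/2000 permutations; the AUC oracle on 1000
random instances. Every stochastic step takes an explicit seed, derived
seeds are spaced with fixed offsets, and the C++ kernel contains no
randomness of its own, so identical seeds reproduce every number
bit for bit. `scripts/acceptance.R` re-runs all of the above from scratch
and writes the resulting quantities as JSON.

## Known limitations

* The epoch container reads and writes a plain-text directory format;
  it is meant for the small epoch sets of tests and examples, not for
  full-size recordings.
* Cluster inference is temporal only; channel-space adjacency (and
  threshold-free enhancement) are out of scope.
* The BIC Bayes-factor approximation compresses all prior information
  into the sample-size penalty; magnitudes should not be compared across
  datasets.
* The greedy alpha maximization can stop at a local optimum by
  construction; this mirrors the sequential procedure it implements.
* Only the automatic amplitude-threshold part of artifact rejection is
  implemented; no manual review stage exists.
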