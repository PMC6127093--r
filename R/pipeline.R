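#' Run one end-to-end parameter-recovery replicate
#'
#' Simulates a cohort with [simulate_cohort()], then runs the full analysis
#' chain: per-subject decoding of disagreement vs agreement
#' ([decode_timecourse()]), the group cluster-mass permutation test
#' ([permutation_null_decoding()]), the AUC-score correlation-cluster test
#' against the z-scored Perceived Infectability score
#' ([permutation_null_correlation()]), and the type-1 mixed model of
#' social-influence scores with the z-PI covariate ([model_set()]).
#' Used as the package's recovery harness: with a positive
#' vulnerability-to-influence link and a positive vulnerability-to-gain
#' link in the generator, all three detections should succeed in most
#' replicates.
#'
#' @param params A [cohort_params()].
#' @param design A [design_config()] (default lab).
#' @param seed Master integer seed for the replicate.
#' @param n_perm_decoding,n_perm_correlation Permutation counts for the two
#'   cluster tests.
#' @param effect_window Planted effect window (ms) a significant decoding
#'   cluster must overlap to count as detected.
#' @return One-row tibble: `seed`, `positive_covariate` (type-1 z-PI
#'   estimate > 0 with BF10 > 1), `decoding_cluster` (significant cluster
#'   overlapping the effect window at p* < 0.01), `correlation_cluster`
#'   (significant positive r-cluster at p* < 0.05), plus the covariate
#'   estimate, its BF10, and the largest cluster masses.
#' @export
run_recovery <- function(params = cohort_params(),
                         design = design_config("lab"), seed = 1,
                         n_perm_decoding = 1000, n_perm_correlation = 2000,
                         effect_window = c(200, 900)) {
  seed <- as.integer(seed)
  coh <- simulate_cohort(params, design, seed = seed)
  times <- coh$epochs[[1]]$times
  A <- t(vapply(coh$epochs, function(ep) {
    decode_timecourse(ep, disagreement_vs_agreement(), k = 10,
                      seed = seed)$auc
  }, numeric(length(times))))
  dec <- permutation_null_decoding(A, n_perm = n_perm_decoding,
                                   seed = seed + 1L, times = times)
  pvd <- score_pvd(coh$pvd)
  corr <- permutation_null_correlation(A, pvd$z_pi,
                                       n_perm = n_perm_correlation,
                                       seed = seed + 2L, times = times)
  scores <- influence_scores(coh$trials)
  long <- long_score_table(scores, pvd)
  ms <- model_set(long, "z_pi")
  cov_row <- filter(tidy(ms$type1), .data$term == "z_pi")
  bf1 <- ms$comparison$bf10_vs_baseline[ms$comparison$model == "type1"]
  overlaps <- function(cl) {
    nrow(cl) > 0 && any(cl$significant &
                          cl$end_ms >= effect_window[1] &
                          cl$start_ms <= effect_window[2])
  }
  tibble(seed = seed,
         positive_covariate = cov_row$estimate > 0 && bf1 > 1,
         decoding_cluster = overlaps(dec),
         correlation_cluster = nrow(corr) > 0 && any(corr$significant),
         covariate_estimate = cov_row$estimate,
         covariate_bf10 = bf1,
         max_decoding_mass = if (nrow(dec)) max(dec$mass) else 0,
         max_correlation_mass = if (nrow(corr)) max(corr$mass) else 0)
}
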