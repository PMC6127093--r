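#' Mean rating change per condition
#'
#' The mean over a condition's trials of (post-test rating minus test
#' rating): positive values mean the participant raised the trustworthiness
#' rating after seeing the peer feedback.
#'
#' @param trials Trial tibble in wide form (one row per face with
#'   `test_rating` and `post_rating`) or the two-phase schedule form, for one
#'   participant.
#' @param condition A single condition code from [condition_levels()].
#' @return Signed mean change in rating-scale points.
#' @export
mean_rating_change <- function(trials, condition) {
  w <- pair_trials(trials)
  w <- filter(w, .data$condition == !!condition)
  if (nrow(w) == 0L) {
    abort(sprintf("no trials in condition '%s'", condition),
          class = "peersway_missing_condition_error")
  }
  mean(w$post_rating - w$test_rating)
}

# Collapse the two-phase schedule into one row per (participant, face) with
# test_rating and post_rating side by side; checks the pairing invariant.
pair_trials <- function(trials) {
  if (!"phase" %in% names(trials) || all(!is.na(trials$post_rating))) {
    needed <- c("participant", "condition", "test_rating", "post_rating")
    if (all(needed %in% names(trials)) &&
        (!"phase" %in% names(trials) || all(trials$phase == "test"))) {
      return(trials)
    }
  }
  test <- filter(trials, .data$phase == "test")
  post <- filter(trials, .data$phase == "post_test")
  w <- inner_join(
    select(test, "participant", "face_id", "condition", "fictive_rating",
           "test_rating"),
    select(post, "participant", "face_id", "post_rating"),
    by = c("participant", "face_id"))
  if (nrow(w) != nrow(test) || nrow(w) != nrow(post)) {
    abort("unmatched test/post-test face pairs", class = "peersway_data_error")
  }
  w
}

#' Social-influence score for a disagreement condition
#'
#' Mean rating change with the sign flipped for negative-valence conditions,
#' so positive values always mean movement toward the peer rating: the
#' greater the score, the greater the susceptibility to social influence.
#'
#' @inheritParams mean_rating_change
#' @param condition One of the four disagreement conditions.
#' @return Signed score in rating-scale points.
#' @export
social_influence_score <- function(trials, condition) {
  if (!condition %in% disagreement_conditions()) {
    abort("social-influence scores are defined for disagreement conditions only; use mean_rating_change()",
          class = "peersway_condition_error")
  }
  s <- if (startsWith(condition, "neg")) -1 else 1
  s * mean_rating_change(trials, condition)
}

#' Per-participant score table
#'
#' Computes, for every participant, the social-influence score in each of
#' the four disagreement conditions (sign-corrected), the plain mean rating
#' change for agreement and no-feedback trials, and the overall
#' social-influence score (unweighted mean of the four condition scores).
#'
#' @param trials Trial tibble covering one or more participants (two-phase
#'   schedule or paired wide form).
#' @return A tibble with columns `participant`, `pos_mod`, `pos_strong`,
#'   `neg_mod`, `neg_strong`, `agree`, `no_feedback`, `si_overall`.
#' @export
influence_scores <- function(trials) {
  w <- pair_trials(trials)
  signed <- w |>
    mutate(sgn = case_when(
      .data$condition %in% c("neg_mod", "neg_strong") ~ -1,
      .default = 1),
      score = .data$sgn * (.data$post_rating - .data$test_rating))
  signed |>
    group_by(.data$participant, .data$condition) |>
    summarise(score = mean(.data$score), .groups = "drop") |>
    pivot_wider(names_from = "condition", values_from = "score") |>
    mutate(si_overall = (.data$pos_mod + .data$pos_strong +
                           .data$neg_mod + .data$neg_strong) / 4)
}

#' Sequential outlier filtering with a no-feedback positive control
#'
#' Two one-pass filters, applied in order: (1) exclude participants whose
#' overall disagreement social-influence score lies outside the sample mean
#' +/- 2 SD; (2) recompute mean and SD of the no-feedback mean rating change
#' on the stage-1 survivors and exclude outside +/- 2 SD. A zero-SD stage is
#' degenerate and excludes nobody. Filters are not iterated.
#'
#' @param scores Score table from [influence_scores()] (needs `participant`,
#'   `si_overall`, `no_feedback`).
#' @param n_sd Width of the exclusion band in SDs (default 2).
#' @return A list of class `qc_report`: `retained` (participant ids),
#'   `excluded` (tibble of id, stage, value), counts `n_input`,
#'   `n_after_si_filter`, `n_after_nofeedback_filter`, and the survivor
#'   no-feedback `nf_mean`/`nf_sd`.
#' @export
qc_filter <- function(scores, n_sd = 2) {
  if (nrow(scores) < 3L) {
    abort("need at least 3 participants for outlier filtering",
          class = "peersway_sample_error")
  }
  flag_outliers <- function(x) {
    s <- sd(x)
    if (!is.finite(s) || s == 0) return(rep(FALSE, length(x)))
    abs(x - mean(x)) > n_sd * s
  }
  out1 <- flag_outliers(scores$si_overall)
  stage1 <- scores[!out1, , drop = FALSE]
  out2 <- flag_outliers(stage1$no_feedback)
  stage2 <- stage1[!out2, , drop = FALSE]
  excluded <- bind_rows(
    tibble(participant = scores$participant[out1], stage = "si_score",
           value = scores$si_overall[out1]),
    tibble(participant = stage1$participant[out2], stage = "no_feedback",
           value = stage1$no_feedback[out2]))
  structure(list(
    retained = stage2$participant,
    excluded = excluded,
    n_input = nrow(scores),
    n_after_si_filter = nrow(stage1),
    n_after_nofeedback_filter = nrow(stage2),
    nf_mean = mean(stage2$no_feedback),
    nf_sd = sd(stage2$no_feedback)), class = "qc_report")
}

#' @export
print.qc_report <- function(x, ...) {
  cat(sprintf("QC report: %d -> %d (SI filter) -> %d (no-feedback filter)\n",
              x$n_input, x$n_after_si_filter, x$n_after_nofeedback_filter))
  cat(sprintf("survivor no-feedback change: M = %.3f, SD = %.3f\n",
              x$nf_mean, x$nf_sd))
  invisible(x)
}

#' No-feedback positive-control test
#'
#' One-sample two-sided t-test of the per-participant no-feedback mean
#' rating change against zero. An unbiased sample (rating criterion stable
#' in the absence of peer feedback) should not differ from zero.
#'
#' @param changes Numeric vector of per-participant no-feedback mean rating
#'   changes.
#' @return A one-row tibble with `mean`, `sd`, `t`, `df`, `p`. With zero
#'   variance and a nonzero mean, `t` is `+/-Inf` and `p = 0`.
#' @export
nofeedback_bias_test <- function(changes) {
  n <- length(changes)
  if (n < 2L) abort("need n >= 2", class = "peersway_sample_error")
  m <- mean(changes)
  s <- sd(changes)
  if (s == 0) {
    t_stat <- if (m == 0) 0 else sign(m) * Inf
    p <- if (m == 0) 1 else 0
  } else {
    t_stat <- m / (s / sqrt(n))
    p <- 2 * pt(abs(t_stat), df = n - 1, lower.tail = FALSE)
  }
  tibble(mean = m, sd = s, t = t_stat, df = n - 1L, p = p)
}
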