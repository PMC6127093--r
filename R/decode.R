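#' Stratified k-fold assignment
#'
#' Splits trials into `k` test folds, randomly within each class, so every
#' trial lands in exactly one test fold and per-fold class counts differ
#' from the global proportions by at most one trial.
#'
#' @param labels Binary label vector (0/1, logical, or two-level factor).
#' @param k Number of folds (default 10).
#' @param seed Integer RNG seed.
#' @return Integer vector of test-fold ids (1..k), one per trial.
#' @export
stratified_folds <- function(labels, k = 10, seed = NULL) {
  y <- as_binary_labels(labels)
  if (any(table(y) < k)) {
    abort(sprintf("each class needs at least k = %d trials", k),
          class = "peersway_validation_error")
  }
  folds <- integer(length(y))
  with_rng(seed, {
    for (cls in unique(y)) {
      idx <- sample(which(y == cls))
      folds[idx] <- rep_len(seq_len(k), length(idx))
    }
  })
  folds
}

as_binary_labels <- function(labels) {
  if (is.factor(labels)) labels <- as.integer(labels) - 1L
  if (is.logical(labels)) labels <- as.integer(labels)
  u <- sort(unique(labels))
  if (length(u) != 2L) {
    abort("labels must have exactly two classes",
          class = "peersway_validation_error")
  }
  as.integer(labels == u[2])
}

#' Define a decoding contrast
#'
#' A named pair of predicates over the trial-label table selecting the two
#' stimulus classes; trials matching neither predicate are excluded, and a
#' trial matching both is an error.
#'
#' @param name Contrast name.
#' @param a,b Unquoted predicate expressions evaluated in the label table
#'   (class A coded 0, class B coded 1).
#' @param lock Epoch time-locking this contrast expects
#'   (`"feedback"` or `"face"`); informational.
#' @return A `contrast_spec` object.
#' @examples
#' disagreement_vs_agreement()
#' @export
contrast_spec <- function(name, a, b, lock = c("feedback", "face")) {
  structure(list(name = name, a = rlang::enquo(a), b = rlang::enquo(b),
                 lock = match.arg(lock)),
            class = "contrast_spec")
}

#' @rdname contrast_spec
#' @export
disagreement_vs_agreement <- function() {
  contrast_spec("disagreement_vs_agreement",
                a = .data$condition == "agree",
                b = .data$condition %in% disagreement_conditions(),
                lock = "feedback")
}

#' Classify rating adjustments as towards or away from the peer rating
#'
#' A disagreement trial is adjusted "towards" the peer rating when the sign
#' of (post - test) matches the sign of (fictive - test) and the rating
#' actually changed; "away" when the signs are opposite; "none" when the
#' post-test rating equals the test rating (excluded from towards/away
#' contrasts).
#'
#' @param trials Trial table with `test_rating`, `post_rating`,
#'   `fictive_rating` (paired wide form, or the two-phase schedule).
#' @return The paired table with an `adjustment` column
#'   (`"towards"`/`"away"`/`"none"`, `NA` where no fictive rating exists).
#' @export
label_adjustment <- function(trials) {
  w <- pair_trials(trials)
  change <- sign(w$post_rating - w$test_rating)
  dev <- sign(w$fictive_rating - w$test_rating)
  w$adjustment <- case_when(
    is.na(w$fictive_rating) ~ NA_character_,
    change == 0 ~ "none",
    change == dev ~ "towards",
    .default = "away")
  w
}

#' Build binary labels for a contrast
#'
#' @param trials Trial-label table (one row per epoch, aligned with the
#'   epoch set).
#' @param contrast A [contrast_spec()].
#' @return A tibble with `trial` (row index into `trials`) and `label`
#'   (0 = class A, 1 = class B).
#' @export
build_labels <- function(trials, contrast) {
  in_a <- rlang::eval_tidy(contrast$a, data = trials)
  in_b <- rlang::eval_tidy(contrast$b, data = trials)
  in_a[is.na(in_a)] <- FALSE
  in_b[is.na(in_b)] <- FALSE
  if (any(in_a & in_b)) {
    abort("contrast predicates are not disjoint",
          class = "peersway_validation_error")
  }
  if (!any(in_a) || !any(in_b)) {
    abort(sprintf("contrast '%s' selects an empty class", contrast$name),
          class = "peersway_contrast_error")
  }
  tibble(trial = which(in_a | in_b),
         label = as.integer(in_b[in_a | in_b]))
}

#' ROC area under the curve
#'
#' Mann-Whitney rank formulation with midrank tie handling: the probability
#' that a randomly chosen class-1 trial receives a higher score than a
#' randomly chosen class-0 trial, ties counting one half.
#'
#' @param probabilities Classifier scores.
#' @param labels Binary labels.
#' @return AUC in `[0, 1]`.
#' @export
auc_score <- function(probabilities, labels) {
  if (length(unique(labels)) < 2L) {
    abort("AUC undefined: only one class present",
          class = "peersway_degenerate_error")
  }
  y <- as_binary_labels(labels)
  n1 <- sum(y == 1L)
  n0 <- sum(y == 0L)
  if (n1 == 0L || n0 == 0L) {
    abort("AUC undefined: only one class present",
          class = "peersway_degenerate_error")
  }
  r <- rank(probabilities, ties.method = "average")
  (sum(r[y == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Per-timepoint decoding time-course
#'
#' For every sample of the epoch independently, fits an L2-regularized
#' logistic classifier on the 64-channel feature vector (features
#' z-standardized with training-fold statistics), pools out-of-fold
#' probabilities across the stratified folds, and scores them with
#' [auc_score()]. One fold assignment is drawn per call and reused at every
#' timepoint.
#'
#' @param epochs An [epoch_set()].
#' @param labels Binary label vector aligned with the epochs, or a
#'   [contrast_spec()] applied to `epochs$labels` (the epoch set is then
#'   subset to the contrast's trials).
#' @param k Folds (default 10).
#' @param seed Integer RNG seed for the fold draw.
#' @param lambda Ridge penalty on the standardized features (default 1).
#' @return A `decoding_timecourse`: list with `auc` (per-sample vector),
#'   `times`, `folds`, `labels`, `prob` (out-of-fold probability matrix),
#'   `participant`.
#' @export
decode_timecourse <- function(epochs, labels, k = 10, seed = NULL,
                              lambda = 1) {
  prep <- prepare_decoding(epochs, labels, k, seed)
  res <- cpp_decode_timecourse(as.numeric(prep$data), dim(prep$data),
                               prep$folds, prep$y, lambda)
  structure(list(auc = as.numeric(res$auc), times = epochs$times,
                 folds = prep$folds, labels = prep$y, prob = res$prob,
                 participant = epochs$participant),
            class = "decoding_timecourse")
}

prepare_decoding <- function(epochs, labels, k, seed) {
  if (inherits(labels, "contrast_spec")) {
    if (is.null(epochs$labels)) {
      abort("epoch set has no label table", class = "peersway_validation_error")
    }
    lab <- build_labels(epochs$labels, labels)
    epochs <- subset_epochs(epochs, lab$trial)
    y <- lab$label
  } else {
    y <- as_binary_labels(labels)
    if (length(y) != dim(epochs$data)[1]) {
      abort("labels not aligned with epochs",
            class = "peersway_validation_error")
    }
  }
  folds <- stratified_folds(y, k = k, seed = seed)
  list(data = epochs$data, y = y, folds = folds)
}

#' Temporal generalization matrix
#'
#' Trains the per-timepoint classifiers exactly as [decode_timecourse()]
#' (same folds under the same seed) and evaluates each training-time model
#' on the features of every testing time, giving a train-time x test-time
#' AUC matrix whose diagonal reproduces the canonical time-course.
#'
#' @inheritParams decode_timecourse
#' @return A `tg_matrix`: list with `auc` (times x times matrix), `times`,
#'   `folds`, `participant`.
#' @export
temporal_generalization <- function(epochs, labels, k = 10, seed = NULL,
                                    lambda = 1) {
  prep <- prepare_decoding(epochs, labels, k, seed)
  tgm <- cpp_temporal_generalization(as.numeric(prep$data), dim(prep$data),
                                     prep$folds, prep$y, lambda)
  structure(list(auc = tgm, times = epochs$times, folds = prep$folds,
                 participant = epochs$participant),
            class = "tg_matrix")
}

#' Median split of a score vector
#'
#' Scores strictly above the sample median go to `"high"`, the rest
#' (including exact ties with the median) to `"low"`.
#'
#' @param scores Numeric vector.
#' @return Character vector `"high"`/`"low"` of the same length.
#' @export
median_split <- function(scores) {
  if (length(scores) < 2L) {
    abort("need at least 2 scores", class = "peersway_sample_error")
  }
  m <- median(scores)
  out <- ifelse(scores > m, "high", "low")
  if (all(out == "low")) warn("all scores at or below the median: no high group")
  out
}

#' @export
print.decoding_timecourse <- function(x, ...) {
  cat(sprintf("<decoding_timecourse> %s: %d samples, mean AUC %.3f, peak %.3f at %g ms\n",
              x$participant, length(x$auc), mean(x$auc), max(x$auc),
              x$times[which.max(x$auc)]))
  invisible(x)
}

#' @export
print.tg_matrix <- function(x, ...) {
  cat(sprintf("<tg_matrix> %s: %d x %d, diagonal mean AUC %.3f\n",
              x$participant, nrow(x$auc), ncol(x$auc), mean(diag(x$auc))))
  invisible(x)
}

#' Tidy a decoding time-course
#' @param x A `decoding_timecourse`.
#' @param ... Unused.
#' @return Tibble with `time_ms` and `auc`.
#' @export
tidy.decoding_timecourse <- function(x, ...) {
  tibble(time_ms = x$times, auc = x$auc)
}

#' Tidy a temporal generalization matrix
#' @param x A `tg_matrix`.
#' @param ... Unused.
#' @return Long tibble with `train_ms`, `test_ms`, `auc`.
#' @export
tidy.tg_matrix <- function(x, ...) {
  tibble(train_ms = rep(x$times, times = length(x$times)),
         test_ms = rep(x$times, each = length(x$times)),
         auc = as.numeric(x$auc))
}

#' Mean AUC over the two processing-stage windows
#'
#' Averages a decoding time-course over the union of the early
#' fronto-central stage (default 200-400 ms) and the late sustained stage
#' (default 400-900 ms) — the per-subject summary entering the combination
#' index.
#'
#' @param tc A `decoding_timecourse` (or numeric AUC vector with `times`).
#' @param times Time axis when `tc` is a bare vector.
#' @param stage1,stage2 Window bounds in ms.
#' @return Mean AUC over the pooled windows.
#' @export
mean_stage_auc <- function(tc, times = NULL, stage1 = c(200, 400),
                           stage2 = c(400, 900)) {
  if (inherits(tc, "decoding_timecourse")) {
    times <- tc$times
    tc <- tc$auc
  }
  sel <- (times >= stage1[1] & times <= stage1[2]) |
    (times >= stage2[1] & times <= stage2[2])
  mean(tc[sel])
}
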