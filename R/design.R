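#' Feedback-condition levels
#'
#' Condition codes used throughout the package: `agree` (the peer rating
#' matches the participant's rating), four disagreement types crossing
#' valence (positive/negative deviation of the peer rating) with strength
#' (moderate = 2 points, strong = 3 points), and `no_feedback` control
#' trials (a question mark instead of a peer rating).
#'
#' @return Character vector of the six condition codes.
#' @export
condition_levels <- function() {
  c("agree", "pos_mod", "pos_strong", "neg_mod", "neg_strong", "no_feedback")
}

#' @rdname condition_levels
#' @export
disagreement_conditions <- function() {
  c("pos_mod", "pos_strong", "neg_mod", "neg_strong")
}

#' Build a trial-design configuration
#'
#' Describes one participant's session: interleaved pairs of test and
#' post-test blocks, the per-condition trial quotas, and the fictive-rating
#' offsets. Two presets are provided: the `"online"` design (6 block pairs of
#' 8 trials: 12 agreement, 6 of each disagreement type, 12 no-feedback over
#' 48 faces) and the `"lab"` design scaled up tenfold for EEG recording
#' (60 block pairs, 480 faces).
#'
#' @param design `"online"` or `"lab"` preset, or `"custom"` with the
#'   remaining arguments supplied.
#' @param n_block_pairs Number of test/post-test block pairs.
#' @param trials_per_block Trials (faces) per block.
#' @param quota Named integer vector of per-condition trial counts; names
#'   must be the [condition_levels()].
#' @param scale_min,scale_max Rating-scale bounds (integer Likert points).
#' @return A `design_config` list with elements `n_block_pairs`,
#'   `trials_per_block`, `quota`, `deltas`, `scale_min`, `scale_max`.
#' @examples
#' cfg <- design_config("online")
#' sum(cfg$quota) == cfg$n_block_pairs * cfg$trials_per_block
#' @export
design_config <- function(design = c("online", "lab", "custom"),
                          n_block_pairs = NULL, trials_per_block = 8,
                          quota = NULL, scale_min = 1, scale_max = 8) {
  design <- match.arg(design)
  if (design == "online") {
    n_block_pairs <- n_block_pairs %||% 6L
    quota <- quota %||% c(agree = 12L, pos_mod = 6L, pos_strong = 6L,
                          neg_mod = 6L, neg_strong = 6L, no_feedback = 12L)
  } else if (design == "lab") {
    n_block_pairs <- n_block_pairs %||% 60L
    quota <- quota %||% c(agree = 120L, pos_mod = 60L, pos_strong = 60L,
                          neg_mod = 60L, neg_strong = 60L, no_feedback = 120L)
  } else {
    if (is.null(n_block_pairs) || is.null(quota)) {
      abort("custom designs need `n_block_pairs` and `quota`",
            class = "peersway_config_error")
    }
  }
  if (!setequal(names(quota), condition_levels())) {
    abort("`quota` must be named by the six condition levels",
          class = "peersway_config_error")
  }
  quota <- quota[condition_levels()]
  cfg <- structure(
    list(design = design,
         n_block_pairs = as.integer(n_block_pairs),
         trials_per_block = as.integer(trials_per_block),
         quota = quota,
         deltas = c(agree = 0L, pos_mod = 2L, pos_strong = 3L,
                    neg_mod = -2L, neg_strong = -3L, no_feedback = NA_integer_),
         scale_min = as.integer(scale_min),
         scale_max = as.integer(scale_max)),
    class = "design_config")
  validate_design(cfg)
  cfg
}

#' Validate a design configuration
#'
#' Checks the structural invariants: quotas sum to the number of trial
#' slots, moderate offsets have magnitude 2 and strong offsets magnitude 3,
#' and the rating scale is a non-degenerate integer interval.
#'
#' @param config A [design_config()].
#' @return `config`, invisibly; aborts with class
#'   `peersway_config_error` on violation.
#' @export
validate_design <- function(config) {
  n_slots <- config$n_block_pairs * config$trials_per_block
  if (sum(config$quota) != n_slots) {
    abort(sprintf("quota sums to %d but the design has %d trial slots",
                  sum(config$quota), n_slots),
          class = "peersway_config_error")
  }
  if (any(abs(config$deltas[c("pos_mod", "neg_mod")]) != 2) ||
      any(abs(config$deltas[c("pos_strong", "neg_strong")]) != 3)) {
    abort("moderate deltas must be +/-2 and strong deltas +/-3",
          class = "peersway_config_error")
  }
  if (config$scale_max <= config$scale_min) {
    abort("rating scale is degenerate", class = "peersway_config_error")
  }
  invisible(config)
}

#' Generate an interleaved test/post-test trial schedule
#'
#' Lays out one participant's session: `n_block_pairs` pairs of blocks, each
#' pair showing `trials_per_block` unique faces once in the test block and
#' once more, in a freshly permuted order, in the following post-test block.
#' Conditions are allocated by shuffling the quota multiset across test
#' trials, so per-condition counts match the quota exactly for every seed.
#' Fictive ratings are left unassigned (`NA`): they depend on the
#' participant's test rating and are filled in by [assign_feedback()].
#'
#' @param config A [design_config()].
#' @param participant Participant identifier stored in the table.
#' @param seed Integer RNG seed; identical seeds give identical schedules.
#' @return A tibble with one row per trial (both phases) and columns
#'   `participant`, `block_pair`, `phase` (`"test"`/`"post_test"`),
#'   `trial_index` (within phase), `face_id`, `condition`, `test_rating`,
#'   `fictive_rating`, `post_rating` (the last three `NA` until filled).
#' @examples
#' sch <- generate_schedule(design_config("online"), seed = 1)
#' table(dplyr::filter(sch, phase == "test")$condition)
#' @export
generate_schedule <- function(config, participant = "P01", seed = NULL) {
  validate_design(config)
  n_faces <- config$n_block_pairs * config$trials_per_block
  with_rng(seed, {
    cond_seq <- sample(rep(names(config$quota), times = config$quota))
    face_ids <- sprintf("face_%03d", seq_len(n_faces))
    test <- tibble(
      participant = participant,
      block_pair = rep(seq_len(config$n_block_pairs),
                       each = config$trials_per_block),
      phase = "test",
      trial_index = seq_len(n_faces),
      face_id = face_ids,
      condition = cond_seq)
    post <- test |>
      group_by(.data$block_pair) |>
      mutate(face_id = sample(.data$face_id),
             phase = "post_test") |>
      ungroup() |>
      select(!"condition") |>
      left_join(select(test, "face_id", "condition"), by = "face_id") |>
      mutate(trial_index = seq_len(n_faces))
    bind_rows(test, post) |>
      mutate(test_rating = NA_integer_, fictive_rating = NA_integer_,
             post_rating = NA_integer_) |>
      arrange(.data$block_pair, desc(.data$phase), .data$trial_index)
  })
}

# Which conditions can legally follow a given test rating: the fictive
# rating test + delta must stay on the scale (agree/no_feedback always can).
feasible_conditions <- function(rating, config) {
  fict <- rating + config$deltas
  ok <- is.na(fict) | (fict >= config$scale_min & fict <= config$scale_max)
  ok["agree"] <- TRUE
  names(config$deltas)[ok]
}

#' Assign feedback conditions and fictive ratings given observed test ratings
#'
#' Walks the test-phase trials in presentation order, drawing for each trial
#' a condition uniformly among the condition types that still have remaining
#' quota *and* whose fictive rating (`test_rating + delta`) stays within the
#' rating scale. If no condition with remaining quota is feasible, the
#' feasible condition with the largest quota deficit is assigned instead
#' (keeping totals as close to quota as possible) and the deviation is
#' counted in the `quota_deviations` attribute of the result. A fictive
#' rating outside the scale is never emitted.
#'
#' @param trials Schedule tibble from [generate_schedule()] with
#'   `test_rating` filled for test-phase rows.
#' @param config The matching [design_config()].
#' @param seed Integer RNG seed for the condition draws.
#' @return The schedule with `condition` and `fictive_rating` set on both
#'   phases (post-test rows inherit from their face's test trial); attribute
#'   `quota_deviations` counts fallback assignments.
#' @export
assign_feedback <- function(trials, config, seed = NULL) {
  test <- filter(trials, .data$phase == "test") |> arrange(.data$trial_index)
  if (anyNA(test$test_rating)) {
    abort("all test-phase trials need a `test_rating` before feedback assignment",
          class = "peersway_data_error")
  }
  if (any(test$test_rating < config$scale_min |
          test$test_rating > config$scale_max)) {
    abort("test ratings outside the rating scale", class = "peersway_data_error")
  }
  remaining <- config$quota
  assigned <- setNames(integer(length(remaining)), names(remaining))
  cond <- character(nrow(test))
  deviations <- 0L
  with_rng(seed, {
    for (i in seq_len(nrow(test))) {
      feas <- feasible_conditions(test$test_rating[i], config)
      pool <- feas[remaining[feas] > 0L]
      if (length(pool) > 0L) {
        pick <- if (length(pool) == 1L) pool else sample(pool, 1L)
      } else {
        deficit <- config$quota[feas] - assigned[feas]
        pick <- feas[which.max(deficit)]
        deviations <- deviations + 1L
      }
      cond[i] <- pick
      remaining[pick] <- remaining[pick] - 1L
      assigned[pick] <- assigned[pick] + 1L
    }
  })
  test$condition <- cond
  test$fictive_rating <- ifelse(
    cond == "no_feedback", NA_integer_,
    test$test_rating + config$deltas[cond])
  out <- trials |>
    select(!c("condition", "fictive_rating")) |>
    left_join(select(test, "face_id", "condition", "fictive_rating"),
              by = "face_id") |>
    left_join(select(test, "face_id", test_rating_test = "test_rating"),
              by = "face_id") |>
    mutate(test_rating = .data$test_rating_test) |>
    select("participant", "block_pair", "phase", "trial_index", "face_id",
           "condition", "test_rating", "fictive_rating", "post_rating")
  if (deviations > 0L) {
    inform(sprintf("feedback assignment: %d quota fallback(s) at scale edges",
                   deviations))
  }
  attr(out, "quota_deviations") <- deviations
  out
}
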