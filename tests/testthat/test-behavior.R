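test_that("mean rating change and influence scores follow their definitions", {
  tr <- make_paired_trials(
    conditions = c("neg_strong", "pos_mod", "pos_mod", "agree"),
    test = c(4, 3, 4, 5), post = c(1, 5, 4, 5),
    fictive = c(1, 5, 6, 5))
  expect_equal(mean_rating_change(tr, "neg_strong"), -3)
  expect_equal(mean_rating_change(tr, "pos_mod"), 1)
  expect_equal(mean_rating_change(tr, "agree"), 0)
  # sign flip for negative valence: moving down toward a lower peer rating
  # counts as positive influence
  expect_equal(social_influence_score(tr, "neg_strong"), 3)
  expect_equal(social_influence_score(tr, "pos_mod"), 1)
  expect_error(social_influence_score(tr, "agree"),
               class = "peersway_condition_error")
  expect_error(mean_rating_change(tr, "neg_mod"),
               class = "peersway_missing_condition_error")
})

test_that("a move away from the peer rating scores negative", {
  tr <- make_paired_trials(conditions = c("neg_mod", "neg_mod"),
                           test = c(4, 4), post = c(5, 4), fictive = c(2, 2))
  expect_equal(social_influence_score(tr, "neg_mod"), -0.5)
})

test_that("mirror symmetry: reflecting the rating scale leaves influence scores unchanged", {
  set.seed(21)
  for (rep in 1:20) {
    conds <- sample(disagreement_conditions(), 40, replace = TRUE)
    test <- sample(3:6, 40, replace = TRUE)
    delta <- c(pos_mod = 2, pos_strong = 3, neg_mod = -2, neg_strong = -3)[conds]
    fict <- test + delta
    post <- pmax(1, pmin(8, test + sample(-2:2, 40, replace = TRUE)))
    tr <- make_paired_trials(conditions = conds, test = test, post = post,
                             fictive = fict)
    mirrored <- tr |>
      dplyr::mutate(
        test_rating = 9L - test_rating,
        post_rating = 9L - post_rating,
        fictive_rating = 9L - fictive_rating,
        condition = dplyr::recode(condition,
                                  pos_mod = "neg_mod", neg_mod = "pos_mod",
                                  pos_strong = "neg_strong",
                                  neg_strong = "pos_strong"))
    for (cond in unique(conds)) {
      mirror_cond <- dplyr::recode(cond,
                                   pos_mod = "neg_mod", neg_mod = "pos_mod",
                                   pos_strong = "neg_strong",
                                   neg_strong = "pos_strong")
      expect_equal(social_influence_score(tr, cond),
                   social_influence_score(mirrored, mirror_cond))
    }
  }
})

test_that("qc_filter removes planted outliers and only those, sequentially", {
  set.seed(3)
  n <- 60
  base <- tibble::tibble(
    participant = sprintf("P%02d", 1:n),
    pos_mod = rnorm(n, 0.5, 0.1), pos_strong = rnorm(n, 0.7, 0.1),
    neg_mod = rnorm(n, 0.5, 0.1), neg_strong = rnorm(n, 0.7, 0.1),
    agree = rnorm(n, 0, 0.05), no_feedback = rnorm(n, 0, 0.05))
  base$si_overall <- rowMeans(base[disagreement_conditions()])
  # plant 11 gross stage-1 outliers and 2 stage-2 outliers among survivors
  out1 <- 1:11
  base$si_overall[out1] <- base$si_overall[out1] + 5
  out2 <- 12:13
  base$no_feedback[out2] <- base$no_feedback[out2] + 3
  rep <- qc_filter(base)
  expect_equal(rep$n_input, 60)
  expect_equal(rep$n_after_si_filter, 49)
  expect_equal(rep$n_after_nofeedback_filter, 47)
  expect_setequal(rep$excluded$participant[rep$excluded$stage == "si_score"],
                  base$participant[out1])
  expect_setequal(rep$excluded$participant[rep$excluded$stage == "no_feedback"],
                  base$participant[out2])
  # verify stage-1 exclusions against direct recomputation on the
  # contaminated sample
  z <- abs(base$si_overall - mean(base$si_overall)) / sd(base$si_overall)
  expect_setequal(base$participant[z > 2],
                  rep$excluded$participant[rep$excluded$stage == "si_score"])
})

test_that("qc_filter is idempotent at stage granularity and degenerate-safe", {
  set.seed(9)
  n <- 30
  tbl <- tibble::tibble(
    participant = sprintf("P%02d", 1:n),
    pos_mod = rnorm(n), pos_strong = rnorm(n),
    neg_mod = rnorm(n), neg_strong = rnorm(n),
    no_feedback = rnorm(n))
  tbl$si_overall <- rowMeans(tbl[disagreement_conditions()])
  first <- qc_filter(tbl)
  survivors <- tbl[tbl$participant %in% first$retained, ]
  # original stage thresholds exclude nobody among their own survivors
  thr <- mean(tbl$si_overall) + c(-2, 2) * sd(tbl$si_overall)
  expect_true(all(survivors$si_overall >= thr[1] &
                    survivors$si_overall <= thr[2]))
  # identical scores: SD = 0 handled as no exclusion
  same <- tbl
  same$si_overall <- 1
  same$no_feedback <- 0.2
  rep <- qc_filter(same)
  expect_equal(rep$n_after_nofeedback_filter, n)
  expect_error(qc_filter(tbl[1:2, ]), class = "peersway_sample_error")
})

test_that("no-feedback bias test matches its closed form and sentinels", {
  x <- c(0.4, 0.1, 0.1, 0.0, 0.2, 0.1, -0.1, 0.0, 0.1)
  res <- nofeedback_bias_test(x)
  expect_equal(res$t, mean(x) / (sd(x) / 3))
  expect_equal(res$p, 2 * pt(abs(res$t), 8, lower.tail = FALSE))
  zero <- nofeedback_bias_test(rep(0, 5))
  expect_equal(zero$t, 0)
  expect_equal(zero$p, 1)
  const <- nofeedback_bias_test(rep(1, 4))
  expect_equal(const$t, Inf)
  expect_equal(const$p, 0)
})
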