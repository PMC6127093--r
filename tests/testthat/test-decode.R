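test_that("stratified folds partition trials and balance classes within one trial", {
  y <- rep(c(0, 1), c(50, 50))
  f <- stratified_folds(y, k = 10, seed = 1)
  expect_setequal(f, 1:10)
  for (i in 1:10) {
    expect_equal(sum(f == i & y == 0), 5)
    expect_equal(sum(f == i & y == 1), 5)
  }
  y2 <- rep(c(0, 1), c(60, 40))
  f2 <- stratified_folds(y2, k = 10, seed = 2)
  expect_true(all(table(f2, y2) == matrix(c(6, 4), 10, 2, byrow = TRUE)))
  expect_error(stratified_folds(rep(c(0, 1), c(5, 95)), k = 10),
               class = "peersway_validation_error")
})

test_that("auc_score matches hand counts, handles ties, and equals the brute-force oracle", {
  expect_equal(auc_score(c(.9, .4, .6, .1), c(1, 1, 0, 0)), 0.75)
  expect_equal(auc_score(c(.9, .8, .2, .1), c(1, 1, 0, 0)), 1)
  expect_equal(auc_score(rep(.5, 10), rep(c(0, 1), 5)), 0.5)
  expect_error(auc_score(c(.2, .8), c(1, 1)), class = "peersway_degenerate_error")
  set.seed(10)
  for (i in 1:50) {
    n <- sample(5:30, 1)
    y <- c(0, 1, rbinom(n - 2, 1, 0.5))
    p <- round(runif(n), sample(1:3, 1))   # coarse rounding forces ties
    expect_equal(auc_score(p, y), auc_bruteforce(p, y), tolerance = 1e-12)
  }
})

test_that("adjustment labelling follows the sign rule and drops unchanged ratings", {
  tr <- make_paired_trials(
    conditions = rep("neg_strong", 3),
    test = c(4, 4, 4), post = c(1, 3, 4), fictive = c(1, 7, 7))
  # (4 -> 1 toward peer 1); (4 -> 3 away from peer 7); (4 -> 4 unchanged)
  lab <- label_adjustment(tr)
  expect_equal(lab$adjustment, c("towards", "away", "none"))
  labs <- build_labels(lab, contrast_spec("adj", a = adjustment == "towards",
                                          b = adjustment == "away"))
  expect_equal(labs$trial, c(1L, 2L))
  expect_error(build_labels(lab, contrast_spec("bad", a = adjustment == "towards",
                                               b = test_rating == 4)),
               class = "peersway_validation_error")
})

test_that("decoding finds a planted window and stays at chance elsewhere", {
  set.seed(31)
  n <- 120
  y <- rep(0:1, each = n / 2)
  ep <- make_toy_epochs(n_trials = n, n_chan = 8, n_samples = 20, seed = 31)
  # separable component at samples 8..12 only
  ep$data[y == 1, 1:4, 8:12] <- ep$data[y == 1, 1:4, 8:12] + 1.5
  tc <- decode_timecourse(ep, y, k = 10, seed = 5)
  expect_gt(mean(tc$auc[8:12]), 0.85)
  expect_lt(abs(mean(tc$auc[c(1:5, 16:20)]) - 0.5), 0.08)
})

test_that("decoding is deterministic in the seed and scale invariant", {
  set.seed(32)
  y <- rep(0:1, each = 30)
  ep <- make_toy_epochs(n_trials = 60, n_chan = 6, n_samples = 8, seed = 32)
  ep$data[y == 1, 1:3, 4] <- ep$data[y == 1, 1:3, 4] + 1
  a <- decode_timecourse(ep, y, k = 10, seed = 9)
  b <- decode_timecourse(ep, y, k = 10, seed = 9)
  expect_identical(a$auc, b$auc)
  scaled <- ep
  scaled$data <- ep$data * 37.5
  c <- decode_timecourse(scaled, y, k = 10, seed = 9)
  expect_equal(c$auc, a$auc, tolerance = 1e-6)
})

test_that("random labels decode at chance on average", {
  set.seed(33)
  grand <- replicate(60, {
    y <- sample(rep(0:1, each = 15))
    ep <- make_toy_epochs(n_trials = 30, n_chan = 4, n_samples = 5,
                          seed = sample.int(1e6, 1))
    mean(decode_timecourse(ep, y, k = 5, seed = 1)$auc)
  })
  expect_lt(abs(mean(grand) - 0.5), 0.02)
})

test_that("temporal generalization shares its diagonal with the canonical decoder", {
  set.seed(34)
  y <- rep(0:1, each = 25)
  ep <- make_toy_epochs(n_trials = 50, n_chan = 6, n_samples = 12, seed = 34)
  # one sustained component: generalization should spread off-diagonal
  ep$data[y == 1, 1:3, 5:12] <- ep$data[y == 1, 1:3, 5:12] + 1.2
  tc <- decode_timecourse(ep, y, k = 5, seed = 3)
  tg <- temporal_generalization(ep, y, k = 5, seed = 3)
  expect_identical(diag(tg$auc), tc$auc)
  expect_gt(mean(tg$auc[5:12, 5:12]), 0.75)       # broad square
  expect_lt(abs(mean(tg$auc[1:4, 1:4]) - 0.5), 0.12)
})

test_that("two orthogonal sequential components give on-diagonal blocks only", {
  set.seed(35)
  y <- rep(0:1, each = 30)
  ep <- make_toy_epochs(n_trials = 60, n_chan = 8, n_samples = 16, seed = 35)
  ep$data[y == 1, 1:4, 3:6] <- ep$data[y == 1, 1:4, 3:6] + 1.5
  ep$data[y == 1, 5:8, 10:14] <- ep$data[y == 1, 5:8, 10:14] - 1.5
  tg <- temporal_generalization(ep, y, k = 5, seed = 4)
  within1 <- mean(tg$auc[3:6, 3:6])
  within2 <- mean(tg$auc[10:14, 10:14])
  cross <- mean(tg$auc[3:6, 10:14])
  expect_gt(within1, 0.8)
  expect_gt(within2, 0.8)
  # the two patterns are anti-correlated in feature space: training on one
  # and testing on the other stays at or below chance
  expect_lt(cross, 0.55)
})

test_that("median split sends strict upper half high and median ties low", {
  expect_equal(median_split(1:17), rep(c("low", "high"), c(9, 8)))
  expect_equal(median_split(c(1, 2, 3, 4)), c("low", "low", "high", "high"))
  expect_warning(out <- median_split(rep(2, 5)))
  expect_true(all(out == "low"))
})

test_that("mean stage AUC pools the two processing windows", {
  times <- seq(-200, 990, by = 10)
  auc <- rep(0.5, length(times))
  auc[times >= 200 & times <= 900] <- 0.7
  expect_equal(mean_stage_auc(auc, times), 0.7)
  expect_equal(mean_stage_auc(auc, times, stage1 = c(-200, -100),
                              stage2 = c(-100, 0)), 0.5)
})
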