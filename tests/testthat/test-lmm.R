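sim_long <- function(n_subj, b_cov = 0, sd_b = 0.3, sd_e = 0.4, seed = 1) {
  set.seed(seed)
  cov <- rnorm(n_subj)
  u <- rnorm(n_subj, sd = sd_b)
  tidyr::expand_grid(subject = seq_len(n_subj),
                     valence = c(-0.5, 0.5), strength = c(-0.5, 0.5)) |>
    dplyr::mutate(
      participant = sprintf("S%02d", subject),
      z_cov = cov[subject],
      score = 0.5 + 0.2 * strength + b_cov * z_cov + u[subject] +
        rnorm(dplyr::n(), sd = sd_e))
}

test_that("with no between-subject variance the fit collapses to OLS", {
  set.seed(51)
  d <- sim_long(12, sd_b = 0, sd_e = 0.3, seed = 51)
  fit <- fit_random_intercept(d, score ~ valence * strength)
  ols <- lm(score ~ valence * strength, data = d)
  expect_equal(unname(fit$coefficients$estimate), unname(coef(ols)),
               tolerance = 1e-6)
})

test_that("balanced two-condition data recover the mean paired difference", {
  set.seed(52)
  n <- 10
  base <- rnorm(n)
  d <- tibble::tibble(
    participant = rep(sprintf("S%02d", 1:n), each = 2),
    cond = rep(c(-0.5, 0.5), n),
    score = rep(base, each = 2) + rep(c(0, 0.7), n) + rnorm(2 * n, sd = 0.1))
  fit <- fit_random_intercept(d, score ~ cond)
  paired_diff <- mean(d$score[d$cond == 0.5] - d$score[d$cond == -0.5])
  expect_equal(fit$coefficients$estimate[2], paired_diff, tolerance = 1e-8)
})

test_that("the profiled likelihood matches a brute-force grid and lme4 ML", {
  d <- sim_long(10, b_cov = 0.1, seed = 53)
  fit <- fit_random_intercept(d, score ~ valence * strength + z_cov)
  # grid oracle over the variance ratio
  grid <- seq(0, 20, length.out = 4000)
  ll <- vapply(grid, function(th) {
    peersway:::ri_profile(th, d$score,
                          model.matrix(~ valence * strength + z_cov, d),
                          split(seq_len(nrow(d)), d$participant),
                          nrow(d))$logLik
  }, numeric(1))
  expect_equal(fit$logLik, max(ll), tolerance = 1e-4)
  lf <- lme4::lmer(score ~ valence * strength + z_cov + (1 | participant),
                   data = d, REML = FALSE)
  expect_equal(fit$logLik, as.numeric(stats::logLik(lf)), tolerance = 1e-5)
  expect_equal(unname(fit$coefficients$estimate), unname(lme4::fixef(lf)),
               tolerance = 1e-4)
})

test_that("degrees of freedom follow the inner-outer convention", {
  d <- sim_long(20, b_cov = 0.2, seed = 54)
  fit <- fit_random_intercept(d, score ~ valence * strength + z_cov)
  co <- tidy(fit)
  n <- nrow(d); g <- 20; p <- 5
  within_df <- n - p - g + 1
  expect_equal(co$df[co$term == "valence"], within_df)
  expect_equal(co$df[co$term == "valence:strength"], within_df)
  expect_equal(co$df[co$term == "z_cov"], g - 2)
})

test_that("fixed effects are recovered within 2 SE in most replicates", {
  hits <- vapply(1:60, function(i) {
    d <- sim_long(15, b_cov = 0.15, seed = 100 + i)
    co <- tidy(fit_random_intercept(d, score ~ valence * strength + z_cov))
    row <- co[co$term == "z_cov", ]
    abs(row$estimate - 0.15) <= 2 * row$se
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})

test_that("Bayes-factor arithmetic and ordering behave as documented", {
  d <- sim_long(15, b_cov = 0, seed = 55)
  base <- fit_random_intercept(d, score ~ valence * strength)
  expect_equal(bayes_factor(base, base), 1)
  alt <- fit_random_intercept(d, score ~ valence * strength + z_cov)
  expect_equal(bayes_factor(alt, base),
               exp((base$BIC - alt$BIC) / 2))
  d2 <- sim_long(8, seed = 56)
  other <- fit_random_intercept(d2, score ~ valence)
  expect_error(bayes_factor(other, base), class = "peersway_validation_error")
})

test_that("a pure-noise covariate loses to the baseline on median evidence", {
  bfs <- vapply(1:40, function(i) {
    d <- sim_long(12, b_cov = 0, seed = 200 + i)
    ms <- model_set(d, "z_cov")
    ms$comparison$bf10_vs_baseline[ms$comparison$model == "type1"]
  }, numeric(1))
  expect_lt(median(bfs), 1)
})

test_that("a planted main effect favours type-1; an interaction favours type-2", {
  wins_t1 <- vapply(1:25, function(i) {
    d <- sim_long(15, b_cov = 0.25, seed = 300 + i)
    ms <- model_set(d, "z_cov")
    bf <- ms$comparison$bf10_vs_baseline
    bf[ms$comparison$model == "type1"] >= bf[ms$comparison$model == "type2"]
  }, logical(1))
  expect_gt(mean(wins_t1), 0.6)
  wins_t2 <- vapply(1:25, function(i) {
    d <- sim_long(20, b_cov = 0, sd_e = 0.25, seed = 400 + i) |>
      dplyr::mutate(score = score + 1.5 * z_cov * valence * strength)
    ms <- model_set(d, "z_cov")
    bf <- ms$comparison$bf10_vs_baseline
    bf[ms$comparison$model == "type2"] > bf[ms$comparison$model == "type1"]
  }, logical(1))
  expect_gt(mean(wins_t2), 0.6)
})

test_that("the combination index is a centred sum of z-scores, affine invariant", {
  set.seed(57)
  auc <- runif(9, 0.5, 0.7)
  pvd <- rnorm(9)
  idx <- combination_index(auc, pvd)
  expect_lt(abs(mean(idx)), 1e-10)
  hand <- (auc - mean(auc)) / sd(auc) + (pvd - mean(pvd)) / sd(pvd)
  expect_equal(idx, hand)
  expect_equal(combination_index(10 * auc - 3, 0.2 * pvd + 7), idx)
  expect_error(combination_index(rep(0.6, 9), pvd),
               class = "peersway_degenerate_error")
})
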