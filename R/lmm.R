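#' Reshape a score table to the long modelling format
#'
#' Turns the wide per-participant table of [influence_scores()] into the
#' long format expected by the mixed models: one row per participant and
#' disagreement condition, with deviation-coded `valence` (negative -0.5,
#' positive +0.5) and `strength` (moderate -0.5, strong +0.5), joined with
#' any per-participant covariates.
#'
#' @param scores Wide score table (`participant`, `pos_mod`, `pos_strong`,
#'   `neg_mod`, `neg_strong`, ...).
#' @param covariates Optional tibble keyed by `participant` with
#'   between-subject covariates (z-scored questionnaire scores, age, ...).
#' @return A long tibble with `participant`, `valence`, `strength`, `score`
#'   and the covariate columns.
#' @export
long_score_table <- function(scores, covariates = NULL) {
  long <- scores |>
    select("participant", all_of(disagreement_conditions())) |>
    pivot_longer(all_of(disagreement_conditions()),
                 names_to = "condition", values_to = "score") |>
    mutate(valence = ifelse(startsWith(.data$condition, "pos"), 0.5, -0.5),
           strength = ifelse(endsWith(.data$condition, "strong"), 0.5, -0.5))
  if (!is.null(covariates)) {
    long <- left_join(long, covariates, by = "participant")
  }
  long
}

#' Random-intercept linear mixed model by maximum likelihood
#'
#' Fits `y = X beta + b_participant + e` with a Gaussian random intercept
#' per participant, by profiling the likelihood over the variance ratio
#' `theta = var(b) / var(e)`: for each theta the fixed effects are the GLS
#' solution and the residual variance its closed-form ML estimate, and the
#' profiled log-likelihood is maximized over theta with one-dimensional
#' search. Fixed-effect t-tests use the inner-outer degrees-of-freedom
#' convention: terms varying within participants are tested against
#' `n_obs - n_fixed - n_groups + 1` df, purely between-participant terms
#' against `n_groups - n_between - 1` df.
#'
#' @param data Long tibble (e.g. [long_score_table()]).
#' @param fixed Model formula for the fixed effects,
#'   e.g. `score ~ valence * strength`.
#' @param group Name of the grouping column (default `"participant"`).
#' @return An `ri_fit` object: `coefficients` tibble (term, estimate, se,
#'   t, df, p), `theta`, `sigma2` (residual), `sigma2_b` (intercept),
#'   `logLik`, `n_params`, `BIC`, `n_obs`, `n_groups`, plus the model frame
#'   pieces needed for comparison.
#' @export
fit_random_intercept <- function(data, fixed, group = "participant") {
  mf <- stats::model.frame(fixed, data = data)
  y <- stats::model.response(mf)
  X <- model.matrix(fixed, data = data)
  if (qr(X)$rank < ncol(X)) {
    abort("fixed-effect design is rank deficient",
          class = "peersway_rank_error")
  }
  g <- as.factor(data[[group]])
  n <- length(y)
  n_g <- nlevels(g)
  if (n_g < 2L || any(table(g) < 1L)) {
    abort("need >= 2 participants", class = "peersway_sample_error")
  }
  idx <- split(seq_len(n), g)
  prof <- function(theta) ri_profile(theta, y, X, idx, n)
  # profiled deviance is smooth in log(1 + theta); search a wide bracket
  opt <- optimize(\(u) -prof(exp(u) - 1)$logLik, interval = c(0, log(1e4)),
                  tol = 1e-10)
  theta <- exp(opt$minimum) - 1
  at0 <- prof(0)
  best <- prof(theta)
  if (at0$logLik >= best$logLik) {     # boundary: no between-subject variance
    theta <- 0
    best <- at0
  }
  p <- ncol(X)
  within <- vapply(seq_len(p), function(j) {
    any(vapply(idx, \(i) length(unique(X[i, j])) > 1L, logical(1)))
  }, logical(1))
  n_between <- sum(!within) - 1L       # intercept excluded
  df <- ifelse(within, n - p - n_g + 1L, n_g - n_between - 1L)
  se <- unname(sqrt(diag(best$cov)))
  beta <- unname(best$beta)
  t_stat <- beta / se
  coefs <- tibble(term = colnames(X), estimate = beta, se = se,
                  t = t_stat, df = df,
                  p = 2 * pt(abs(t_stat), df = df, lower.tail = FALSE))
  n_params <- p + 2L                   # beta, sigma2, sigma2_b
  structure(list(coefficients = coefs, theta = theta,
                 sigma2 = best$sigma2, sigma2_b = theta * best$sigma2,
                 logLik = best$logLik, n_params = n_params,
                 BIC = -2 * best$logLik + n_params * log(n),
                 n_obs = n, n_groups = n_g, formula = fixed, response = y),
            class = "ri_fit")
}

# GLS at a fixed variance ratio; block structure makes V^{-1} cheap:
# within a group of size m, V^{-1} = (I - theta/(1 + m*theta) * J) / sigma2.
ri_profile <- function(theta, y, X, idx, n) {
  p <- ncol(X)
  XtWX <- matrix(0, p, p)
  XtWy <- numeric(p)
  ytWy <- 0
  logdet <- 0
  for (i in idx) {
    m <- length(i)
    c_i <- theta / (1 + m * theta)
    Xi <- X[i, , drop = FALSE]
    yi <- y[i]
    sx <- colSums(Xi)
    sy <- sum(yi)
    XtWX <- XtWX + crossprod(Xi) - c_i * tcrossprod(sx)
    XtWy <- XtWy + crossprod(Xi, yi) - c_i * sx * sy
    ytWy <- ytWy + sum(yi^2) - c_i * sy^2
    logdet <- logdet + log(1 + m * theta)
  }
  beta <- solve(XtWX, XtWy)
  rss <- ytWy - 2 * sum(beta * XtWy) + drop(t(beta) %*% XtWX %*% beta)
  sigma2 <- max(rss / n, 1e-12)
  logLik <- -0.5 * (n * log(2 * pi * sigma2) + logdet + n)
  list(beta = drop(beta), sigma2 = sigma2, logLik = logLik,
       cov = solve(XtWX) * sigma2)
}

#' @export
print.ri_fit <- function(x, ...) {
  cat(sprintf("Random-intercept LMM (ML): logLik %.3f, BIC %.2f, sd(intercept) %.4f, sd(resid) %.4f\n",
              x$logLik, x$BIC, sqrt(x$sigma2_b), sqrt(x$sigma2)))
  print(x$coefficients)
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a random-intercept fit
#' @param x An `ri_fit`.
#' @param ... Unused.
#' @return The coefficient tibble (term, estimate, se, t, df, p).
#' @export
tidy.ri_fit <- function(x, ...) x$coefficients

#' One-row model summary of a random-intercept fit
#' @param x An `ri_fit`.
#' @param ... Unused.
#' @return Tibble with `logLik`, `BIC`, `sigma2`, `sigma2_b`, `theta`,
#'   `n_obs`, `n_groups`.
#' @export
glance.ri_fit <- function(x, ...) {
  tibble(logLik = x$logLik, BIC = x$BIC, sigma2 = x$sigma2,
         sigma2_b = x$sigma2_b, theta = x$theta, n_obs = x$n_obs,
         n_groups = x$n_groups)
}

#' BIC-approximated Bayes factor between two fits
#'
#' `BF10 = exp((BIC_base - BIC_alt) / 2)`: the Schwarz approximation to the
#' Bayes factor in favour of the alternative model. Values above 1 favour
#' the alternative. This is an approximation to default-prior Bayes
#' factors; model orderings, not magnitudes, are its reliable output.
#'
#' @param model_alt,model_base `ri_fit` objects fitted to the same response.
#' @return BF10 as a scalar.
#' @export
bayes_factor <- function(model_alt, model_base) {
  if (model_alt$n_obs != model_base$n_obs ||
      !isTRUE(all.equal(model_alt$response, model_base$response))) {
    abort("models were not fitted to the same response",
          class = "peersway_validation_error")
  }
  exp((model_base$BIC - model_alt$BIC) / 2)
}

#' Baseline / type-1 / type-2 model set for one covariate
#'
#' Fits the baseline model `score ~ valence * strength`, the type-1 model
#' adding the between-subject covariate as a main effect, and the type-2
#' model letting the covariate interact with valence and strength, and
#' compares each enriched model to the baseline with [bayes_factor()].
#'
#' @param table Long score table with the covariate column present.
#' @param covariate Covariate column name (string), e.g. `"z_pi"`.
#' @return A list with `baseline`, `type1`, `type2` fits and the tibble
#'   `comparison` (`model`, `BIC`, `bf10_vs_baseline`).
#' @export
model_set <- function(table, covariate) {
  base_f <- score ~ valence * strength
  f1 <- stats::as.formula(paste("score ~ valence * strength +", covariate))
  f2 <- stats::as.formula(paste("score ~ valence * strength *", covariate))
  fits <- list(baseline = fit_random_intercept(table, base_f),
               type1 = fit_random_intercept(table, f1),
               type2 = fit_random_intercept(table, f2))
  comparison <- tibble(
    model = names(fits),
    BIC = map_dbl(fits, "BIC"),
    bf10_vs_baseline = map_dbl(fits, \(f) bayes_factor(f, fits$baseline)))
  c(fits, list(comparison = comparison))
}

#' Combination index of decoding sensitivity and perceived vulnerability
#'
#' Per-subject sum of the z-scored mean stage AUC (decoding sensitivity
#' averaged over the early and late processing-stage windows) and the
#' z-scored questionnaire subscale score.
#'
#' @param mean_stage_auc Per-subject mean stage AUC (see
#'   [mean_stage_auc()]).
#' @param pvd_score Per-subject subscale score (raw or z).
#' @return Per-subject index (sample mean zero by construction).
#' @export
combination_index <- function(mean_stage_auc, pvd_score) {
  if (length(mean_stage_auc) < 3L) {
    abort("need >= 3 subjects", class = "peersway_sample_error")
  }
  z_standardize(mean_stage_auc, "mean stage AUC") +
    z_standardize(pvd_score, "questionnaire scores")
}
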