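#' Per-timepoint group tests of decoding sensitivity against chance
#'
#' One-sample t-test of the subjects' AUC at each timepoint against the
#' chance level, upper tail (is decoding better than chance?).
#'
#' @param auc_matrix Subjects x timepoints AUC matrix.
#' @param chance Chance level (default 0.5).
#' @return Tibble with `timepoint`, `mean_auc`, `t`, `p`. Zero-variance
#'   timepoints get the sentinel `p = 0` when the mean exceeds chance and
#'   `p = 1` otherwise.
#' @export
timepoint_tests <- function(auc_matrix, chance = 0.5) {
  auc_matrix <- as.matrix(auc_matrix)
  n <- nrow(auc_matrix)
  if (n < 3L) abort("need >= 3 subjects", class = "peersway_sample_error")
  m <- colMeans(auc_matrix)
  s <- apply(auc_matrix, 2, sd)
  t_stat <- ifelse(s > 0, (m - chance) / (s / sqrt(n)),
                   ifelse(m > chance, Inf, ifelse(m < chance, -Inf, 0)))
  p <- ifelse(is.finite(t_stat),
              pt(t_stat, df = n - 1, lower.tail = FALSE),
              ifelse(t_stat > 0, 0, 1))
  tibble(timepoint = seq_along(m), mean_auc = m, t = t_stat, p = p)
}

#' Find temporal clusters of sub-threshold timepoints
#'
#' Maximal runs of at least `min_len` adjacent samples with `p` below the
#' cluster-forming alpha ("dyads of adjacent timepoints"); each cluster's
#' mass is the sum of the statistic series over the run.
#'
#' @param p_values Per-timepoint p-values.
#' @param stat_series Per-timepoint statistic summed into the cluster mass
#'   (e.g. the group-mean AUC).
#' @param forming_alpha Cluster-forming threshold (default 0.05).
#' @param min_len Minimum run length (default 2).
#' @return Tibble with `start`, `end` (sample indices, inclusive) and
#'   `mass`; zero rows when no run qualifies.
#' @export
find_clusters <- function(p_values, stat_series, forming_alpha = 0.05,
                          min_len = 2L) {
  runs_to_clusters(p_values < forming_alpha, stat_series, min_len)
}

runs_to_clusters <- function(below, stat_series, min_len = 2L) {
  r <- rle(as.logical(below))
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values & r$lengths >= min_len
  if (!any(keep)) {
    return(tibble(start = integer(), end = integer(), mass = numeric()))
  }
  tibble(start = starts[keep], end = ends[keep]) |>
    mutate(mass = map2(.data$start, .data$end,
                       \(s, e) sum(stat_series[s:e])) |> unlist())
}

# shared permutation engine: per-subject sign flips of (auc - chance),
# fully vectorized over permutations
flip_null_max_masses <- function(auc_matrix, n_perm, forming_alpha, chance,
                                 centered, min_len) {
  n <- nrow(auc_matrix)
  C <- as.matrix(auc_matrix) - chance
  m2 <- colMeans(C^2)
  S <- matrix(sample(c(-1, 1), n * n_perm, replace = TRUE), nrow = n)
  M <- crossprod(S, C) / n                       # n_perm x T permuted means
  V <- pmax(sweep(-M^2, 2, m2, `+`), 0) * n / (n - 1)
  Tm <- ifelse(V > 0, M / sqrt(V / n),
               ifelse(M > 0, Inf, ifelse(M < 0, -Inf, 0)))
  t_crit <- qt(1 - forming_alpha, df = n - 1)
  below <- Tm > t_crit | (!is.finite(Tm) & Tm > 0)
  vapply(seq_len(n_perm), function(i) {
    stat <- if (centered) M[i, ] else chance + M[i, ]
    cl <- runs_to_clusters(below[i, ], stat, min_len)
    if (nrow(cl)) max(cl$mass) else 0
  }, numeric(1))
}

#' Cluster-mass permutation test for group decoding time-courses
#'
#' Forms clusters from the observed per-timepoint one-tailed t-tests
#' ([timepoint_tests()], [find_clusters()]), then builds the null
#' distribution of the maximum cluster mass by flipping the sign of
#' `(AUC - chance)` independently per subject and re-running the test and
#' clustering on each of `n_perm` permutations. Each observed cluster's
#' `p_star` is the proportion of permutations whose maximum mass reaches its
#' mass (floored at `1/n_perm` when no permutation does).
#'
#' @param auc_matrix Subjects x timepoints AUC matrix.
#' @param n_perm Number of Monte-Carlo permutations (default 1000).
#' @param seed Integer RNG seed.
#' @param forming_alpha Cluster-forming threshold (default 0.05).
#' @param alpha Cluster significance threshold on `p_star` (default 0.01).
#' @param chance Chance AUC (default 0.5).
#' @param centered Sum `(AUC - chance)` instead of raw AUC into the mass
#'   (default `FALSE`: the raw sum, which also grows with cluster length).
#' @param times Optional time axis (ms) to annotate clusters.
#' @return A `cluster_result` tibble: `start`, `end` (indices),
#'   `start_ms`/`end_ms` when `times` given, `mass`, `mean_stat`, `p_star`,
#'   `significant`; the null max-mass distribution in attribute `null_max`.
#' @export
permutation_null_decoding <- function(auc_matrix, n_perm = 1000, seed = NULL,
                                      forming_alpha = 0.05, alpha = 0.01,
                                      chance = 0.5, centered = FALSE,
                                      times = NULL) {
  if (n_perm < 100) warn("fewer than 100 permutations: p* resolution is coarse")
  auc_matrix <- as.matrix(auc_matrix)
  tests <- timepoint_tests(auc_matrix, chance)
  stat <- if (centered) tests$mean_auc - chance else tests$mean_auc
  obs <- find_clusters(tests$p, stat, forming_alpha)
  null_max <- with_rng(seed, {
    flip_null_max_masses(auc_matrix, n_perm, forming_alpha, chance,
                         centered, min_len = 2L)
  })
  finish_clusters(obs, null_max, n_perm, alpha, times)
}

finish_clusters <- function(obs, null_max, n_perm, alpha, times) {
  if (nrow(obs)) {
    obs$mean_stat <- obs$mass / (obs$end - obs$start + 1)
    obs$p_star <- map_dbl(obs$mass, \(m) max(mean(null_max >= m), 1 / n_perm))
    obs$significant <- obs$p_star < alpha
    if (!is.null(times)) {
      obs <- mutate(obs, start_ms = times[.data$start],
                    end_ms = times[.data$end], .after = "end")
    }
  } else {
    obs$mean_stat <- numeric()
    obs$p_star <- numeric()
    obs$significant <- logical()
  }
  structure(obs, null_max = null_max,
            class = c("cluster_result", class(obs)))
}

#' Per-timepoint correlation between decoding sensitivity and a score
#'
#' Pearson correlation, across subjects, between each timepoint's AUC and a
#' per-subject behavioural or questionnaire score.
#'
#' @param auc_matrix Subjects x timepoints AUC matrix.
#' @param scores Per-subject score vector.
#' @return Numeric vector of r per timepoint.
#' @export
correlation_timecourse <- function(auc_matrix, scores) {
  auc_matrix <- as.matrix(auc_matrix)
  if (nrow(auc_matrix) < 4L) {
    abort("need >= 4 subjects", class = "peersway_sample_error")
  }
  if (sd(scores) == 0) {
    abort("scores are constant: correlation undefined",
          class = "peersway_degenerate_error")
  }
  as.numeric(cor(scores, auc_matrix))
}

#' Correlation-cluster permutation test
#'
#' Clusters are runs of at least two adjacent timepoints where the
#' AUC-score Pearson correlation is at or above `r_threshold` (positive
#' tail only); the mass is the summed r. The null permutes the score vector
#' across subjects `n_perm` times, recomputing the correlation series and
#' the maximum cluster mass each time.
#'
#' @inheritParams correlation_timecourse
#' @param r_threshold Cluster-forming correlation threshold (default 0.40).
#' @param n_perm Permutations (default 10000).
#' @param seed Integer RNG seed.
#' @param alpha Cluster significance threshold on `p_star` (default 0.05).
#' @param times Optional time axis (ms).
#' @return A `cluster_result` tibble as in [permutation_null_decoding()],
#'   with `mean_stat` the cluster's mean r.
#' @export
permutation_null_correlation <- function(auc_matrix, scores,
                                         r_threshold = 0.40, n_perm = 10000,
                                         seed = NULL, alpha = 0.05,
                                         times = NULL) {
  auc_matrix <- as.matrix(auc_matrix)
  r_obs <- correlation_timecourse(auc_matrix, scores)
  obs <- runs_to_clusters(r_obs >= r_threshold, r_obs, min_len = 2L)
  n <- nrow(auc_matrix)
  Z <- scale(auc_matrix)               # per-timepoint standardization
  Z[is.na(Z)] <- 0                     # constant columns: r treated as 0
  zs <- as.numeric(scale(scores))
  null_max <- with_rng(seed, {
    P <- vapply(seq_len(n_perm), \(i) zs[sample.int(n)], numeric(n))
    R <- crossprod(P, Z) / (n - 1)     # n_perm x T permuted r series
    vapply(seq_len(n_perm), function(i) {
      cl <- runs_to_clusters(R[i, ] >= r_threshold, R[i, ], min_len = 2L)
      if (nrow(cl)) max(cl$mass) else 0
    }, numeric(1))
  })
  finish_clusters(obs, null_max, n_perm, alpha, times)
}
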