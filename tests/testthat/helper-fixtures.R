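# Shared in-code fixtures for the test suite.

# Minimal paired trial table (wide form): one row per face with both ratings.
make_paired_trials <- function(participant = "P1", conditions, test, post,
                               fictive = NULL) {
  n <- length(conditions)
  tibble::tibble(
    participant = participant,
    face_id = sprintf("f%02d", seq_len(n)),
    condition = conditions,
    test_rating = as.integer(test),
    fictive_rating = if (is.null(fictive)) NA_integer_ else as.integer(fictive),
    post_rating = as.integer(post))
}

# Tiny epoch set: white-noise data with optional planted class signal.
make_toy_epochs <- function(n_trials = 60, n_chan = 8, n_samples = 20,
                            seed = 1, labels = NULL) {
  set.seed(seed)
  mont <- standard_montage_64()[seq_len(n_chan), ]
  d <- array(rnorm(n_trials * n_chan * n_samples), c(n_trials, n_chan, n_samples))
  times <- seq(-200, by = 10, length.out = n_samples)
  epoch_set(d, times, mont, labels = labels, participant = "T1")
}

# Exhaustive pairwise-concordance AUC: the brute-force oracle.
auc_bruteforce <- function(p, y) {
  pos <- p[y == 1]
  neg <- p[y == 0]
  total <- 0
  for (a in pos) for (b in neg) {
    total <- total + if (a > b) 1 else if (a == b) 0.5 else 0
  }
  total / (length(pos) * length(neg))
}

# Multivariate item generator: n x k responses loading on one factor.
make_item_matrix <- function(n, k, loading, seed = 1, L = 7) {
  set.seed(seed)
  v <- rnorm(n)
  sapply(seq_len(k), function(j) {
    x <- loading * v + rnorm(n)
    pmin(L, pmax(1, round((L + 1) / 2 + x)))
  })
}
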