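#' Item map of the Perceived Vulnerability to Disease scale
#'
#' Fifteen Likert items split over two subscales: Perceived Infectability
#' (PI: beliefs about one's susceptibility to infection; items 2, 5, 6, 8,
#' 10, 12, 14) and Germ Aversion (GA: discomfort in transmission-risk
#' situations; items 1, 3, 4, 7, 9, 11, 13, 15). Items 3, 5, 11, 12, 13 and
#' 14 are reverse-scored. The four-item "maximized" GA set retained after
#' reliability pruning in low-consistency samples is items 1, 3, 7 and 13.
#'
#' @return A tibble with columns `item`, `subscale` (`"PI"`/`"GA"`),
#'   `reverse` (logical).
#' @export
pvd_item_map <- function() {
  pi_items <- c(2L, 5L, 6L, 8L, 10L, 12L, 14L)
  rev_items <- c(3L, 5L, 11L, 12L, 13L, 14L)
  tibble(item = 1:15,
         subscale = ifelse(1:15 %in% pi_items, "PI", "GA"),
         reverse = 1:15 %in% rev_items)
}

#' Reverse-score a Likert response
#'
#' Maps a response `r` on a 1..L scale to `(L + 1) - r`; applying it twice
#' returns the original response.
#'
#' @param response Integer response(s) in `[1, L]`.
#' @param L Number of Likert points (default 7).
#' @return The reversed response(s).
#' @export
reverse_score <- function(response, L = 7L) {
  if (any(response < 1 | response > L, na.rm = TRUE)) {
    abort(sprintf("responses must lie in [1, %d]", L),
          class = "peersway_validation_error")
  }
  (as.integer(L) + 1L) - response
}

# responses: tibble participant + item_1..item_15 -> matrix after validation
pvd_matrix <- function(responses, L = 7L) {
  item_cols <- sprintf("item_%d", 1:15)
  if (!all(item_cols %in% names(responses))) {
    abort("responses need columns item_1..item_15",
          class = "peersway_validation_error")
  }
  m <- as.matrix(responses[item_cols])
  if (any(m < 1 | m > L, na.rm = TRUE)) {
    abort(sprintf("item responses must lie in [1, %d]", L),
          class = "peersway_validation_error")
  }
  rownames(m) <- responses$participant
  m
}

#' Score the PVD questionnaire
#'
#' Reverse-scores the marked items, averages each subscale, and z-transforms
#' the subscale scores over the included participants. Optionally also
#' returns the maximized Germ Aversion score (mean of items 1, 3, 7, 13),
#' the pruned set used when the full GA subscale shows unacceptable internal
#' consistency.
#'
#' @param responses Tibble with `participant` and `item_1`..`item_15`.
#' @param L Likert points per item (default 7).
#' @param maximize_ga If `TRUE`, add `germ_aversion_maximized` and its z.
#' @return A tibble with `participant`, `perceived_infectability`,
#'   `germ_aversion`, `z_pi`, `z_ga` (and the maximized GA columns when
#'   requested).
#' @export
score_pvd <- function(responses, L = 7L, maximize_ga = FALSE) {
  m <- pvd_matrix(responses, L)
  if (nrow(m) < 2L) {
    abort("need >= 2 participants for z-transformed scores",
          class = "peersway_sample_error")
  }
  map_tbl <- pvd_item_map()
  keyed <- m
  keyed[, map_tbl$reverse] <- reverse_score(m[, map_tbl$reverse], L)
  pi_score <- unname(rowMeans(keyed[, map_tbl$subscale == "PI", drop = FALSE]))
  ga_score <- unname(rowMeans(keyed[, map_tbl$subscale == "GA", drop = FALSE]))
  out <- tibble(
    participant = responses$participant,
    perceived_infectability = pi_score,
    germ_aversion = ga_score,
    z_pi = z_standardize(pi_score, "Perceived Infectability scores"),
    z_ga = z_standardize(ga_score, "Germ Aversion scores"))
  if (maximize_ga) {
    ga_max <- unname(rowMeans(keyed[, c(1L, 3L, 7L, 13L), drop = FALSE]))
    out$germ_aversion_maximized <- ga_max
    out$z_ga_max <- z_standardize(ga_max, "maximized Germ Aversion scores")
  }
  out
}

#' Cronbach's alpha
#'
#' Internal-consistency coefficient
#' `alpha = k/(k-1) * (1 - sum(item variances) / var(item sums))`
#' over a participants-by-items matrix. Reverse-keying must be applied
#' before calling.
#'
#' @param item_matrix Numeric matrix, participants in rows, items in columns.
#' @return Alpha as a scalar.
#' @export
cronbach_alpha <- function(item_matrix) {
  item_matrix <- as.matrix(item_matrix)
  k <- ncol(item_matrix)
  if (k < 2L || nrow(item_matrix) < 2L) {
    abort("need >= 2 items and >= 2 participants",
          class = "peersway_validation_error")
  }
  total_var <- var(rowSums(item_matrix))
  if (total_var == 0) {
    abort("total score has zero variance: alpha undefined",
          class = "peersway_degenerate_error")
  }
  (k / (k - 1)) * (1 - sum(apply(item_matrix, 2, var)) / total_var)
}

#' Greedy alpha-maximizing item pruning
#'
#' Sequentially removes the single item whose removal most increases
#' Cronbach's alpha, stopping when alpha reaches `target_alpha`, when no
#' removal increases alpha, or when only two items remain. Ties are broken
#' toward the lowest item index.
#'
#' @param item_matrix Participants-by-items matrix (keyed); column names
#'   identify items.
#' @param target_alpha Stopping threshold (default 0.7).
#' @return A list with `retained` (column names kept), `removed` (in removal
#'   order), `alpha` (final), and `trajectory` (tibble of step, removed item,
#'   alpha after removal; step 0 is the intact scale).
#' @export
maximize_alpha <- function(item_matrix, target_alpha = 0.7) {
  item_matrix <- as.matrix(item_matrix)
  if (is.null(colnames(item_matrix))) {
    colnames(item_matrix) <- sprintf("item_%d", seq_len(ncol(item_matrix)))
  }
  if (ncol(item_matrix) < 3L) {
    abort("need >= 3 items to prune", class = "peersway_validation_error")
  }
  current <- item_matrix
  alpha <- cronbach_alpha(current)
  removed <- character(0)
  traj <- tibble(step = 0L, removed = NA_character_, alpha = alpha)
  while (alpha < target_alpha && ncol(current) > 2L) {
    drop_alphas <- map_dbl(seq_len(ncol(current)), function(j) {
      cronbach_alpha(current[, -j, drop = FALSE])
    })
    best <- which.max(drop_alphas)   # which.max takes the first (lowest index) tie
    if (drop_alphas[best] <= alpha) break
    removed <- c(removed, colnames(current)[best])
    current <- current[, -best, drop = FALSE]
    alpha <- drop_alphas[best]
    traj <- bind_rows(traj, tibble(step = length(removed),
                                   removed = removed[length(removed)],
                                   alpha = alpha))
  }
  list(retained = colnames(current), removed = removed,
       alpha = alpha, trajectory = traj)
}
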