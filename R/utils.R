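#' @importFrom rlang abort warn inform .data
#' @importFrom tibble tibble as_tibble
#' @import dplyr
#' @importFrom tidyr pivot_longer pivot_wider
#' @importFrom purrr map map_dbl map2 imap list_rbind
#' @importFrom stats var sd cor qt pt rnorm runif median plogis optimize
#'   model.matrix rbinom setNames aggregate complete.cases
#' @importFrom utils head
NULL

# Evaluate `code` under a temporary RNG state seeded with `seed`; the caller's
# RNG stream is untouched. If seed is NULL the current stream is used.
with_rng <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) runif(1)
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(as.integer(seed))
  force(code)
}

# z-transform with an informative error on degenerate input
z_standardize <- function(x, what = "input") {
  s <- sd(x)
  if (!is.finite(s) || s == 0) {
    abort(sprintf("cannot z-transform %s: zero variance", what),
          class = "peersway_degenerate_error")
  }
  (x - mean(x)) / s
}

`%||%` <- function(a, b) if (is.null(a)) b else a
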