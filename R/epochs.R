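#' Idealized 64-channel EEG montage
#'
#' Standard 10-10 electrode labels of a 64-channel actiCAP-style layout,
#' with positions generated on an idealized unit sphere: each electrode is
#' placed from its row (anterior-posterior ring angle) and its lateral
#' fraction within the row, the classic flattened-cap parametrization.
#' Positions are meant for neighbour lookup and region grouping, not for
#' source modelling.
#'
#' @return A tibble with columns `channel`, `x` (right), `y` (front),
#'   `z` (up) on the unit sphere.
#' @export
standard_montage_64 <- function() {
  # row label -> ring azimuth (deg from front midline) of its 7/8 member
  ring_az <- c(Fp = 18, AF = 36, F = 54, FT = 72, FC = 72, T = 90, C = 90,
               TP = 108, CP = 108, P = 126, PO = 144, O = 162)
  spec <- list(
    # label, row, signed lateral fraction (0 midline, 1 on the ring, >1 below)
    c("Fp1", "Fp", -1), c("Fp2", "Fp", 1),
    c("AF7", "AF", -1), c("AF3", "AF", -0.4), c("AFz", "AF", 0),
    c("AF4", "AF", 0.4), c("AF8", "AF", 1),
    c("F7", "F", -1), c("F5", "F", -0.75), c("F3", "F", -0.5),
    c("F1", "F", -0.25), c("Fz", "F", 0), c("F2", "F", 0.25),
    c("F4", "F", 0.5), c("F6", "F", 0.75), c("F8", "F", 1),
    c("FT9", "FT", -1.25), c("FT7", "FT", -1), c("FC5", "FC", -0.75),
    c("FC3", "FC", -0.5), c("FC1", "FC", -0.25), c("FC2", "FC", 0.25),
    c("FC4", "FC", 0.5), c("FC6", "FC", 0.75), c("FT8", "FT", 1),
    c("FT10", "FT", 1.25),
    c("T7", "T", -1), c("C5", "C", -0.75), c("C3", "C", -0.5),
    c("C1", "C", -0.25), c("Cz", "C", 0), c("C2", "C", 0.25),
    c("C4", "C", 0.5), c("C6", "C", 0.75), c("T8", "T", 1),
    c("TP9", "TP", -1.25), c("TP7", "TP", -1), c("CP5", "CP", -0.75),
    c("CP3", "CP", -0.5), c("CP1", "CP", -0.25), c("CPz", "CP", 0),
    c("CP2", "CP", 0.25), c("CP4", "CP", 0.5), c("CP6", "CP", 0.75),
    c("TP8", "TP", 1), c("TP10", "TP", 1.25),
    c("P7", "P", -1), c("P5", "P", -0.75), c("P3", "P", -0.5),
    c("P1", "P", -0.25), c("Pz", "P", 0), c("P2", "P", 0.25),
    c("P4", "P", 0.5), c("P6", "P", 0.75), c("P8", "P", 1),
    c("PO7", "PO", -1), c("PO3", "PO", -0.5), c("POz", "PO", 0),
    c("PO4", "PO", 0.5), c("PO8", "PO", 1),
    c("O1", "O", -1), c("Oz", "O", 0), c("O2", "O", 1),
    c("Iz", "O", 0.001))  # Iz: below Oz, handled as an over-ring midline site
  tbl <- map(spec, \(s) tibble(channel = s[1], row = s[2],
                               frac = as.numeric(s[3]))) |> list_rbind()
  az_row <- ring_az[tbl$row]
  y_disc <- cos(az_row * pi / 180)
  half_width <- sqrt(pmax(0, 1 - y_disc^2))
  x_disc <- tbl$frac * half_width
  # Iz sits 10% below Oz on the back midline
  iz <- tbl$channel == "Iz"
  x_disc[iz] <- 0
  y_disc[iz] <- -1.1
  r <- sqrt(x_disc^2 + y_disc^2)
  incl <- pmin(r, 1.3) * pi / 2
  az <- atan2(x_disc, y_disc)
  tibble(channel = tbl$channel,
         x = unname(sin(incl) * sin(az)),
         y = unname(sin(incl) * cos(az)),
         z = unname(cos(incl)))
}

#' Named scalp regions of the 64-channel montage
#'
#' @param montage Montage tibble (defaults to [standard_montage_64()]).
#' @return Named list of channel-label vectors: `fronto_central`,
#'   `occipito_parietal`, `right_frontal`.
#' @export
channel_groups <- function(montage = standard_montage_64()) {
  g <- list(
    fronto_central = c("Fz", "F1", "F2", "FC1", "FC2", "FC3", "FC4",
                       "Cz", "C1", "C2"),
    occipito_parietal = c("O1", "Oz", "O2", "Iz", "PO7", "PO3", "POz",
                          "PO4", "PO8", "P5", "P3", "P1", "Pz", "P2",
                          "P4", "P6"),
    right_frontal = c("Fp2", "AF4", "AF8", "F4", "F6", "F8", "FC4",
                      "FC6", "FT8"))
  map(g, \(ch) intersect(ch, montage$channel))
}

#' Construct an epoch set
#'
#' Container for segmented EEG: a trials x channels x samples array in
#' microvolts, the sample time axis in milliseconds, the electrode montage,
#' and a trial-label table aligned with the first array dimension.
#'
#' @param data Numeric array `trials x channels x samples`.
#' @param times Numeric vector of sample times (ms), evenly spaced.
#' @param montage Tibble `channel`, `x`, `y`, `z`; rows aligned with the
#'   channel dimension.
#' @param labels Tibble with one row per trial (any columns; typically the
#'   schedule row of the trial).
#' @param participant Identifier.
#' @return An object of class `epoch_set`.
#' @export
epoch_set <- function(data, times, montage, labels, participant = NA_character_) {
  stopifnot(length(dim(data)) == 3)
  if (dim(data)[3] != length(times)) {
    abort("time axis length does not match the sample dimension",
          class = "peersway_validation_error")
  }
  if (dim(data)[2] != nrow(montage)) {
    abort("channel count does not match the montage",
          class = "peersway_validation_error")
  }
  if (!is.null(labels) && nrow(labels) != dim(data)[1]) {
    abort("label table not aligned with trials",
          class = "peersway_validation_error")
  }
  steps <- diff(times)
  if (length(steps) && max(abs(steps - steps[1])) > 1e-9) {
    abort("time axis must be evenly spaced", class = "peersway_validation_error")
  }
  structure(list(data = data, times = times, montage = as_tibble(montage),
                 labels = if (is.null(labels)) NULL else as_tibble(labels),
                 participant = participant),
            class = "epoch_set")
}

#' @export
print.epoch_set <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<epoch_set> %s: %d trials x %d channels x %d samples (%g..%g ms, %g Hz)\n",
              x$participant, d[1], d[2], d[3], min(x$times), max(x$times),
              1000 / diff(x$times[1:2])))
  invisible(x)
}

#' @export
dim.epoch_set <- function(x) dim(x$data)

#' Sampling frequency of an epoch set (Hz)
#' @param epochs An `epoch_set`.
#' @export
sfreq <- function(epochs) 1000 / diff(epochs$times[1:2])

#' Subset an epoch set by trial
#' @param epochs An `epoch_set`.
#' @param keep Logical or integer trial index.
#' @return The subsetted `epoch_set`.
#' @export
subset_epochs <- function(epochs, keep) {
  epochs$data <- epochs$data[keep, , , drop = FALSE]
  if (!is.null(epochs$labels)) epochs$labels <- epochs$labels[keep, ]
  epochs
}

#' Re-reference epochs to the channel average
#'
#' Subtracts, for each trial and sample, the instantaneous mean across
#' channels, so the channel sum is exactly zero afterwards. Idempotent.
#'
#' @param epochs An `epoch_set`.
#' @return The re-referenced `epoch_set`.
#' @export
average_reference <- function(epochs) {
  d <- epochs$data
  ch_mean <- apply(d, c(1, 3), mean)        # trials x samples
  epochs$data <- d - rep(ch_mean, times = dim(d)[2]) |>
    array(dim = dim(d)[c(1, 3, 2)]) |> aperm(c(1, 3, 2))
  epochs
}

#' Baseline-correct epochs
#'
#' Subtracts, per trial and channel, the mean amplitude over the
#' pre-stimulus window (default -200..0 ms, 0 exclusive).
#'
#' @param epochs An `epoch_set`.
#' @param window Length-2 vector `(from, to)` in ms; samples with
#'   `from <= t < to` form the baseline.
#' @return The corrected `epoch_set`.
#' @export
baseline_correct <- function(epochs, window = c(-200, 0)) {
  sel <- epochs$times >= window[1] & epochs$times < window[2]
  if (!any(sel)) {
    abort("baseline window contains no samples",
          class = "peersway_validation_error")
  }
  d <- epochs$data
  base <- apply(d[, , sel, drop = FALSE], c(1, 2), mean)  # trials x channels
  epochs$data <- d - array(base, dim = dim(d))
  epochs
}

#' Amplitude-threshold epoch rejection
#'
#' Flags a trial when any sample on any channel exceeds the threshold in
#' absolute value.
#'
#' @param epochs An `epoch_set`.
#' @param threshold Amplitude bound in the data's units (default 100 uV).
#' @return A list: `keep` (logical per trial), `pct_rejected`,
#'   `exceed_by_channel` (per-channel count of trials in which that channel
#'   exceeded the threshold).
#' @export
reject_epochs <- function(epochs, threshold = 100) {
  d <- abs(epochs$data) > threshold
  bad_trial_channel <- apply(d, c(1, 2), any)     # trials x channels
  keep <- !apply(bad_trial_channel, 1, any)
  list(keep = keep,
       pct_rejected = 100 * mean(!keep),
       exceed_by_channel = setNames(colSums(bad_trial_channel),
                                    epochs$montage$channel))
}

#' Detect channels driving excessive rejection
#'
#' A channel is flagged bad when it exceeds the amplitude threshold in more
#' than `prop` of all epochs — the rule used to decide which channels get
#' replaced by interpolation.
#'
#' @inheritParams reject_epochs
#' @param prop Proportion of epochs above which a channel is bad
#'   (default 0.25).
#' @return Character vector of bad channel labels.
#' @export
detect_bad_channels <- function(epochs, threshold = 100, prop = 0.25) {
  counts <- reject_epochs(epochs, threshold)$exceed_by_channel
  names(counts)[counts / dim(epochs$data)[1] > prop]
}

#' Interpolate a channel from its montage neighbours
#'
#' Replaces the channel, in every trial and sample, by the
#' inverse-distance-weighted mean of its `k` nearest neighbours on the
#' montage sphere. Weights sum to one, so a spatially constant field is
#' reproduced exactly.
#'
#' @param epochs An `epoch_set`.
#' @param channel Channel label (or index) to replace.
#' @param k Number of neighbours (default 4).
#' @return The `epoch_set` with the channel rebuilt.
#' @export
interpolate_channel <- function(epochs, channel, k = 4) {
  mont <- epochs$montage
  idx <- if (is.character(channel)) match(channel, mont$channel) else channel
  if (is.na(idx)) abort("unknown channel", class = "peersway_validation_error")
  if (nrow(mont) - 1 < k) {
    abort("fewer than k other channels available",
          class = "peersway_validation_error")
  }
  pos <- as.matrix(mont[c("x", "y", "z")])
  dist <- sqrt(colSums((t(pos) - pos[idx, ])^2))
  dist[idx] <- Inf
  nb <- order(dist)[seq_len(k)]
  w <- 1 / dist[nb]
  w <- w / sum(w)
  acc <- array(0, dim = dim(epochs$data)[c(1, 3)])
  for (j in seq_len(k)) acc <- acc + w[j] * epochs$data[, nb[j], ]
  epochs$data[, idx, ] <- acc
  epochs
}

#' Write / read an epoch set as a plain-text directory container
#'
#' The container holds `times.tsv`, `montage.tsv`, `labels.tsv`, `meta.tsv`
#' and `data.tsv` (one row per trial-channel pair, samples in columns) —
#' a transparent, diff-able format suited to the small epoch sets used in
#' tests and examples.
#'
#' @param epochs An `epoch_set`.
#' @param dir Directory path (created if needed).
#' @return `write_epochs()` returns `dir` invisibly; `read_epochs()` the
#'   reconstructed `epoch_set`.
#' @export
write_epochs <- function(epochs, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  d <- dim(epochs$data)
  flat <- matrix(aperm(epochs$data, c(3, 2, 1)), nrow = d[1] * d[2],
                 byrow = TRUE)
  idx <- expand.grid(channel = seq_len(d[2]), trial = seq_len(d[1]))
  utils::write.table(cbind(trial = idx$trial, channel = idx$channel, flat),
                     file.path(dir, "data.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  utils::write.table(data.frame(time_ms = epochs$times),
                     file.path(dir, "times.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  utils::write.table(epochs$montage, file.path(dir, "montage.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  if (!is.null(epochs$labels)) {
    utils::write.table(epochs$labels, file.path(dir, "labels.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
  }
  utils::write.table(data.frame(participant = epochs$participant),
                     file.path(dir, "meta.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(dir)
}

#' @rdname write_epochs
#' @export
read_epochs <- function(dir) {
  times <- utils::read.table(file.path(dir, "times.tsv"), header = TRUE,
                             sep = "\t")$time_ms
  montage <- as_tibble(utils::read.table(file.path(dir, "montage.tsv"),
                                         header = TRUE, sep = "\t"))
  meta <- utils::read.table(file.path(dir, "meta.tsv"), header = TRUE,
                            sep = "\t")
  flat <- as.matrix(utils::read.table(file.path(dir, "data.tsv"),
                                      header = TRUE, sep = "\t"))
  n_trial <- max(flat[, "trial"])
  n_chan <- max(flat[, "channel"])
  ord <- order(flat[, "trial"], flat[, "channel"])
  vals <- flat[ord, -(1:2), drop = FALSE]
  data <- aperm(array(t(vals), dim = c(length(times), n_chan, n_trial)),
                c(3, 2, 1))
  labels_path <- file.path(dir, "labels.tsv")
  labels <- if (file.exists(labels_path)) {
    as_tibble(utils::read.table(labels_path, header = TRUE, sep = "\t"))
  }
  epoch_set(data, times, montage, labels, participant = meta$participant[1])
}
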