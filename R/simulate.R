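#' Cohort generative parameters
#'
#' Defines the synthetic cohort: a standard-normal latent vulnerability
#' trait `v` per subject drives (i) the behavioural reliance weight on peer
#' feedback, `w = plogis(a + b * v)`, (ii) questionnaire item responses
#' through factor loadings, and (iii) the gain of the condition-dependent
#' EEG components, `g = c0 + c1 * v + noise`. The `"paper-like"` preset
#' uses positive `b` and `c1`, so higher perceived vulnerability means both
#' stronger rating adjustment and stronger neural sensitivity to
#' disagreement — the structure the analysis pipeline is built to detect.
#'
#' Preset magnitudes are calibration choices for desk-scale power (see the
#' methods vignette), versioned here as explicit constants.
#'
#' @param preset `"paper-like"` (positive links) or `"null"` (all effects
#'   zero: flat behaviour, noise-only EEG).
#' @param n_subjects Cohort size (default 17).
#' @param a,b Intercept and slope of the logistic vulnerability-to-reliance
#'   link.
#' @param rating_noise_sd SD of the post-rating noise (scale points).
#' @param init_mean,init_sd Mean and SD of initial trustworthiness ratings
#'   (defaults 4.2 and 1.5 on the 1-8 scale).
#' @param likert_points Questionnaire scale points (default 7).
#' @param pi_loading,ga_loading Factor loadings of the PI and GA items.
#' @param ga_noise_items Item numbers whose loading is forced to zero
#'   (e.g. `c(4, 9, 11, 15)` to emulate an incoherent GA subscale).
#' @param c0,c1 Intercept and slope of the vulnerability-to-gain link.
#' @param gain_noise_sd SD of the subject gain noise.
#' @param amp_moderate,amp_strong Component amplitudes (uV) for moderate
#'   and strong disagreement; agreement trials carry no component.
#' @param noise_sd EEG noise SD per channel (uV).
#' @param ar_phi AR(1) coefficient of the temporal noise correlation.
#' @param spatial_scale Length scale of the exponential spatial noise
#'   correlation (unit-sphere distance).
#' @param sfreq Sampling rate in Hz (default 100 for desk-scale runs; 500
#'   mirrors the recording standard).
#' @return A `cohort_params` list.
#' @export
cohort_params <- function(preset = c("paper-like", "null"),
                          n_subjects = 17,
                          a = -1.1, b = 0.8,
                          rating_noise_sd = 0.8,
                          init_mean = 4.2, init_sd = 1.5,
                          likert_points = 7L,
                          pi_loading = 1.4, ga_loading = 0.75,
                          ga_noise_items = NULL,
                          c0 = 1, c1 = 0.45, gain_noise_sd = 0.15,
                          amp_moderate = 7, amp_strong = 10,
                          noise_sd = 10, ar_phi = 0.9, spatial_scale = 0.6,
                          sfreq = 100) {
  preset <- match.arg(preset)
  if (preset == "null") {
    b <- 0; c1 <- 0; amp_moderate <- 0; amp_strong <- 0
  }
  if (b < 0 || c1 < 0) {
    abort("the vulnerability links b and c1 must be non-negative",
          class = "peersway_config_error")
  }
  if (amp_strong < amp_moderate) {
    abort("strong-disagreement amplitude must be >= moderate",
          class = "peersway_config_error")
  }
  structure(as.list(environment()), class = "cohort_params")
}

#' Spatiotemporal component templates
#'
#' The two condition-dependent components planted in synthetic epochs:
#' an early fronto-central component with a Gaussian time-course peaking at
#' 300 ms (support 200-400 ms), mirroring feedback-conflict activity, and a
#' late sustained occipito-parietal/right-frontal component spanning
#' 400-900 ms. Spatial weight vectors are unit-norm over the montage;
#' temporal profiles are non-negative and exactly zero outside their
#' support (so the pre-stimulus baseline stays signal-free).
#'
#' @param montage Montage tibble (default [standard_montage_64()]).
#' @param times Sample time axis in ms.
#' @return A list of two components, each with `spatial` (per-channel
#'   weights) and `temporal` (per-sample profile).
#' @export
make_templates <- function(montage = standard_montage_64(),
                           times) {
  groups <- channel_groups(montage)
  unit_weights <- function(chs) {
    w <- as.numeric(montage$channel %in% chs)
    w / sqrt(sum(w^2))
  }
  tp1 <- exp(-0.5 * ((times - 300) / 40)^2)
  tp1[times < 200 | times > 400] <- 0
  ramp <- function(t, from, to) pmin(1, pmax(0, (t - from) / (to - from)))
  tp2 <- 1.35 * ramp(times, 400, 475) * ramp(-times, -900, -825)
  tp2[times < 400 | times > 900] <- 0
  list(
    stage1 = list(spatial = unit_weights(groups$fronto_central),
                  temporal = tp1),
    stage2 = list(spatial = unit_weights(c(groups$occipito_parietal,
                                           groups$right_frontal)),
                  temporal = tp2))
}

clip_rating <- function(x, lo = 1L, hi = 8L) {
  as.integer(pmin(hi, pmax(lo, round(x))))
}

#' Simulate behaviour for a cohort
#'
#' Draws latent vulnerability `v ~ N(0,1)` and reliance `w = plogis(a+b*v)`
#' per subject; generates a schedule per subject, initial ratings
#' `round(clip(N(init_mean, init_sd)))`, assigns feedback adaptively, and
#' produces post-test ratings `round(clip(test + w*(fictive - test) +
#' noise))` on disagreement trials (agreement and no-feedback trials move
#' by noise only).
#'
#' @param params A [cohort_params()].
#' @param design A [design_config()] (default the lab design).
#' @param seed Integer RNG seed.
#' @return A list: `trials` (all subjects' two-phase tables, post ratings
#'   filled) and `truth` (tibble `participant`, `v`, `w`, `gain`).
#' @export
simulate_behavior <- function(params, design = design_config("lab"),
                              seed = NULL) {
  with_rng(seed, {
    n <- params$n_subjects
    ids <- sprintf("S%02d", seq_len(n))
    v <- rnorm(n)
    w <- plogis(params$a + params$b * v)
    gain <- params$c0 + params$c1 * v + rnorm(n, sd = params$gain_noise_sd)
    trials <- map(seq_len(n), function(i) {
      sch <- generate_schedule(design, participant = ids[i])
      n_faces <- design$n_block_pairs * design$trials_per_block
      ratings <- clip_rating(rnorm(n_faces, params$init_mean, params$init_sd),
                             design$scale_min, design$scale_max)
      sch$test_rating[sch$phase == "test"] <- ratings
      sch <- suppressMessages(assign_feedback(sch, design))
      post_idx <- sch$phase == "post_test"
      pull_toward <- ifelse(
        sch$condition[post_idx] %in% disagreement_conditions(),
        w[i] * (sch$fictive_rating[post_idx] - sch$test_rating[post_idx]),
        0)
      pull_toward[is.na(pull_toward)] <- 0
      sch$post_rating[post_idx] <- clip_rating(
        sch$test_rating[post_idx] + pull_toward +
          rnorm(sum(post_idx), sd = params$rating_noise_sd),
        design$scale_min, design$scale_max)
      sch
    }) |> list_rbind()
    list(trials = trials,
         truth = tibble(participant = ids, v = v, w = w, gain = gain))
  })
}

#' Simulate questionnaire responses
#'
#' Each item response loads on the latent vulnerability trait:
#' `x = loading * v + N(0,1)`, mapped to the Likert scale by
#' `round(clip(midpoint + spread * x / sd(x)))`. Reverse-marked items are
#' generated with the inverted sign, so reverse-scoring recovers the
#' positive loading.
#'
#' @param params A [cohort_params()].
#' @param truth Truth table from [simulate_behavior()] (uses `v`).
#' @param seed Integer RNG seed.
#' @return Tibble `participant`, `item_1`..`item_15`.
#' @export
simulate_pvd <- function(params, truth, seed = NULL) {
  with_rng(seed, {
    map_tbl <- pvd_item_map()
    L <- params$likert_points
    mid <- (L + 1) / 2
    v <- truth$v
    items <- map(seq_len(15), function(j) {
      lam <- if (map_tbl$subscale[j] == "PI") params$pi_loading
             else params$ga_loading
      if (j %in% params$ga_noise_items) lam <- 0
      sgn <- if (map_tbl$reverse[j]) -1 else 1
      x <- sgn * lam * v + rnorm(length(v))
      spread <- 1.3 / sqrt(lam^2 + 1)
      as.integer(pmin(L, pmax(1, round(mid + spread * x))))
    })
    names(items) <- sprintf("item_%d", 1:15)
    bind_cols(tibble(participant = truth$participant), as_tibble(items))
  })
}

# spatially correlated AR(1) noise: channels x samples
correlated_noise <- function(L_chol, n_samples, ar_phi, noise_sd) {
  n_chan <- nrow(L_chol)
  white <- matrix(rnorm(n_chan * n_samples), n_chan, n_samples)
  sp <- L_chol %*% white
  out <- sp
  scale_innov <- sqrt(1 - ar_phi^2)
  for (t in 2:n_samples) {
    out[, t] <- ar_phi * out[, t - 1] + scale_innov * sp[, t]
  }
  noise_sd * out
}

#' Simulate EEG epochs for one subject's feedback trials
#'
#' Each epoch is the sum of the two component templates, scaled by the
#' condition amplitude (agreement 0; moderate < strong disagreement) and
#' the subject gain, plus spatially correlated AR(1) Gaussian noise.
#' No-feedback trials carry no epoch (they are excluded from EEG analysis).
#'
#' @param params A [cohort_params()].
#' @param templates From [make_templates()] (built on `times` if `NULL`).
#' @param trials One subject's test-phase trial rows with conditions
#'   assigned; no-feedback rows are dropped.
#' @param gain Subject gain (from the truth table).
#' @param montage Montage tibble.
#' @param seed Integer RNG seed.
#' @return An [epoch_set()] with the retained trial rows as labels.
#' @export
simulate_epochs <- function(params, templates = NULL, trials, gain = 1,
                            montage = standard_montage_64(), seed = NULL) {
  step <- 1000 / params$sfreq
  times <- seq(-200, 1000 - step, by = step)
  if (is.null(templates)) templates <- make_templates(montage, times)
  if (length(templates$stage1$spatial) != nrow(montage) ||
      length(templates$stage1$temporal) != length(times)) {
    abort("templates do not match the montage/time axis",
          class = "peersway_validation_error")
  }
  keep <- trials$phase == "test" & trials$condition != "no_feedback"
  trials <- trials[keep, ]
  n_trial <- nrow(trials)
  n_chan <- nrow(montage)
  amp <- case_when(
    trials$condition %in% c("pos_mod", "neg_mod") ~ params$amp_moderate,
    trials$condition %in% c("pos_strong", "neg_strong") ~ params$amp_strong,
    .default = 0)
  signal1 <- outer(templates$stage1$spatial, templates$stage1$temporal)
  signal2 <- outer(templates$stage2$spatial, templates$stage2$temporal)
  base_signal <- signal1 + signal2           # channels x samples
  pos <- as.matrix(montage[c("x", "y", "z")])
  D2 <- as.matrix(stats::dist(pos))
  L_chol <- t(chol(exp(-D2 / params$spatial_scale) +
                     diag(1e-8, n_chan)))
  data <- array(0, dim = c(n_trial, n_chan, length(times)))
  with_rng(seed, {
    for (i in seq_len(n_trial)) {
      eps <- if (params$noise_sd > 0) {
        correlated_noise(L_chol, length(times), params$ar_phi,
                         params$noise_sd)
      } else 0
      data[i, , ] <- amp[i] * gain * base_signal + eps
    }
  })
  epoch_set(data, times, montage, labels = trials,
            participant = trials$participant[1])
}

#' Simulate a full cohort dataset
#'
#' Behaviour, questionnaire responses and (optionally) EEG epochs for every
#' subject, with per-stage seeds derived from one master seed.
#'
#' @param params A [cohort_params()].
#' @param design A [design_config()].
#' @param seed Master integer seed.
#' @param eeg Generate epochs (default `TRUE`).
#' @return A list: `trials`, `truth`, `pvd`, and `epochs` (named list of
#'   per-subject `epoch_set`s) when requested.
#' @export
simulate_cohort <- function(params, design = design_config("lab"),
                            seed = 1, eeg = TRUE) {
  seed <- as.integer(seed)
  beh <- simulate_behavior(params, design, seed = seed)
  pvd <- simulate_pvd(params, beh$truth, seed = seed + 10007L)
  out <- list(trials = beh$trials, truth = beh$truth, pvd = pvd)
  if (eeg) {
    montage <- standard_montage_64()
    out$epochs <- map(seq_len(nrow(beh$truth)), function(i) {
      id <- beh$truth$participant[i]
      simulate_epochs(params,
                      trials = filter(beh$trials, .data$participant == id),
                      gain = beh$truth$gain[i], montage = montage,
                      seed = seed + 20011L + i)
    }) |> setNames(beh$truth$participant)
  }
  out
}
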