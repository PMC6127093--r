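test_that("average reference zeroes the channel sum and is idempotent", {
  ep <- make_toy_epochs(n_trials = 10, seed = 2)
  # constant offset across channels vanishes
  ep_off <- ep
  ep_off$data <- ep$data + 5
  r1 <- average_reference(ep_off)
  r2 <- average_reference(ep)
  expect_equal(r1$data, r2$data)
  sums <- apply(r1$data, c(1, 3), sum)
  expect_lt(max(abs(sums)), 1e-9)
  expect_equal(average_reference(r1)$data, r1$data)
})

test_that("baseline correction subtracts the analytic window mean", {
  ep <- make_toy_epochs(n_trials = 2, n_samples = 40, seed = 3)
  # flat epochs go to zero
  flat <- ep
  flat$data[] <- 5
  expect_true(all(baseline_correct(flat)$data == 0))
  # linear ramp: post-stimulus values shift by the baseline-ramp mean
  ramp <- ep
  for (t in seq_along(ramp$times)) ramp$data[, , t] <- ramp$times[t]
  bc <- baseline_correct(ramp, window = c(-200, 0))
  base_mean <- mean(ramp$times[ramp$times >= -200 & ramp$times < 0])
  t_post <- which(ramp$times == 100)
  expect_equal(unname(bc$data[1, 1, t_post]), 100 - base_mean)
  # idempotent
  expect_equal(baseline_correct(bc)$data, bc$data, tolerance = 1e-12)
  expect_error(baseline_correct(ep, window = c(-900, -800)),
               class = "peersway_validation_error")
})

test_that("epoch rejection flags exactly the threshold crossings, monotonically", {
  ep <- make_toy_epochs(n_trials = 20, seed = 4)
  ep$data <- ep$data * 10   # within +/- 50 or so
  ep$data[7, 3, 5] <- 150
  res <- reject_epochs(ep, threshold = 100)
  expect_equal(which(!res$keep), 7L)
  expect_equal(res$pct_rejected, 5)
  expect_equal(unname(res$exceed_by_channel[3]), 1)
  # monotone non-increasing rejection count in the threshold
  counts <- sapply(c(50, 100, 150, 200), \(th) sum(!reject_epochs(ep, th)$keep))
  expect_true(all(diff(counts) <= 0))
  clean <- reject_epochs(ep, threshold = 1e5)
  expect_equal(clean$pct_rejected, 0)
})

test_that("bad-channel detection uses the 25% contribution rule", {
  ep <- make_toy_epochs(n_trials = 20, seed = 5)
  ep$data[1:6, 2, 4] <- 500    # channel 2 breaks 6/20 = 30% of epochs
  bad <- detect_bad_channels(ep, threshold = 100, prop = 0.25)
  expect_equal(bad, ep$montage$channel[2])
  expect_length(detect_bad_channels(ep, threshold = 100, prop = 0.35), 0)
})

test_that("neighbour interpolation is exact on constant fields and bounded on gradients", {
  mont <- standard_montage_64()
  n_ch <- nrow(mont)
  times <- seq(-200, 190, by = 10)
  # spatially constant field: interpolation must reproduce it exactly
  const <- array(rep(sin(times / 50), each = 2 * n_ch), c(2, n_ch, length(times)))
  ep <- epoch_set(const, times, mont, labels = NULL)
  ip <- interpolate_channel(ep, "Cz", k = 4)
  expect_equal(ip$data, ep$data, tolerance = 1e-12)
  # planted linear gradient in x: error bounded by the neighbour x-spread
  grad <- array(0, c(1, n_ch, length(times)))
  for (ch in seq_len(n_ch)) grad[1, ch, ] <- mont$x[ch]
  epg <- epoch_set(grad, times, mont, labels = NULL)
  ig <- interpolate_channel(epg, "C3", k = 4)
  idx <- match("C3", mont$channel)
  pos <- as.matrix(mont[c("x", "y", "z")])
  d <- sqrt(colSums((t(pos) - pos[idx, ])^2)); d[idx] <- Inf
  nb <- order(d)[1:4]
  spread <- max(abs(mont$x[nb] - mont$x[idx]))
  expect_lt(abs(ig$data[1, idx, 1] - mont$x[idx]), spread + 1e-12)
  # untouched channels stay identical
  expect_equal(ig$data[, -idx, ], epg$data[, -idx, ])
  expect_error(interpolate_channel(make_toy_epochs(n_chan = 3), 1, k = 4),
               class = "peersway_validation_error")
})

test_that("text container round-trips an epoch set", {
  lab <- tibble::tibble(condition = rep(c("agree", "pos_mod"), 3),
                        test_rating = 1:6)
  ep <- make_toy_epochs(n_trials = 6, n_chan = 4, n_samples = 10, seed = 6,
                        labels = lab)
  dir <- withr::local_tempdir()
  write_epochs(ep, dir)
  back <- read_epochs(dir)
  expect_equal(back$data, ep$data, tolerance = 1e-12)
  expect_equal(back$times, ep$times)
  expect_equal(back$labels$condition, lab$condition)
  expect_equal(back$montage$channel, ep$montage$channel)
})

test_that("the montage has 64 uniquely named channels on the unit sphere with sane regions", {
  m <- standard_montage_64()
  expect_equal(nrow(m), 64)
  expect_equal(anyDuplicated(m$channel), 0)
  r <- sqrt(m$x^2 + m$y^2 + m$z^2)
  expect_equal(r, rep(1, 64), tolerance = 1e-9)
  g <- channel_groups(m)
  expect_true(all(lengths(g) >= 5))
  # frontal channels are in front (y > 0), occipital behind
  expect_true(all(m$y[m$channel %in% g$right_frontal] > 0))
  expect_true(all(m$x[m$channel %in% g$right_frontal] > 0))
  expect_true(all(m$y[m$channel %in% g$occipito_parietal] < 0))
})
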