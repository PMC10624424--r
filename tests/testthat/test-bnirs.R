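layout19 <- probe_layout()

make_noise_free_rec <- function(ext, seed = 3, n_trials = 2) {
  s <- generate_schedule(n_trials, rng_seed = seed)
  amp <- matrix(0, 19, 2)
  amp[c(3, 14), 1] <- c(0.4, 1.0)
  amp[14, 2] <- -0.5
  tr <- simulate_chromophore_truth(s, layout19, amplitude = amp,
                                   chromophore_scale = c(1, -0.5, 0.1))
  list(truth = tr,
       rec = forward_attenuation(tr, ext, layout19, noise_sd = 0))
}

test_that("UCLn inversion is the exact inverse of the forward model", {
  for (ext in list(ext16, synthetic_extinction())) {
    fx <- make_noise_free_rec(ext)
    back <- ucln_invert(fx$rec, ext)
    expect_lt(max(abs(back$conc - fx$truth$conc)), 1e-9)
  }
})

test_that("zero attenuation maps to zero concentration", {
  fx <- make_noise_free_rec(ext16)
  fx$rec$attenuation[] <- 0
  back <- ucln_invert(fx$rec, ext16)
  expect_true(all(back$conc == 0))
})

test_that("three wavelengths reproduce the closed-form 3x3 solve", {
  e3 <- extinction_table(c(790, 830, 870),
                         matrix(c(0.8, 1.1, 0.9,
                                  1.0, 0.7, 1.3,
                                  1.2, 0.9, 0.5) / 1000, 3, 3, byrow = TRUE))
  dc <- c(1.0, -0.5, 0.1)
  d <- 2.5; dpf <- 5.13
  dA <- e3$epsilon %*% dc * d * dpf
  rec <- structure(list(
    attenuation = array(rep(dA, 4), dim = c(1, 3, 4)),
    wavelengths_nm = e3$wavelengths_nm, time_s = seq(0, 4.2, by = 1.4),
    intensity_counts = 10000,
    layout = probe_layout(1, 1, data.frame(source = 1, detector = 1))),
    class = "bnirs_recording")
  got <- ucln_invert(rec, e3, dpf = dpf)
  # independent oracle: direct 3x3 inverse
  oracle <- solve(e3$epsilon * d * dpf, dA)
  expect_equal(got$conc[1, , 2], drop(oracle), tolerance = 1e-9,
               ignore_attr = TRUE)
  expect_equal(got$conc[1, , 2], dc, tolerance = 1e-9, ignore_attr = TRUE)
})

test_that("noise error shrinks as wavelength count grows from 3 to 120", {
  s <- generate_schedule(1, rng_seed = 5)
  amp <- matrix(0, 19, 2); amp[1, 1] <- 1
  tr <- simulate_chromophore_truth(s, layout19, amplitude = amp)
  errs <- sapply(c(3, 10, 40, 120), function(nw) {
    ext <- synthetic_extinction(seq(780, 900, length.out = nw))
    mean(sapply(1:50, function(seed) {
      rec <- forward_attenuation(tr, ext, layout19, noise_sd = 0.005,
                                 rng_seed = seed)
      back <- ucln_invert(rec, ext)
      sqrt(mean((back$conc[1, , ] - tr$conc[1, , ])^2))
    }))
  })
  expect_true(all(diff(errs) < 0))
})

test_that("rank-deficient extinction matrices are rejected", {
  e <- synthetic_extinction(seq(780, 900, length.out = 12))
  e$epsilon[, 3] <- e$epsilon[, 1] + e$epsilon[, 2]  # collinear
  fx <- make_noise_free_rec(synthetic_extinction(seq(780, 900, length.out = 12)))
  expect_error(ucln_invert(fx$rec, e), "rank")
})

test_that("the band-pass filter has the stated frequency response", {
  fs <- 5
  t <- seq(0, 400, by = 1 / fs)
  mk <- function(x) chromophore_ts(array(x, dim = c(1, 3, length(x))), t)
  # DC rejected
  dc <- bandpass_bnirs(mk(rep(5, length(t))), 0.01, 0.4)
  expect_lt(mean(abs(dc$conc[1, 1, ])), 0.05)
  # 0.05 Hz in the passband: amplitude gain ~ 1
  x <- sin(2 * pi * 0.05 * t)
  mid <- seq(round(length(t) * 0.3), round(length(t) * 0.7))
  g_pass <- max(abs(bandpass_bnirs(mk(x), 0.01, 0.4)$conc[1, 1, mid]))
  expect_gt(g_pass, 0.9); expect_lt(g_pass, 1.1)
  # 1 Hz in the stopband: gain < 0.1
  y <- sin(2 * pi * 1 * t)
  g_stop <- max(abs(bandpass_bnirs(mk(y), 0.01, 0.4)$conc[1, 1, mid]))
  expect_lt(g_stop, 0.1)
})

test_that("a 0.4 Hz edge above Nyquist is clamped with a warning", {
  t <- seq(0, 140, by = 1.4)  # fs ~ 0.714 Hz, Nyquist ~ 0.357 Hz
  ts <- chromophore_ts(array(rnorm(3 * length(t)), dim = c(1, 3, length(t))), t)
  expect_warning(bandpass_bnirs(ts, 0.01, 0.4), "clamped")
})

test_that("QC applies the 2000/40000 count bounds and the 60% subject rule", {
  fx <- make_noise_free_rec(ext16)
  rec <- fx$rec
  rec$intensity_counts <- rep(25000, 19)
  rec$intensity_counts[1] <- 1500    # too dim
  rec$intensity_counts[2] <- 45000   # saturated
  qc <- qc_channels(rec)
  expect_false(qc$channels$keep[1])
  expect_false(qc$channels$keep[2])
  expect_true(all(qc$channels$keep[3:19]))
  expect_equal(qc$exclusion_fraction, 2 / 19)
  expect_false(qc$subject_excluded)
  # exactly at the bounds is retained
  rec$intensity_counts <- c(2000, 40000, rep(10000, 17))
  expect_true(all(qc_channels(rec)$channels$keep))
  # 12 of 19 excluded (63.2%) crosses the 60% subject threshold
  rec$intensity_counts <- c(rep(100, 12), rep(10000, 7))
  qc <- qc_channels(rec)
  expect_identical(length(qc$excluded_channels), 12L)
  expect_true(qc$subject_excluded)
  # 11 of 19 (57.9%) does not
  rec$intensity_counts <- c(rep(100, 11), rep(10000, 8))
  expect_false(qc_channels(rec)$subject_excluded)
})

test_that("block averaging is the mean of identical blocks and cancels x/-x", {
  t <- seq(0, 100, by = 1.4)
  conc <- array(0, dim = c(1, 3, length(t)))
  s <- structure(
    data.frame(condition = c("baseline", "social", "baseline", "social"),
               onset_s = c(2, 10, 40, 48), duration_s = c(8, 10, 8, 10)),
    total_duration_s = 100, class = c("stim_schedule", "data.frame"))
  s$sub_durations_s <- vector("list", 4)
  shape <- sin(seq(0, pi, length.out = 15))
  i1 <- which.min(abs(t - 10)); i2 <- which.min(abs(t - 48))
  conc[1, 1, i1:(i1 + 14)] <- shape
  conc[1, 1, i2:(i2 + 14)] <- shape
  ts <- chromophore_ts(conc, t)
  ba <- block_average_bnirs(ts, s, "social", window_s = 20)
  expect_identical(ba$n_blocks, 2L)
  post <- ba$time_s >= 0 & ba$time_s <= 14 * 1.4
  expect_equal(ba$mean[1, 1, post], shape[seq_len(sum(post))], tolerance = 1e-9)
  # opposite-sign blocks cancel
  conc[1, 1, i2:(i2 + 14)] <- -shape
  ba2 <- block_average_bnirs(chromophore_ts(conc, t), s, "social", window_s = 20)
  expect_lt(max(abs(ba2$mean)), 1e-12)
  # no usable blocks is an error
  expect_error(block_average_bnirs(ts, s, "non-social"), "no usable")
})

test_that("averaging n white-noise blocks shrinks RMS like 1/sqrt(n)", {
  set.seed(77)
  n_blocks <- 100
  dt <- 1.4
  block_len <- 20
  total <- 10 + n_blocks * (8 + block_len) + 10
  t <- seq(0, total, by = dt)
  onsets <- 10 + (seq_len(n_blocks) - 1) * (8 + block_len) + 8
  s <- structure(
    data.frame(condition = rep(c("baseline", "social"), n_blocks),
               onset_s = as.vector(rbind(onsets - 8, onsets)),
               duration_s = rep(c(8, block_len - 8), n_blocks)),
    total_duration_s = total, class = c("stim_schedule", "data.frame"))
  s$sub_durations_s <- vector("list", 2 * n_blocks)
  conc <- array(rnorm(3 * length(t)), dim = c(1, 3, length(t)))
  ba <- block_average_bnirs(chromophore_ts(conc, t), s, "social",
                            window_s = 10)
  avg_rms <- sqrt(mean(ba$mean[1, 1, ]^2))
  expect_lt(abs(avg_rms - 1 / sqrt(n_blocks)) / (1 / sqrt(n_blocks)), 0.30)
})
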