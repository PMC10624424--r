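layout19 <- probe_layout()

test_that("chromophore truth is linear in the amplitudes", {
  s <- generate_schedule(2, rng_seed = 5)
  amp0 <- matrix(0, 19, 2)
  z <- simulate_chromophore_truth(s, layout19, amplitude = amp0)
  expect_true(all(z$conc == 0))

  amp <- amp0; amp[7, 1] <- 0.5
  one <- simulate_chromophore_truth(s, layout19, amplitude = amp)
  amp2 <- amp0; amp2[7, 1] <- 1.0
  two <- simulate_chromophore_truth(s, layout19, amplitude = amp2)
  expect_equal(two$conc[7, , ], 2 * one$conc[7, , ], tolerance = 1e-12)
  # untouched channels stay zero
  expect_true(all(one$conc[-7, , ] == 0))
})

test_that("a single block reproduces the brute-force boxcar convolution", {
  s <- structure(
    data.frame(condition = c("baseline", "social"), onset_s = c(2, 10),
               duration_s = c(8, 10)),
    total_duration_s = 40, class = c("stim_schedule", "data.frame"))
  s$sub_durations_s <- list(c(3, 3, 2), NULL)
  amp <- matrix(0, 19, 2, dimnames = list(NULL, c("social", "non-social")))
  amp[1, "social"] <- 1
  dt <- 1.4
  tr <- simulate_chromophore_truth(s, layout19, amplitude = amp,
                                   chromophore_scale = c(1, 0, 0),
                                   sample_period_s = dt)
  kern <- double_gamma(infant_basis_defaults()$HbO2, sample_period_s = dt)
  box <- as.numeric(tr$time_s >= 10 & tr$time_s < 20)
  expect_equal(tr$conc[1, 1, ], conv_oracle(box, kern$kernel) * dt,
               tolerance = 1e-12)
})

test_that("the forward model reduces to eps * c * d * DPF at one wavelength", {
  s <- generate_schedule(1, rng_seed = 1)
  tr <- simulate_chromophore_truth(s, layout19)
  tr$conc[] <- 0
  tr$conc[1, 1, ] <- 1  # 1 uM HbO2 everywhere in time
  e1 <- extinction_table(c(800, 850, 900), diag(3))
  rec <- forward_attenuation(tr, e1, layout19, dpf = 5.13, noise_sd = 0)
  # eps 1 OD/(uM cm) x 1 uM x 2.5 cm x 5.13
  expect_equal(rec$attenuation[1, 1, 5], 1 * 2.5 * 5.13, tolerance = 1e-12)
  expect_true(all(rec$attenuation[1, 2:3, ] == 0))
  expect_true(all(rec$attenuation[2:19, , ] == 0))
})

test_that("zero concentrations give zero noise-free attenuation", {
  s <- generate_schedule(1, rng_seed = 2)
  tr <- simulate_chromophore_truth(s, layout19)
  rec <- forward_attenuation(tr, ext16, layout19, noise_sd = 0)
  expect_true(all(rec$attenuation == 0))
  expect_true(all(rec$intensity_counts >= 0))
})

test_that("a wavelength outside the extinction table is an error", {
  s <- generate_schedule(1, rng_seed = 2)
  tr <- simulate_chromophore_truth(s, layout19)
  rec <- forward_attenuation(tr, ext16, layout19, noise_sd = 0)
  expect_error(ucln_invert(rec, extinction_table(c(800, 850, 899), diag(3)),
                           fit_range_nm = c(780, 900)),
               "not covered")
})

test_that("motion spikes are shared across wavelengths within a channel", {
  s <- generate_schedule(2, rng_seed = 7)
  tr <- simulate_chromophore_truth(s, layout19)
  rec <- forward_attenuation(tr, ext16, layout19, noise_sd = 0,
                             spike_spec = list(rate_per_min = 6,
                                               amplitude_od = 0.5,
                                               width_s = 1),
                             rng_seed = 3)
  # spikes exist, and wherever one wavelength deviates, all do identically
  dev <- abs(rec$attenuation) > 1e-9
  expect_true(any(dev))
  hit <- which(apply(dev, c(1, 3), any), arr.ind = TRUE)
  for (r in seq_len(nrow(hit))) {
    col <- rec$attenuation[hit[r, 1], , hit[r, 2]]
    expect_equal(max(col) - min(col), 0, tolerance = 1e-12)
  }
})

test_that("EEG simulation respects the aliasing guard and determinism", {
  s <- generate_schedule(2, rng_seed = 1)
  expect_error(simulate_eeg(s, fs = 120), "aliasing|too low")
  a <- simulate_eeg(s, fs = 250, channels = c("Pz", "Cz"), rng_seed = 8)
  b <- simulate_eeg(s, fs = 250, channels = c("Pz", "Cz"), rng_seed = 8)
  expect_identical(a, b)
  expect_identical(dim(a$signal)[1], 2L)
})

test_that("unit gains give matched stimulus and baseline band power", {
  # many blocks so the sampling error of the RMS contrast is small
  s <- generate_schedule(50, rng_seed = 21)
  eeg <- simulate_eeg(s, gains = NULL, fs = 250, channels = c("Pz", "O2"),
                      rng_seed = 9)
  f <- rereference_average(filter_eeg(eeg))
  seg <- reject_artifact_segments(segment_and_baseline(f, s))
  bp <- band_rms(seg, bands2)
  avg <- block_baseline_correct_and_average(bp)
  for (cond in c("social", "non-social")) {
    stim <- mean(avg[[cond]]$rms[, , 9:16])
    base <- mean(avg[[cond]]$rms[, , 1:8])
    # block baseline correction centres the baseline near zero; the stimulus
    # level must not differ from it by more than sampling noise
    expect_lt(abs(stim - base), 0.15)
  }
})

test_that("requested artifacts exceed the 200 uV rejection threshold", {
  s <- generate_schedule(3, rng_seed = 2)
  eeg <- simulate_eeg(s, fs = 250, channels = c("Pz", "Cz", "O2"),
                      artifact_rate = 0.3, rng_seed = 4)
  n_seg <- floor(attr(s, "total_duration_s"))
  over <- vapply(seq_len(n_seg), function(k) {
    idx <- ((k - 1) * 250 + 1):(k * 250)
    max(abs(eeg$signal[, idx])) > 200
  }, logical(1))
  expect_true(any(over))
})

test_that("the attention mask marks inattentive segments", {
  s <- generate_schedule(3, rng_seed = 2)
  eeg <- simulate_eeg(s, fs = 250, channels = c("Pz", "Cz"),
                      inattention_prob = 0.4, rng_seed = 6)
  expect_true(any(!eeg$attention_mask))
  expect_true(any(eeg$attention_mask))
  seg <- segment_and_baseline(eeg, s)
  reasons <- unlist(lapply(seg$blocks, `[[`, "reason"))
  expect_true("inattention" %in% reasons)
})

test_that("identical seeds give identical complete sessions", {
  a <- simulate_subject(n_trials = 2, fs = 250,
                        eeg_channels = c("Pz", "Cz"), extinction = ext16,
                        rng_seed = 123)
  b <- simulate_subject(n_trials = 2, fs = 250,
                        eeg_channels = c("Pz", "Cz"), extinction = ext16,
                        rng_seed = 123)
  expect_identical(a, b)
})
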