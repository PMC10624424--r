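make_eeg <- function(signal, fs = 500, labels = NULL, mask = NULL) {
  if (is.null(labels)) labels <- montage_labels()[seq_len(nrow(signal))]
  structure(list(signal = signal, fs = fs, labels = labels,
                 attention_mask = mask),
            class = "eeg_recording")
}

test_that("the EEG filter passes 10 Hz, notches 50 Hz and removes DC", {
  fs <- 500
  t <- seq(0, 20, by = 1 / fs)
  mid <- seq(round(length(t) * 0.3), round(length(t) * 0.7))
  one <- function(f, dc = 0) {
    rec <- make_eeg(matrix(sin(2 * pi * f * t) + dc, 1), fs, "Pz")
    filter_eeg(rec)$signal[1, ]
  }
  expect_gt(max(abs(one(10)[mid])), 0.9)
  expect_lt(max(abs(one(10)[mid])), 1.1)
  expect_lt(max(abs(one(50)[mid])), 0.05)
  # 100 uV DC offset: residual mean far below 1 uV
  rec <- make_eeg(matrix(rep(100, length(t)), 1), fs, "Pz")
  expect_lt(mean(abs(filter_eeg(rec)$signal[1, mid])), 1)
  # band edge at Nyquist is refused
  expect_error(filter_eeg(make_eeg(matrix(0, 1, 100), 150, "Pz")), "Nyquist")
})

test_that("average re-referencing zeroes the montage mean", {
  a <- sin(seq(0, 10, length.out = 200)); b <- rnorm(200)
  two <- rereference_average(make_eeg(rbind(a, b), 100, c("Pz", "Cz")))
  expect_equal(two$signal[1, ], (a - b) / 2, tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_equal(two$signal[2, ], (b - a) / 2, tolerance = 1e-12,
               ignore_attr = TRUE)
  # idempotent on zero-mean montages
  again <- rereference_average(two)
  expect_equal(again$signal, two$signal, tolerance = 1e-12)
  # random 32-channel frame: column means vanish
  x <- matrix(rnorm(32 * 50), 32)
  out <- rereference_average(make_eeg(x, 100))
  expect_lt(max(abs(colMeans(out$signal))), 1e-12)
})

test_that("bad channels are rebuilt from their nearest neighbours", {
  labels <- montage_labels()
  n <- length(labels)
  x <- matrix(rnorm(n * 100), n)
  rec <- make_eeg(x, 100)
  # identity when nothing is bad
  expect_identical(interpolate_bad_channels(rec, character(0)), rec)
  # a bad channel whose 3 nearest good neighbours are constant c becomes c
  coords <- montage_coordinates()
  bi <- match("Pz", labels)
  pos <- as.matrix(coords[, c("x", "y", "z")])
  d <- sqrt(rowSums((pos - matrix(pos[bi, ], n, 3, byrow = TRUE))^2))
  near3 <- setdiff(order(d), bi)[1:3]
  rec$signal[near3, ] <- 4.2
  out <- interpolate_bad_channels(rec, "Pz")
  expect_equal(out$signal[bi, ], rep(4.2, 100), tolerance = 1e-12,
               ignore_attr = TRUE)
  # planted channel = mean of neighbours + noise is recovered below noise SD
  base <- sin(seq(0, 20, length.out = 500))
  sig <- matrix(rnorm(n * 500, sd = 0.2), n)
  sig <- sweep(sig, 2, base, `+`)
  noise_sd <- 0.5
  sig[bi, ] <- base + rnorm(500, sd = noise_sd)
  out2 <- interpolate_bad_channels(make_eeg(sig, 100), "Pz")
  err <- sqrt(mean((out2$signal[bi, ] - base)^2))
  expect_lt(err, noise_sd)
})

test_that("interpolation fails when too few good channels remain", {
  rec <- make_eeg(matrix(rnorm(300), 3), 100, c("Pz", "Cz", "Oz"))
  expect_error(interpolate_bad_channels(rec, c("Pz", "Cz")), "unrecoverable")
})

test_that("segment counts follow the block durations", {
  fs <- 250
  for (dur in c(8, 12)) {
    s <- structure(
      data.frame(condition = c("baseline", "social"), onset_s = c(10, 18),
                 duration_s = c(8, dur)),
      total_duration_s = 18 + dur + 8, class = c("stim_schedule", "data.frame"))
    s$sub_durations_s <- vector("list", 2)
    nt <- ceiling((18 + dur + 8) * fs)
    rec <- make_eeg(matrix(rnorm(2 * nt), 2), fs, c("Pz", "Cz"))
    seg <- segment_and_baseline(rec, s)
    bl <- seg$blocks[[1]]
    expect_identical(sum(bl$phase == "stimulus"), as.integer(dur))
    expect_identical(sum(bl$phase == "baseline"), 8L)
    # each segment holds exactly fs samples
    expect_identical(dim(bl$segments)[2], as.integer(fs))
  }
})

test_that("segments are built from 200 ms carryover plus 800 ms current", {
  fs <- 100
  total <- 30
  nt <- total * fs
  # signal equal to sample index so segment content is predictable
  rec <- make_eeg(matrix(seq_len(nt), 1), fs, "Pz")
  s <- structure(
    data.frame(condition = c("baseline", "social"), onset_s = c(2, 10),
               duration_s = c(8, 8)),
    total_duration_s = total, class = c("stim_schedule", "data.frame"))
  s$sub_durations_s <- vector("list", 2)
  seg <- segment_and_baseline(rec, s)
  bl <- seg$blocks[[1]]
  # second segment of the block: second [3,4) -> samples (3-0.2)*fs+1 ...
  raw <- seq_len(nt)[(2.8 * fs + 1):(3.8 * fs)]
  expect_equal(bl$segments[1, , 2], raw - mean(raw[1:(0.2 * fs)]),
               tolerance = 1e-9, ignore_attr = TRUE)
  # a constant segment is zeroed by the within-segment correction
  rec2 <- make_eeg(matrix(7, 1, nt), fs, "Pz")
  bl2 <- segment_and_baseline(rec2, s)$blocks[[1]]
  expect_true(all(abs(bl2$segments) < 1e-12))
})

test_that("a block running past the recording end drops partial segments", {
  fs <- 100
  s <- structure(
    data.frame(condition = c("baseline", "social"), onset_s = c(2, 10),
               duration_s = c(8, 12)),
    total_duration_s = 30, class = c("stim_schedule", "data.frame"))
  s$sub_durations_s <- vector("list", 2)
  rec <- make_eeg(matrix(rnorm(15 * fs), 1), fs, "Pz")  # ends at 15 s
  expect_warning(seg <- segment_and_baseline(rec, s), "past the recording")
  bl <- seg$blocks[[1]]
  expect_true(any(bl$reason == "truncated"))
})

test_that("amplitude rejection uses the 200 uV rule and conserves segments", {
  fs <- 100
  s <- structure(
    data.frame(condition = c("baseline", "social"), onset_s = c(2, 10),
               duration_s = c(8, 8)),
    total_duration_s = 26, class = c("stim_schedule", "data.frame"))
  s$sub_durations_s <- vector("list", 2)
  nt <- 26 * fs
  # 10 Hz carrier: segment means vanish, so the corrected amplitude is 150 uV
  x <- matrix(sin(2 * pi * 10 * seq_len(nt) / fs) * 150, 1)
  seg <- reject_artifact_segments(segment_and_baseline(make_eeg(x, fs, "Pz"), s))
  expect_true(all(!seg$blocks[[1]]$rejected))
  # plant a 250 uV excursion inside stimulus second 3
  x2 <- x
  x2[1, (12.3 * fs):(12.5 * fs)] <- 250
  seg2 <- reject_artifact_segments(segment_and_baseline(make_eeg(x2, fs, "Pz"), s))
  bl <- seg2$blocks[[1]]
  expect_true(any(bl$rejected & bl$reason == "amplitude"))
  # total = retained + rejected
  expect_identical(length(bl$rejected), 16L)
  expect_identical(sum(!bl$rejected) + sum(bl$rejected), 16L)
  # an infinite threshold rejects nothing
  seg3 <- reject_artifact_segments(segment_and_baseline(make_eeg(x2, fs, "Pz"), s),
                                   amp_threshold = Inf)
  expect_true(all(!seg3$blocks[[1]]$rejected))
})

test_that("band RMS of a 10 Hz, 10 uV sinusoid is 10/sqrt(2) in alpha only", {
  fs <- 500
  s <- structure(
    data.frame(condition = c("baseline", "social"), onset_s = c(10, 18),
               duration_s = c(8, 8)),
    total_duration_s = 34, class = c("stim_schedule", "data.frame"))
  s$sub_durations_s <- vector("list", 2)
  nt <- 34 * fs
  t <- (seq_len(nt) - 1) / fs
  rec <- make_eeg(matrix(10 * sin(2 * pi * 10 * t), 1), fs, "Pz")
  seg <- segment_and_baseline(rec, s)
  bp <- band_rms(seg)
  rms <- bp$blocks[[1]]$rms
  alpha <- rms[1, "alpha", ]
  expect_true(all(abs(alpha - 10 / sqrt(2)) / (10 / sqrt(2)) < 0.02))
  # neighbouring theta band sees almost nothing
  expect_true(all(rms[1, "theta", ] < 0.1 * alpha))
  # zero signal gives zero RMS everywhere
  rec0 <- make_eeg(matrix(0, 1, nt), fs, "Pz")
  bp0 <- band_rms(segment_and_baseline(rec0, s))
  expect_true(all(bp0$blocks[[1]]$rms == 0))
  # RMS is sign-invariant and non-negative
  recn <- make_eeg(matrix(-10 * sin(2 * pi * 10 * t), 1), fs, "Pz")
  bpn <- band_rms(segment_and_baseline(recn, s))
  expect_equal(bpn$blocks[[1]]$rms, rms, tolerance = 1e-9)
  expect_true(all(rms >= 0))
})

test_that("block baseline correction subtracts the final 2 s baseline mean", {
  # hand-built band_power: baseline RMS 2, stimulus RMS 5 -> corrected 3
  mk_block <- function(base_rms, stim_rms) {
    rms <- array(c(rep(base_rms, 8), rep(stim_rms, 8)), dim = c(1, 1, 16),
                 dimnames = list(NULL, "beta", NULL))
    list(condition = "social", onset_s = 0, rms = rms,
         phase = c(rep("baseline", 8), rep("stimulus", 8)),
         rejected = logical(16))
  }
  bp <- structure(list(blocks = list(mk_block(2, 5)),
                       bands = eeg_bands()[3, ], labels = "Pz"),
                  class = "band_power")
  avg <- block_baseline_correct_and_average(bp)
  expect_equal(as.numeric(avg$social$rms[1, 1, 9:16]), rep(3, 8))
  expect_equal(as.numeric(avg$social$rms[1, 1, 1:8]), rep(0, 8))
  # two blocks with corrected stimulus levels 1 and 3 average to 2
  bp2 <- structure(list(blocks = list(mk_block(0, 1), mk_block(0, 3)),
                        bands = eeg_bands()[3, ], labels = "Pz"),
                   class = "band_power")
  avg2 <- block_baseline_correct_and_average(bp2)
  expect_equal(as.numeric(avg2$social$rms[1, 1, 9:16]), rep(2, 8))
  expect_identical(avg2$social$n_blocks, 2L)
})

test_that("group EEG statistics match a hand computation and flag nulls", {
  # build subject responses directly: channel Pz carries a +1 social effect
  mk_resp <- function(effect) {
    rms <- array(0, dim = c(2, 1, 16), dimnames = list(NULL, "beta", NULL))
    rms[1, 1, 9:16] <- effect
    r <- list(social = list(rms = rms,
                            phase = c(rep("baseline", 8), rep("stimulus", 8)),
                            n_blocks = 3),
              `non-social` = list(rms = 0 * rms,
                                  phase = c(rep("baseline", 8),
                                            rep("stimulus", 8)),
                                  n_blocks = 3))
    attr(r, "bands") <- eeg_bands()[3, ]
    attr(r, "labels") <- c("Pz", "Cz")
    r
  }
  resp <- lapply(c(0.9, 1.0, 1.1, 1.05, 0.95), mk_resp)
  stats_tab <- eeg_condition_stats(resp)
  soc <- stats_tab[stats_tab$contrast == "social-baseline", ]
  pz <- soc[soc$channel == "Pz", ]
  x <- c(0.9, 1.0, 1.1, 1.05, 0.95)
  expect_equal(pz$t, mean(x) / (sd(x) / sqrt(5)), tolerance = 1e-9)
  expect_true(pz$sig)
  # Cz never deviates: zero-variance cell is NA-flagged, not significant
  cz <- soc[soc$channel == "Cz", ]
  expect_true(is.na(cz$t))
  expect_false(cz$sig)
  expect_error(eeg_condition_stats(resp[1:2]), "3 subjects")
})

test_that("planted Pz gain is detected across a synthetic cohort", {
  # EEG-only cohort: social beta gain at Pz, 8 subjects
  labels <- c("Pz", "C3", "O2")
  gains <- data.frame(channel = "Pz", band = "beta", condition = "social",
                      gain = 2)
  resp <- lapply(1:8, function(seed) {
    s <- generate_schedule(4, rng_seed = seed)
    eeg <- simulate_eeg(s, gains, fs = 250, channels = labels,
                        rng_seed = 100 + seed)
    f <- rereference_average(filter_eeg(eeg))
    bp <- band_rms(reject_artifact_segments(segment_and_baseline(f, s)),
                   bands2)
    block_baseline_correct_and_average(bp)
  })
  tab <- eeg_condition_stats(resp)
  cell <- tab[tab$channel == "Pz" & tab$band == "beta" &
                tab$contrast == "social-baseline", ]
  expect_true(cell$sig)
  expect_gt(cell$t, 0)
})
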