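# Shared fixtures, all generated in code.

# compact extinction table for fast forward/inverse round trips
ext16 <- synthetic_extinction(seq(780, 900, length.out = 16))

# low/high band subset used by the reduced cohort studies
bands2 <- eeg_bands()[eeg_bands()$band %in% c("theta", "beta"), ]

# a single-block epoch clock: stimulus onset at t = 0
single_block_events <- function(duration_s = 10) {
  data.frame(onset_s = 0, duration_s = duration_s)
}

# noise-free grand average generated from known basis parameters on a grid
make_grand_average <- function(params, time_s = seq(0, 24, by = 1.4),
                               duration_s = 10, scale = 0.7) {
  kern <- double_gamma(params, sample_period_s = time_s[2] - time_s[1])
  box <- as.numeric(time_s >= 0 & time_s < duration_s)
  conv_oracle(box, kern$kernel) * (time_s[2] - time_s[1]) * scale
}

# independent brute-force causal convolution oracle (naive double loop)
conv_oracle <- function(x, h) {
  n <- length(x)
  y <- numeric(n)
  for (t in seq_len(n)) {
    for (k in seq_len(min(t, length(h)))) {
      y[t] <- y[t] + h[k] * x[t - k + 1]
    }
  }
  y
}

# independent Benjamini-Hochberg step-up oracle: returns rejection logicals
bh_oracle <- function(p, q = 0.05) {
  m <- length(p)
  ord <- order(p)
  ps <- p[ord]
  below <- which(ps <= (seq_len(m) / m) * q)
  rej <- logical(m)
  if (length(below)) rej[ord[seq_len(max(below))]] <- TRUE
  rej
}

# planted-coupling cohort used by pipeline-level tests: the joint-analysis
# sample size (14), with the per-subject burden reduced (5 trials, 3 EEG
# channels, 250 Hz, 16 wavelengths)
planted_cohort <- function(seed, n_subjects = 14, gain = 2, amplitude = 1) {
  plant <- data.frame(bnirs_channel = 14, eeg_channel = "Pz", band = "beta",
                      condition = "social", amplitude_um = amplitude,
                      gain = gain)
  simulate_cohort(n_subjects = n_subjects, rng_seed = seed, n_trials = 5,
                  coupling = plant, fs = 250,
                  eeg_channels = c("Pz", "C3", "O2"),
                  chromophore_scale = c(1, 0, 0), extinction = ext16)
}

reduced_config <- function(...) {
  pipeline_config(bands = bands2, fit_hrf = FALSE, extinction = ext16, ...)
}
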