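# Synthetic multimodal data generator. Everything downstream is validated
# against cohorts built here, with known ground-truth coupling structure.

#' Simulate ground-truth chromophore concentration changes
#'
#' Each channel's trace is the superposition, over experimental blocks, of
#' `amplitude x (boxcar convolved with the chromophore's response kernel)`,
#' sampled on a uniform grid. This is the forward analogue of the GLM used in
#' the coupling analysis: a linear time-invariant response to the stimulus
#' boxcar.
#'
#' @param schedule A `stim_schedule` with at least one experimental block.
#' @param layout A `probe_layout`.
#' @param basis Named list of `basis_params` per chromophore
#'   (`HbO2`, `HHb`, `oxCCO`); see [basis_params()]. Defaults to the infant
#'   best-fit parameters (response delay 8 s Hb / 9 s oxCCO, undershoot 7 s,
#'   ratio 2 / 3).
#' @param amplitude Matrix (`n_channels` x 2, columns `social`, `non-social`)
#'   of peak response amplitudes in uM for HbO2; other chromophores are scaled
#'   by `chromophore_scale`.
#' @param chromophore_scale Length-3 multiplier (HbO2, HHb, oxCCO) applied to
#'   `amplitude`; the defaults give a canonical positive HbO2 response with a
#'   smaller HHb decrease and a small oxCCO increase.
#' @param sample_period_s Sampling period of the bNIRS grid in seconds
#'   (default 1.4, one multiplexing cycle).
#' @return A `chromo_ts`: list with `conc` (channel x chromophore x time, uM),
#'   `time_s`, `chromophores`, `excluded_channels`.
#' @export
simulate_chromophore_truth <- function(schedule, layout = probe_layout(),
                                       basis = infant_basis_defaults(),
                                       amplitude = NULL,
                                       chromophore_scale = c(1, -0.3, 0.15),
                                       sample_period_s = 1.4) {
  stop_if_not(sample_period_s > 0, "sample_period_s must be positive")
  blocks <- experimental_blocks(schedule)
  if (nrow(blocks) == 0) stop("schedule contains no experimental blocks",
                              call. = FALSE)
  n_ch <- layout$n_channels
  if (is.null(amplitude)) {
    amplitude <- matrix(0, n_ch, 2, dimnames = list(NULL, c("social", "non-social")))
  }
  stop_if_not(all(is.finite(amplitude)), "amplitudes must be finite")
  stop_if_not(nrow(amplitude) == n_ch && ncol(amplitude) == 2,
              "amplitude must be n_channels x 2 (social, non-social)")
  if (is.null(colnames(amplitude))) {
    colnames(amplitude) <- c("social", "non-social")
  }

  total <- attr(schedule, "total_duration_s")
  time_s <- seq(0, total, by = sample_period_s)
  nt <- length(time_s)
  conc <- array(0, dim = c(n_ch, 3, nt),
                dimnames = list(NULL, CHROMOPHORES, NULL))

  # per-(chromophore, condition) unit response on the grid, reused per channel
  for (ci in 1:3) {
    kern <- double_gamma(basis[[CHROMOPHORES[ci]]],
                         sample_period_s = sample_period_s)
    for (cond in c("social", "non-social")) {
      bl <- blocks[blocks$condition == cond, , drop = FALSE]
      if (nrow(bl) == 0) next
      unit <- boxcar_response(bl, time_s, kern$kernel, sample_period_s)
      for (ch in seq_len(n_ch)) {
        a <- amplitude[ch, cond] * chromophore_scale[ci]
        if (a != 0) conc[ch, ci, ] <- conc[ch, ci, ] + a * unit
      }
    }
  }
  structure(list(conc = conc, time_s = time_s, chromophores = CHROMOPHORES,
                 excluded_channels = integer(0)),
            class = "chromo_ts")
}

# Convolve a set of event boxcars with a sampled kernel on the `time_s` grid.
boxcar_response <- function(blocks, time_s, kernel, sample_period_s) {
  box <- numeric(length(time_s))
  for (i in seq_len(nrow(blocks))) {
    on <- blocks$onset_s[i]
    off <- on + blocks$duration_s[i]
    box[time_s >= on - 1e-9 & time_s < off - 1e-9] <- 1
  }
  conv_causal(box, kernel) * sample_period_s
}

#' Forward modified Beer-Lambert model: chromophores to broadband attenuation
#'
#' Generates a broadband recording whose attenuation change at each
#' (channel, wavelength, time) is
#' `sum_i eps_i(lambda) * dc_i(t) * d * DPF` plus Gaussian noise and optional
#' injected motion spikes (brief additive transients shared by all wavelengths
#' of a channel, emulating optode-coupling disturbances). Synthetic mean
#' detector intensity counts are attached for QC testing.
#'
#' @param truth A `chromo_ts` of ground-truth concentration changes (uM).
#' @param extinction An `extinction_table` covering the simulated wavelengths.
#' @param layout A `probe_layout`; `separation_cm` supplies the pathlength d.
#' @param dpf Differential pathlength factor (default 5.13).
#' @param noise_sd Gaussian noise SD in OD units.
#' @param spike_spec Optional list describing motion spikes:
#'   `rate_per_min` (expected spikes per minute per channel), `amplitude_od`,
#'   `width_s` (spike width <= 1 s).
#' @param counts Optional numeric vector of per-channel mean intensity counts;
#'   default draws plausible in-range values around 10,000.
#' @param rng_seed Integer seed.
#' @return A `bnirs_recording`: list with `attenuation`
#'   (channel x wavelength x time, OD change), `wavelengths_nm`, `time_s`,
#'   `intensity_counts`, `layout`.
#' @export
forward_attenuation <- function(truth, extinction, layout = probe_layout(),
                                dpf = 5.13, noise_sd = 0, spike_spec = NULL,
                                counts = NULL, rng_seed = 1L) {
  stop_if_not(dpf > 0, "dpf must be positive")
  stopifnot(inherits(truth, "chromo_ts"), inherits(extinction, "extinction_table"))
  n_ch <- dim(truth$conc)[1]
  nt <- dim(truth$conc)[3]
  wl <- extinction$wavelengths_nm
  set.seed(as.integer(rng_seed))
  d <- layout$separation_cm
  att <- array(0, dim = c(n_ch, length(wl), nt))
  for (ch in seq_len(n_ch)) {
    # (wavelength x time) = epsilon (wl x 3) %*% conc (3 x time) * d * dpf
    att[ch, , ] <- extinction$epsilon %*% truth$conc[ch, , ] * d * dpf
  }
  if (noise_sd > 0) {
    att <- att + stats::rnorm(length(att), sd = noise_sd)
  }
  if (!is.null(spike_spec)) {
    dt <- truth$time_s[2] - truth$time_s[1]
    width <- max(1L, round((spike_spec$width_s %||% 1) / dt))
    n_spikes <- stats::rpois(n_ch, (spike_spec$rate_per_min %||% 1) *
                               (max(truth$time_s) / 60))
    for (ch in seq_len(n_ch)) {
      if (n_spikes[ch] == 0) next
      starts <- sample.int(max(1L, nt - width), n_spikes[ch], replace = TRUE)
      for (s in starts) {
        idx <- s:min(nt, s + width - 1L)
        amp <- (spike_spec$amplitude_od %||% 0.5) * sample(c(-1, 1), 1)
        # half-sine transient, nonzero even for single-sample spikes,
        # shared across all wavelengths of the channel
        shape <- sin(pi * (seq_along(idx) - 0.5) / length(idx))
        att[ch, , idx] <- att[ch, , idx] + rep(amp * shape, each = length(wl))
      }
    }
  }
  if (is.null(counts)) {
    counts <- round(stats::rlnorm(n_ch, log(10000), 0.3))
  }
  stop_if_not(length(counts) == n_ch, "counts must have one entry per channel")
  structure(list(attenuation = att, wavelengths_nm = wl, time_s = truth$time_s,
                 intensity_counts = as.numeric(counts), layout = layout),
            class = "bnirs_recording")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Simulate a multichannel EEG recording with condition-locked band power
#'
#' Background is 1/f ("pink") noise per channel; on top, each (channel, band)
#' carries a narrowband oscillation at the band's centre frequency whose
#' amplitude during an experimental block is scaled by the ground-truth gain
#' for that (channel, band, condition) (gain 1 = baseline level). Optional
#' high-amplitude artifact segments (> 200 uV) and a Bernoulli inattention
#' mask at 1 s resolution emulate infant recording conditions.
#'
#' @param schedule A `stim_schedule`.
#' @param gains Data frame with columns `channel` (montage label), `band`,
#'   `condition`, `gain` (> 0). Unlisted combinations default to gain 1.
#' @param fs Sampling rate in Hz (default 500); must exceed twice the highest
#'   band edge.
#' @param channels Character vector of montage labels (default: the bundled
#'   32-electrode montage).
#' @param background_sd Pink-noise SD in uV.
#' @param osc_amp_uv Baseline oscillation amplitude in uV per band.
#' @param artifact_rate Probability that a 1 s segment receives an injected
#'   > 200 uV artifact (applied on one random channel).
#' @param inattention_prob Bernoulli probability that a 1 s segment is marked
#'   inattentive in the attention mask.
#' @param rng_seed Integer seed.
#' @return An `eeg_recording`: list with `signal` (channel x time, uV), `fs`,
#'   `labels`, `attention_mask` (logical, TRUE = attending, per 1 s segment).
#' @export
simulate_eeg <- function(schedule, gains = NULL, fs = 500,
                         channels = montage_labels(),
                         background_sd = 10, osc_amp_uv = 5,
                         artifact_rate = 0, inattention_prob = 0,
                         rng_seed = 1L) {
  bands <- eeg_bands()
  stop_if_not(fs > 2 * max(bands$high_hz),
              sprintf("fs = %g Hz is too low for the %g Hz band edge (aliasing)",
                      fs, max(bands$high_hz)))
  set.seed(as.integer(rng_seed))
  total <- attr(schedule, "total_duration_s")
  nt <- ceiling(total * fs)
  t <- (seq_len(nt) - 1) / fs
  n_ch <- length(channels)

  sig <- matrix(0, n_ch, nt)
  for (ch in seq_len(n_ch)) sig[ch, ] <- pink_noise(nt) * background_sd

  # condition gain lookup
  gain_of <- function(ch_label, band, cond) {
    if (is.null(gains)) return(1)
    hit <- gains$channel == ch_label & gains$band == band & gains$condition == cond
    if (any(hit)) gains$gain[which(hit)[1]] else 1
  }
  blocks <- experimental_blocks(schedule)
  centre <- sqrt(bands$low_hz * bands$high_hz)  # geometric band centre

  for (ch in seq_len(n_ch)) {
    for (bi in seq_len(nrow(bands))) {
      phase <- stats::runif(1, 0, 2 * pi)
      env <- rep(1, nt)
      for (k in seq_len(nrow(blocks))) {
        g <- gain_of(channels[ch], bands$band[bi], blocks$condition[k])
        stop_if_not(g > 0, "amplitude gains must be positive")
        if (g != 1) {
          idx <- t >= blocks$onset_s[k] & t < blocks$onset_s[k] + blocks$duration_s[k]
          env[idx] <- g
        }
      }
      sig[ch, ] <- sig[ch, ] +
        osc_amp_uv * env * sin(2 * pi * centre[bi] * t + phase)
    }
  }

  n_seg <- floor(total)
  if (artifact_rate > 0) {
    hit <- stats::runif(n_seg) < artifact_rate
    for (s in which(hit)) {
      ch <- sample.int(n_ch, 1)
      idx <- which(t >= s - 1 & t < s)
      sig[ch, idx] <- sig[ch, idx] +
        300 * sin(seq(0, pi, length.out = length(idx)))
    }
  }
  attention <- stats::runif(n_seg) >= inattention_prob

  structure(list(signal = sig, fs = fs, labels = channels,
                 attention_mask = attention),
            class = "eeg_recording")
}

# 1/f-shaped noise via spectral shaping of white noise, unit SD. The FFT runs
# on a highly composite padded length for speed; the result is truncated.
pink_noise <- function(n) {
  np <- stats::nextn(n, c(2, 3, 5))
  white <- stats::rnorm(np)
  spec <- stats::fft(white)
  f <- c(1, seq_len(np - 1))
  f <- pmin(f, np - f + 1)  # symmetric frequency index
  spec <- spec / sqrt(f)
  x <- Re(stats::fft(spec, inverse = TRUE))[seq_len(n)] / np
  (x - mean(x)) / stats::sd(x)
}

#' Bundled 32-electrode montage (10/20 labels with unit-sphere coordinates)
#'
#' @return Data frame with columns `label`, `x`, `y`, `z`.
#' @export
montage_coordinates <- function() {
  path <- system.file("extdata", "montage32_1020.csv", package = "bnirseeg")
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' @rdname montage_coordinates
#' @export
montage_labels <- function() montage_coordinates()$label

#' Infant best-fit response-function basis parameters
#'
#' The double-gamma basis parameters reconstructed for 4- to 7-month-old
#' infants: response delay 8 s for HbO2 and HHb, 9 s for oxCCO (2 s and 3 s
#' later than the 6 s adult canonical); undershoot delay 7 s (9 s earlier than
#' the 16 s adult canonical); response:undershoot ratio 2 for the haemoglobin
#' species and 3 for oxCCO.
#'
#' @return Named list of [basis_params()] per chromophore.
#' @export
infant_basis_defaults <- function() {
  list(HbO2 = basis_params(8, 7, 2),
       HHb = basis_params(8, 7, 2),
       oxCCO = basis_params(9, 7, 3))
}

#' Simulate one subject's complete multimodal session
#'
#' Convenience wrapper producing the schedule, ground-truth chromophores,
#' broadband recording and EEG for one subject, with optional planted
#' couplings: a planted coupling at (bNIRS channel, EEG channel, band,
#' chromophore, condition) means that channel's chromophore response and that
#' EEG channel's band gain are both driven by the same condition.
#'
#' @param n_trials Experimental blocks per session.
#' @param coupling Data frame of planted couplings with columns
#'   `bnirs_channel`, `eeg_channel`, `band`, `condition`, `amplitude_um`
#'   (HbO2 peak amplitude) and `gain` (EEG band gain); may be NULL (null
#'   cohort).
#' @param layout,extinction,basis,fs,eeg_channels,sample_period_s,noise_sd_od
#'   Forwarded to the stage generators.
#' @param eeg_noise_sd,osc_amp_uv,artifact_rate,inattention_prob Forwarded to
#'   [simulate_eeg()].
#' @param chromophore_scale See [simulate_chromophore_truth()].
#' @param rng_seed Integer seed (keep below 2^31).
#' @return List with `schedule`, `truth`, `bnirs`, `eeg`, `coupling`, `seed`.
#' @export
simulate_subject <- function(n_trials = 6, coupling = NULL,
                             layout = probe_layout(),
                             extinction = synthetic_extinction(),
                             basis = infant_basis_defaults(),
                             fs = 500, eeg_channels = montage_labels(),
                             sample_period_s = 1.4, noise_sd_od = 0.001,
                             eeg_noise_sd = 10, osc_amp_uv = 5,
                             artifact_rate = 0, inattention_prob = 0,
                             chromophore_scale = c(1, -0.3, 0.15),
                             rng_seed = 1L) {
  schedule <- generate_schedule(n_trials, rng_seed = rng_seed)
  amp <- matrix(0, layout$n_channels, 2,
                dimnames = list(NULL, c("social", "non-social")))
  gains <- NULL
  if (!is.null(coupling) && nrow(coupling)) {
    for (i in seq_len(nrow(coupling))) {
      amp[coupling$bnirs_channel[i], coupling$condition[i]] <-
        amp[coupling$bnirs_channel[i], coupling$condition[i]] +
        coupling$amplitude_um[i]
      stop_if_not(coupling$eeg_channel[i] %in% eeg_channels,
                  "planted coupling references an EEG channel not in the montage")
      stop_if_not(coupling$band[i] %in% eeg_bands()$band,
                  "planted coupling references an unknown band")
    }
    gains <- data.frame(channel = coupling$eeg_channel, band = coupling$band,
                        condition = coupling$condition, gain = coupling$gain)
  }
  truth <- simulate_chromophore_truth(schedule, layout, basis, amp,
                                      chromophore_scale = chromophore_scale,
                                      sample_period_s = sample_period_s)
  bnirs <- forward_attenuation(truth, extinction, layout,
                               noise_sd = noise_sd_od,
                               rng_seed = rng_seed + 10000L)
  eeg <- simulate_eeg(schedule, gains, fs = fs, channels = eeg_channels,
                      background_sd = eeg_noise_sd, osc_amp_uv = osc_amp_uv,
                      artifact_rate = artifact_rate,
                      inattention_prob = inattention_prob,
                      rng_seed = rng_seed + 20000L)
  list(schedule = schedule, truth = truth, bnirs = bnirs, eeg = eeg,
       coupling = coupling, seed = rng_seed)
}

#' Simulate a cohort of subjects
#'
#' @param n_subjects Number of subjects.
#' @param rng_seed Base seed; subject i uses `rng_seed + i`.
#' @param ... Forwarded to [simulate_subject()].
#' @return List of subject session lists.
#' @export
simulate_cohort <- function(n_subjects = 14, rng_seed = 1L, ...) {
  lapply(seq_len(n_subjects), function(i) {
    simulate_subject(rng_seed = as.integer(rng_seed) + i, ...)
  })
}
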