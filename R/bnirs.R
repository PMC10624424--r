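# Broadband-NIRS preprocessing: multiwavelength chromophore resolution,
# band-pass filtering, intensity-count QC and block averaging.

#' Construct a chromophore concentration time series
#'
#' @param conc Array (channel x 3 chromophores x time) of concentration
#'   changes in uM, chromophores ordered HbO2, HHb, oxCCO.
#' @param time_s Uniform time grid in seconds.
#' @param excluded_channels Integer channel indices excluded by QC.
#' @return A `chromo_ts`.
#' @export
chromophore_ts <- function(conc, time_s, excluded_channels = integer(0)) {
  stop_if_not(length(dim(conc)) == 3 && dim(conc)[2] == 3,
              "conc must be channel x 3 x time")
  stop_if_not(dim(conc)[3] == length(time_s),
              "time grid does not match conc")
  stop_if_not(all(is.finite(conc)), "concentrations must be finite")
  dimnames(conc) <- list(NULL, CHROMOPHORES, NULL)
  structure(list(conc = conc, time_s = as.numeric(time_s),
                 chromophores = CHROMOPHORES,
                 excluded_channels = as.integer(excluded_channels)),
            class = "chromo_ts")
}

#' Resolve chromophore concentration changes (UCLn multiwavelength inversion)
#'
#' Inverts the modified Beer-Lambert law over all wavelengths in the fit
#' range: per channel and time point, solves the least-squares system
#' `dA(lambda) = E(lambda) %*% dc * d * DPF` for the three chromophore
#' concentration changes (HbO2, HHb, oxCCO, in uM). The pathlength `d` is the
#' source-detector separation of the recording's layout; the differential
#' pathlength factor defaults to the age-appropriate fixed value 5.13. By
#' default the fit uses the wavelengths between 780 and 900 nm.
#'
#' Attenuation is in natural OD change; a log10-convention extinction table
#' only rescales the recovered concentrations by ln(10), it does not change
#' their time course.
#'
#' @param rec A `bnirs_recording`.
#' @param extinction An `extinction_table` tabulating every recorded
#'   wavelength inside the fit range.
#' @param dpf Differential pathlength factor (scalar, or a vector with one
#'   value per fit wavelength for a DPF(lambda) table).
#' @param fit_range_nm Length-2 wavelength window used for the fit.
#' @return A `chromo_ts` (channel x chromophore x time, uM).
#' @export
ucln_invert <- function(rec, extinction, dpf = 5.13,
                        fit_range_nm = c(780, 900)) {
  stopifnot(inherits(rec, "bnirs_recording"))
  in_range <- rec$wavelengths_nm >= fit_range_nm[1] &
    rec$wavelengths_nm <= fit_range_nm[2]
  if (sum(in_range) < 3) {
    stop("need at least 3 wavelengths inside the fit range", call. = FALSE)
  }
  wl <- rec$wavelengths_nm[in_range]
  ext <- subset_extinction(extinction, wl)
  stop_if_not(length(dpf) == 1 || length(dpf) == length(wl),
              "dpf must be scalar or one value per fit wavelength")
  stop_if_not(all(dpf > 0), "dpf must be positive")
  d <- rec$layout$separation_cm
  M <- ext$epsilon * (d * dpf)  # recycles DPF(lambda) down the rows
  if (qr(M)$rank < 3) {
    stop("extinction submatrix over the fit range is rank-deficient",
         call. = FALSE)
  }
  MtM <- crossprod(M)
  n_ch <- dim(rec$attenuation)[1]
  nt <- dim(rec$attenuation)[3]
  conc <- array(0, dim = c(n_ch, 3, nt),
                dimnames = list(NULL, CHROMOPHORES, NULL))
  for (ch in seq_len(n_ch)) {
    A <- rec$attenuation[ch, in_range, , drop = TRUE]
    if (is.null(dim(A))) A <- matrix(A, nrow = sum(in_range))
    conc[ch, , ] <- solve(MtM, crossprod(M, A))
  }
  structure(list(conc = conc, time_s = rec$time_s, chromophores = CHROMOPHORES,
                 excluded_channels = integer(0)),
            class = "chromo_ts")
}

#' Band-pass filter chromophore time series
#'
#' Zero-phase (forward-backward) Butterworth band-pass, default fourth order
#' from 0.01 to 0.4 Hz, applied per channel and chromophore. If the upper
#' edge reaches the Nyquist frequency of the sampling grid (as 0.4 Hz does at
#' the 1.4 s multiplexing period, Nyquist ~0.357 Hz), it is clamped just
#' below Nyquist with a warning rather than guessing a faster acquisition
#' rate.
#'
#' @param ts A `chromo_ts`.
#' @param low_hz,high_hz Band edges in Hz.
#' @param order Butterworth design order (the `n` of MATLAB-style
#'   `butter(n, ...)`; default 4).
#' @return A `chromo_ts` on the same grid.
#' @export
bandpass_bnirs <- function(ts, low_hz = 0.01, high_hz = 0.4, order = 4) {
  stopifnot(inherits(ts, "chromo_ts"))
  stop_if_not(order >= 1, "order must be a positive count")
  fs <- 1 / (ts$time_s[2] - ts$time_s[1])
  nyq <- fs / 2
  stop_if_not(low_hz > 0 && high_hz > low_hz, "need 0 < low_hz < high_hz")
  if (high_hz >= nyq) {
    high_hz <- 0.95 * nyq
    warning(sprintf(
      "upper band edge clamped to %.3f Hz (Nyquist %.3f Hz at fs %.3f Hz)",
      high_hz, nyq, fs), call. = FALSE)
    if (high_hz <= low_hz) stop("band collapsed after Nyquist clamping",
                                call. = FALSE)
  }
  bf <- signal::butter(order, c(low_hz, high_hz) / nyq, type = "pass")
  for (ch in seq_len(dim(ts$conc)[1])) {
    for (ci in 1:3) {
      ts$conc[ch, ci, ] <- zp_filter(bf, ts$conc[ch, ci, ])
    }
  }
  ts
}

#' Intensity-count channel quality control
#'
#' Flags channels whose mean detector intensity counts fall below
#' `low_counts` or above `high_counts`; the subject is excluded when the
#' excluded fraction exceeds `subject_threshold` (default more than 60% of
#' channels).
#'
#' @param rec A `bnirs_recording` carrying per-channel `intensity_counts`.
#' @param low_counts,high_counts Count bounds (defaults 2000 and 40000).
#' @param subject_threshold Exclusion fraction above which the subject is
#'   dropped (default 0.60).
#' @return A `channel_qc` list: data frame `channels` (channel, mean_counts,
#'   keep), `excluded_channels`, `exclusion_fraction`, `subject_excluded`.
#' @export
qc_channels <- function(rec, low_counts = 2000, high_counts = 40000,
                        subject_threshold = 0.60) {
  counts <- rec$intensity_counts
  stop_if_not(!is.null(counts) && all(is.finite(counts)),
              "recording lacks intensity counts")
  keep <- counts >= low_counts & counts <= high_counts
  frac <- mean(!keep)
  structure(list(
    channels = data.frame(channel = seq_along(counts), mean_counts = counts,
                          keep = keep),
    excluded_channels = which(!keep),
    exclusion_fraction = frac,
    subject_excluded = frac > subject_threshold
  ), class = "channel_qc")
}

#' Block-average chromophore responses for one condition
#'
#' Epochs the concentration time series around each experimental block of the
#' requested condition (a pre-onset baseline span plus `window_s` seconds
#' after onset) and averages across blocks.
#'
#' @param ts A `chromo_ts`.
#' @param schedule A `stim_schedule`.
#' @param condition `"social"` or `"non-social"`.
#' @param window_s Post-onset window length in seconds (default 20).
#' @param baseline_s Pre-onset span included in the epoch (default 8).
#' @return List with `mean` (channel x chromophore x epoch-sample), `time_s`
#'   (epoch times relative to onset, baseline negative), `n_blocks`.
#' @export
block_average_bnirs <- function(ts, schedule, condition, window_s = 20,
                                baseline_s = 8) {
  stopifnot(inherits(ts, "chromo_ts"))
  blocks <- experimental_blocks(schedule, condition)
  dt <- ts$time_s[2] - ts$time_s[1]
  n_pre <- floor(baseline_s / dt)
  n_post <- floor(window_s / dt)
  usable <- 0L
  acc <- NULL
  for (i in seq_len(nrow(blocks))) {
    i0 <- which.min(abs(ts$time_s - blocks$onset_s[i]))
    idx <- (i0 - n_pre):(i0 + n_post)
    if (idx[1] < 1 || idx[length(idx)] > length(ts$time_s)) next
    ep <- ts$conc[, , idx, drop = FALSE]
    acc <- if (is.null(acc)) ep else acc + ep
    usable <- usable + 1L
  }
  if (usable == 0L) {
    stop(sprintf("no usable '%s' blocks inside the recording", condition),
         call. = FALSE)
  }
  list(mean = acc / usable,
       time_s = seq(-n_pre, n_post) * dt,
       n_blocks = usable)
}

#' Write a channel QC report as TSV
#' @param qc A `channel_qc`.
#' @param path Output file.
#' @export
write_qc_report <- function(qc, path) {
  utils::write.table(qc$channels, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}
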