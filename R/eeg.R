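# EEG preprocessing: filtering, re-referencing, bad-channel interpolation,
# segmentation with two-stage baseline correction, artifact rejection, band
# RMS power and channel-level condition statistics.

#' Band-pass and notch filter an EEG recording
#'
#' Zero-phase Butterworth band-pass (default 0.1-100 Hz) followed by a
#' band-stop notch (default 48-52 Hz) to remove line noise, per channel.
#'
#' @param rec An `eeg_recording`.
#' @param band Length-2 pass band in Hz.
#' @param notch Length-2 stop band in Hz (NULL to skip).
#' @param order Butterworth design order of both filters (default 2).
#' @return Filtered `eeg_recording`.
#' @export
filter_eeg <- function(rec, band = c(0.1, 100), notch = c(48, 52), order = 2) {
  stopifnot(inherits(rec, "eeg_recording"))
  nyq <- rec$fs / 2
  stop_if_not(band[2] < nyq,
              sprintf("upper band edge %g Hz must be below Nyquist %g Hz",
                      band[2], nyq))
  bp <- signal::butter(order, band / nyq, type = "pass")
  bs <- if (!is.null(notch)) signal::butter(order, notch / nyq, type = "stop")
  for (ch in seq_len(nrow(rec$signal))) {
    x <- zp_filter(bp, rec$signal[ch, ])
    if (!is.null(notch)) x <- zp_filter(bs, x)
    rec$signal[ch, ] <- x
  }
  rec
}

#' Re-reference an EEG recording to the average reference
#'
#' Subtracts the instantaneous mean across channels from every channel, so
#' the montage mean is zero at each sample.
#'
#' @param rec An `eeg_recording` with at least 2 channels.
#' @return Re-referenced `eeg_recording`.
#' @export
rereference_average <- function(rec) {
  stopifnot(inherits(rec, "eeg_recording"))
  stop_if_not(nrow(rec$signal) >= 2, "average reference needs >= 2 channels")
  rec$signal <- sweep(rec$signal, 2, colMeans(rec$signal))
  rec
}

#' Detect channels with excessive artifact load
#'
#' A channel is flagged bad when more than `segment_fraction` of its 1 s
#' segments exceed `amp_threshold` uV in absolute amplitude.
#'
#' @param rec An `eeg_recording`.
#' @param amp_threshold Amplitude threshold in uV (default 200).
#' @param segment_fraction Fraction of offending segments above which the
#'   channel is flagged (default 0.30).
#' @return Character vector of bad channel labels.
#' @export
detect_bad_channels <- function(rec, amp_threshold = 200,
                                segment_fraction = 0.30) {
  n_seg <- floor(ncol(rec$signal) / rec$fs)
  if (n_seg == 0) return(character(0))
  bad <- vapply(seq_len(nrow(rec$signal)), function(ch) {
    over <- vapply(seq_len(n_seg), function(s) {
      idx <- ((s - 1) * rec$fs + 1):(s * rec$fs)
      max(abs(rec$signal[ch, idx])) > amp_threshold
    }, logical(1))
    mean(over) > segment_fraction
  }, logical(1))
  rec$labels[bad]
}

#' Interpolate bad EEG channels from their neighbours
#'
#' Replaces each bad channel with the inverse-distance-weighted mean of its
#' `k` nearest good channels, using the bundled montage coordinates.
#'
#' @param rec An `eeg_recording`.
#' @param bad Character vector of bad channel labels (subset of the montage).
#' @param k Number of nearest good neighbours used (default 3).
#' @param coords Montage coordinate table (default [montage_coordinates()]).
#' @return `eeg_recording` with bad channels replaced.
#' @export
interpolate_bad_channels <- function(rec, bad, k = 3,
                                     coords = montage_coordinates()) {
  stopifnot(inherits(rec, "eeg_recording"))
  if (length(bad) == 0) return(rec)
  stop_if_not(all(bad %in% rec$labels), "bad channels must be in the montage")
  good <- setdiff(rec$labels, bad)
  if (length(good) < k) {
    stop("unrecoverable recording: fewer good channels than neighbours needed",
         call. = FALSE)
  }
  pos <- coords[match(rec$labels, coords$label), c("x", "y", "z")]
  for (b in bad) {
    bi <- match(b, rec$labels)
    gi <- match(good, rec$labels)
    dists <- sqrt(rowSums((pos[gi, , drop = FALSE] -
                             matrix(unlist(pos[bi, ]), length(gi), 3,
                                    byrow = TRUE))^2))
    ord <- order(dists)[seq_len(k)]
    w <- 1 / pmax(dists[ord], 1e-9)
    w <- w / sum(w)
    rec$signal[bi, ] <- drop(w %*% rec$signal[gi[ord], , drop = FALSE])
  }
  rec
}

#' Segment an EEG recording into overlapping 1 s segments per block
#'
#' Each block spans the baseline period preceding a stimulus presentation
#' plus the full stimulus period. Every second of the block yields one
#' segment of exactly `fs` samples composed of the last 200 ms of the
#' previous second plus the first 800 ms of the current second; the mean of
#' the leading 200 ms is subtracted from the whole segment (within-segment
#' baseline correction). Segments overlapping inattentive spans of the
#' recording's attention mask are flagged removed. An 8-12 s presentation
#' yields 8-12 stimulus segments.
#'
#' @param rec An `eeg_recording`.
#' @param schedule A `stim_schedule` lying inside the recording span.
#' @return A `segmented_blocks` list: one entry per (baseline + stimulus)
#'   block with fields `condition`, `onset_s`, `segments` (channel x sample x
#'   segment array), `phase` (`"baseline"`/`"stimulus"` per segment),
#'   `rejected` (logical), `reason` (character).
#' @export
segment_and_baseline <- function(rec, schedule) {
  stopifnot(inherits(rec, "eeg_recording"))
  fs <- rec$fs
  n <- ncol(rec$signal)
  lead <- round(0.2 * fs)
  exper <- which(schedule$condition != "baseline")
  blocks <- list()
  for (e in exper) {
    # the baseline block immediately preceding this stimulus
    b <- if (e > 1 && schedule$condition[e - 1] == "baseline") e - 1L else NA
    base_on <- if (is.na(b)) schedule$onset_s[e] else schedule$onset_s[b]
    base_dur <- if (is.na(b)) 0 else schedule$duration_s[b]
    stim_on <- schedule$onset_s[e]
    stim_dur <- schedule$duration_s[e]
    n_base <- floor(base_dur)
    n_stim <- floor(stim_dur)
    n_seg <- n_base + n_stim
    if (n_seg == 0) next
    segs <- array(NA_real_, dim = c(nrow(rec$signal), fs, n_seg))
    phase <- c(rep("baseline", n_base), rep("stimulus", n_stim))
    rejected <- logical(n_seg)
    reason <- character(n_seg)
    start_idx <- integer(n_seg)
    truncated <- FALSE
    for (s in seq_len(n_seg)) {
      sec_start <- base_on + (s - 1)      # start of this segment's second
      i0 <- round(sec_start * fs) - lead + 1L
      i1 <- i0 + fs - 1L
      start_idx[s] <- i0
      if (i0 < 1 || i1 > n) {
        rejected[s] <- TRUE
        reason[s] <- "truncated"
        truncated <- TRUE
        next
      }
      seg <- rec$signal[, i0:i1, drop = FALSE]
      # within-segment baseline correction: subtract leading 200 ms mean
      seg <- seg - rowMeans(seg[, seq_len(lead), drop = FALSE])
      segs[, , s] <- seg
      # attention mask is per 1 s segment of the whole recording
      if (!is.null(rec$attention_mask)) {
        covered <- unique(pmax(1L, pmin(length(rec$attention_mask),
                                        c(floor(sec_start - 0.2) + 1L,
                                          floor(sec_start) + 1L))))
        if (any(!rec$attention_mask[covered])) {
          rejected[s] <- TRUE
          reason[s] <- "inattention"
        }
      }
    }
    if (truncated) {
      warning("block extends past the recording end; partial segments dropped",
              call. = FALSE)
    }
    blocks[[length(blocks) + 1]] <- list(
      condition = schedule$condition[e], onset_s = stim_on,
      baseline_s = base_dur, segments = segs, phase = phase,
      rejected = rejected, reason = reason, start_idx = start_idx)
  }
  structure(list(blocks = blocks, fs = fs, labels = rec$labels,
                 signal = rec$signal),
            class = "segmented_blocks")
}

#' Reject high-amplitude artifact segments
#'
#' Flags any segment whose absolute amplitude exceeds `amp_threshold` on any
#' channel. Previously flagged segments stay flagged.
#'
#' @param seg A `segmented_blocks`.
#' @param amp_threshold Amplitude threshold in uV (default 200).
#' @return `segmented_blocks` with updated rejection flags; attribute
#'   `n_retained` counts surviving segments. A warning names blocks left with
#'   zero retained segments.
#' @export
reject_artifact_segments <- function(seg, amp_threshold = 200) {
  stopifnot(inherits(seg, "segmented_blocks"))
  for (i in seq_along(seg$blocks)) {
    bl <- seg$blocks[[i]]
    for (s in seq_along(bl$rejected)) {
      if (bl$rejected[s]) next
      if (max(abs(bl$segments[, , s])) > amp_threshold) {
        bl$rejected[s] <- TRUE
        bl$reason[s] <- "amplitude"
      }
    }
    if (all(bl$rejected)) {
      warning(sprintf("block %d (%s): zero segments retained; block dropped",
                      i, bl$condition), call. = FALSE)
    }
    seg$blocks[[i]] <- bl
  }
  attr(seg, "n_retained") <- sum(vapply(seg$blocks,
                                        function(b) sum(!b$rejected), numeric(1)))
  seg
}

#' Band-limited RMS power per 1 s segment
#'
#' For each retained segment, channel and frequency band: zero-phase
#' fourth-order Butterworth band-pass filtering followed by the RMS amplitude
#' over the segment's unique 800 ms portion. The band filter is applied to
#' the continuous per-channel record before windowing (equivalent for these
#' bands, since the within-segment DC correction carries no band-limited
#' power, and free of 1 s window edge transients). Rejected segments yield
#' NA.
#'
#' @param seg A `segmented_blocks`.
#' @param bands Band definition data frame (default [eeg_bands()]).
#' @return A `band_power` list: per block, `rms` array (channel x band x
#'   segment, uV), plus the block metadata.
#' @export
band_rms <- function(seg, bands = eeg_bands()) {
  stopifnot(inherits(seg, "segmented_blocks"))
  fs <- seg$fs
  nyq <- fs / 2
  stop_if_not(max(bands$high_hz) < nyq,
              "a band edge reaches Nyquist; raise fs or drop the band")
  lead <- round(0.2 * fs)
  n_ch <- nrow(seg$signal)
  n <- ncol(seg$signal)
  # continuous band-filtered copies of every channel, one per band
  filtered <- lapply(seq_len(nrow(bands)), function(bi) {
    bf <- signal::butter(2, c(bands$low_hz[bi], bands$high_hz[bi]) / nyq,
                         type = "pass")
    t(vapply(seq_len(n_ch), function(ch) zp_filter(bf, seg$signal[ch, ]),
             numeric(n)))
  })
  blocks <- lapply(seg$blocks, function(bl) {
    n_seg <- dim(bl$segments)[3]
    rms <- array(NA_real_, dim = c(n_ch, nrow(bands), n_seg),
                 dimnames = list(NULL, bands$band, NULL))
    for (s in seq_len(n_seg)) {
      if (bl$rejected[s]) next
      # unique 800 ms portion of the segment in continuous-record indices
      u0 <- bl$start_idx[s] + lead
      u1 <- bl$start_idx[s] + fs - 1L
      for (bi in seq_len(nrow(bands))) {
        x <- filtered[[bi]][, u0:u1, drop = FALSE]
        rms[, bi, s] <- sqrt(rowMeans(x^2))
      }
    }
    list(condition = bl$condition, onset_s = bl$onset_s, rms = rms,
         phase = bl$phase, rejected = bl$rejected)
  })
  structure(list(blocks = blocks, bands = bands, labels = seg$labels),
            class = "band_power")
}

#' Block baseline correction and trial averaging of band RMS power
#'
#' Subtracts from each block's RMS sequence the mean over the final 2 s of
#' that block's baseline period (block baseline correction), then averages
#' blocks across trials per condition. Blocks are aligned on stimulus onset;
#' the averaged output keeps `baseline_keep_s` baseline seconds and the first
#' `stimulus_keep_s` seconds of the stimulus period (default 8 s, the portion
#' carried into the coupling GLM).
#'
#' @param bp A `band_power`.
#' @param baseline_keep_s,stimulus_keep_s Segments retained in the average.
#' @return List with one entry per condition: `rms` (channel x band x
#'   segment), `phase`, `n_blocks`.
#' @export
block_baseline_correct_and_average <- function(bp, baseline_keep_s = 8,
                                               stimulus_keep_s = 8) {
  stopifnot(inherits(bp, "band_power"))
  out <- list()
  for (cond in c("social", "non-social")) {
    bls <- Filter(function(b) b$condition == cond && !all(b$rejected), bp$blocks)
    if (!length(bls)) next
    n_ch <- dim(bls[[1]]$rms)[1]
    n_band <- dim(bls[[1]]$rms)[2]
    n_out <- baseline_keep_s + stimulus_keep_s
    dn <- list(NULL, dimnames(bls[[1]]$rms)[[2]], NULL)
    acc <- array(0, dim = c(n_ch, n_band, n_out), dimnames = dn)
    cnt <- array(0, dim = c(n_ch, n_band, n_out))
    for (bl in bls) {
      base_idx <- which(bl$phase == "baseline")
      stim_idx <- which(bl$phase == "stimulus")
      if (length(stim_idx) == 0 || length(base_idx) == 0) next
      # block baseline: mean over the final 2 s of the baseline period
      tail2 <- utils::tail(base_idx, 2)
      baseval <- apply(bl$rms[, , tail2, drop = FALSE], c(1, 2), mean,
                       na.rm = TRUE)
      corrected <- sweep(bl$rms, c(1, 2), baseval)
      keep <- c(utils::tail(base_idx, baseline_keep_s),
                utils::head(stim_idx, stimulus_keep_s))
      # left-pad if the block has fewer baseline segments than requested
      sel <- array(NA_real_, dim = c(n_ch, n_band, n_out))
      off <- n_out - length(keep)
      sel[, , (off + 1):n_out] <- corrected[, , keep, drop = FALSE]
      ok <- !is.na(sel)
      acc[ok] <- acc[ok] + sel[ok]
      cnt <- cnt + ok
    }
    mean_rms <- acc / pmax(cnt, 1)
    mean_rms[cnt == 0] <- NA_real_
    out[[cond]] <- list(
      rms = mean_rms,
      phase = c(rep("baseline", baseline_keep_s),
                rep("stimulus", stimulus_keep_s)),
      n_blocks = length(bls))
  }
  if (!length(out)) stop("no usable blocks for any condition", call. = FALSE)
  attr(out, "bands") <- bp$bands
  attr(out, "labels") <- bp$labels
  out
}

#' Group-level EEG condition statistics
#'
#' Paired t-tests across subjects on stimulus-period-averaged RMS power, per
#' channel and band, for the three contrasts social-baseline,
#' nonsocial-baseline and social-nonsocial, with Benjamini-Hochberg FDR
#' correction across the montage channels within each (band, contrast)
#' family.
#'
#' @param subject_responses List (one per subject) of the per-condition
#'   averaged responses returned by [block_baseline_correct_and_average()].
#' @param alpha Significance level (default 0.05).
#' @return Data frame with columns `channel`, `band`, `contrast`, `t`, `p`,
#'   `q`, `sig`, `sig_fdr`. Zero-variance cells carry NA t/p.
#' @export
eeg_condition_stats <- function(subject_responses, alpha = 0.05) {
  stop_if_not(length(subject_responses) >= 3, "need at least 3 subjects")
  bands <- attr(subject_responses[[1]], "bands")
  labels <- attr(subject_responses[[1]], "labels")
  n_ch <- length(labels)
  # per subject x channel x band: mean RMS over stimulus and baseline phases
  summarise <- function(resp, cond, phase) {
    if (is.null(resp[[cond]])) return(matrix(NA_real_, n_ch, nrow(bands)))
    idx <- which(resp[[cond]]$phase == phase)
    apply(resp[[cond]]$rms[, , idx, drop = FALSE], c(1, 2), mean, na.rm = TRUE)
  }
  n_sub <- length(subject_responses)
  arr <- function(cond, phase) {
    a <- vapply(subject_responses, summarise, matrix(0, n_ch, nrow(bands)),
                cond = cond, phase = phase)
    array(a, dim = c(n_ch, nrow(bands), n_sub))
  }
  soc_stim <- arr("social", "stimulus"); soc_base <- arr("social", "baseline")
  non_stim <- arr("non-social", "stimulus"); non_base <- arr("non-social", "baseline")
  contrasts <- list(
    "social-baseline" = soc_stim - soc_base,
    "nonsocial-baseline" = non_stim - non_base,
    "social-nonsocial" = soc_stim - non_stim)
  rows <- list()
  for (cn in names(contrasts)) {
    for (bi in seq_len(nrow(bands))) {
      tp <- lapply(seq_len(n_ch), function(ch) {
        t_one_sample(contrasts[[cn]][ch, bi, ])
      })
      p <- vapply(tp, `[[`, numeric(1), "p")
      q <- bh_adjust(p)
      rows[[length(rows) + 1]] <- data.frame(
        channel = labels, band = bands$band[bi], contrast = cn,
        t = vapply(tp, `[[`, numeric(1), "t"), p = p, q = q,
        sig = !is.na(p) & p < alpha, sig_fdr = !is.na(q) & q < alpha,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
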