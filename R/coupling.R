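# Neurovascular / neurometabolic coupling: neural regressors from EEG band
# RMS power and the reconstructed response functions, subject-level GLMs on
# bNIRS block-averaged responses, and FDR-corrected group statistics.

#' Select bNIRS channels for the coupling analysis
#'
#' The coupling analysis is restricted to the channels that showed
#' significant haemodynamic-metabolic coupling in any condition or
#' chromophore; for consistency the same channel set is used everywhere, so
#' the selection is the sorted union of all the per-(condition, chromophore)
#' channel lists.
#'
#' @param per_condition_lists List (arbitrarily nested) of integer channel
#'   vectors, e.g. `list(social = list(HbO2 = c(12,13,14), ...), ...)`.
#' @return Sorted integer vector of selected channels.
#' @export
select_coupling_channels <- function(per_condition_lists) {
  sets <- unlist(per_condition_lists, use.names = FALSE)
  sort(unique(as.integer(sets)))
}

#' Haemodynamic-metabolic coupling channel lists
#'
#' The per-condition, per-chromophore channel lists from the prior
#' haemodynamic-metabolic coupling analysis of this infant cohort, consumed
#' here as printed inputs (the coupling metric itself is not re-derived).
#' Their union is channels 11, 12, 13, 14, 16 and 18.
#'
#' @return Nested list `condition -> chromophore -> integer channels`.
#' @export
reported_coupling_channels <- function() {
  list(
    social = list(HbO2 = c(12, 13, 14), HHb = c(11, 12, 14, 18),
                  oxCCO = c(11, 12, 13, 14, 18)),
    `non-social` = list(HbO2 = c(12, 14), HHb = c(12, 14, 16),
                        oxCCO = c(12, 14, 16))
  )
}

#' Build the neural regressor for one (EEG channel, band, condition) cell
#'
#' Implements the double convolution: the response-function kernel is
#' convolved with the stimulus events to obtain the "predicted" bNIRS signal
#' on a 1 s working grid; the predicted signal is then convolved with the
#' stimulus-period EEG RMS power block (causal, same-length, onset-anchored)
#' and linearly interpolated onto the bNIRS stimulus-period grid, then
#' z-scored. An alternative conventional construction (RMS block convolved
#' directly with the kernel) is available via `mode = "rms_conv_kernel"` for
#' sensitivity analysis.
#'
#' @param rf A `response_function` (1 s sampling).
#' @param rms_block Numeric stimulus-period RMS power block at 1 s resolution
#'   (typically 8 values).
#' @param bnirs_time Time grid (seconds from stimulus onset) of the bNIRS
#'   window the regressor must match.
#' @param stim_duration_s Modelled stimulus duration in seconds (default the
#'   length of `rms_block`).
#' @param mode Construction variant (see above).
#' @return Z-scored numeric regressor of `length(bnirs_time)`.
#' @export
build_neural_regressor <- function(rf, rms_block, bnirs_time,
                                   stim_duration_s = length(rms_block),
                                   mode = c("predicted_conv_rms",
                                            "rms_conv_kernel")) {
  mode <- match.arg(mode)
  stopifnot(inherits(rf, "response_function"))
  if (all(rms_block == 0)) {
    stop("degenerate regressor: RMS power block is identically zero",
         call. = FALSE)
  }
  # 1 s working grid spanning the bNIRS window
  work_t <- seq(0, max(ceiling(max(bnirs_time)), length(rms_block)) , by = 1)
  kern <- if (rf$sample_period_s == 1) rf$kernel else {
    stats::approx(rf$time_s, rf$kernel, xout = seq(0, max(rf$time_s), by = 1),
                  rule = 2)$y
  }
  box <- as.numeric(work_t >= 0 & work_t < stim_duration_s)
  predicted <- conv_causal(box, kern)
  series <- switch(mode,
    predicted_conv_rms = conv_causal(predicted, rms_block),
    rms_conv_kernel = conv_causal(c(rms_block,
                                    numeric(length(work_t) - length(rms_block))),
                                  kern))
  on_grid <- stats::approx(work_t, series, xout = bnirs_time, rule = 2)$y
  zscore(on_grid)
}

#' Subject-level coupling GLM for one design
#'
#' Ordinary least squares of a bNIRS trace on an intercept plus one or more
#' neural regressors. With a single regressor this is the per-cell fit of the
#' spec examples; with two condition-specific regressors (each zero outside
#' its condition's span) it is the joint both-conditions fit used by the
#' pipeline.
#'
#' @param bnirs_trace Numeric response vector.
#' @param regressors Numeric vector or matrix (one column per regressor).
#' @return List with `beta` (named per regressor), `residual_var`,
#'   `condition_number` of the design matrix.
#' @export
fit_subject_glm <- function(bnirs_trace, regressors) {
  X <- cbind(intercept = 1, as.matrix(regressors))
  stop_if_not(nrow(X) == length(bnirs_trace),
              "trace and regressor lengths differ")
  kap <- kappa(X, exact = TRUE)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    stop("degenerate design: collinear regressors", call. = FALSE)
  }
  fit <- qr.coef(qrX, bnirs_trace)
  res <- bnirs_trace - X %*% fit
  list(beta = fit[-1], residual_var = sum(res^2) / max(1, nrow(X) - ncol(X)),
       condition_number = kap)
}

#' Subject-level coupling betas across all cells
#'
#' For one subject: builds, per (EEG channel, band), the condition-specific
#' neural regressors from the subject's averaged stimulus-period RMS blocks,
#' concatenates the social and non-social block-averaged bNIRS windows, and
#' fits the joint GLM per (bNIRS channel, chromophore), yielding a beta per
#' condition.
#'
#' @param bnirs_avg Named list (`social`, `non-social`) of block averages
#'   from [block_average_bnirs()] restricted later to `stimulus_keep_s`.
#' @param eeg_avg Per-condition averaged band RMS from
#'   [block_baseline_correct_and_average()].
#' @param rf_list Named list of `response_function`s per chromophore.
#' @param channels Integer vector of bNIRS channels to fit.
#' @param eeg_channels Character vector of EEG channels (default all in
#'   `eeg_avg`).
#' @param bands Character vector of band names (default all).
#' @param stimulus_keep_s Stimulus-period window length entered in the GLM
#'   (default 8 s).
#' @param subject_id Identifier attached to the result rows.
#' @return Data frame with one row per (bNIRS channel, chromophore, EEG
#'   channel, band, condition): `beta`, plus metadata.
#' @export
subject_coupling <- function(bnirs_avg, eeg_avg, rf_list = infant_rf(),
                             channels, eeg_channels = NULL, bands = NULL,
                             stimulus_keep_s = 8, subject_id = NA) {
  band_tab <- attr(eeg_avg, "bands")
  labels <- attr(eeg_avg, "labels")
  if (is.null(eeg_channels)) eeg_channels <- labels
  if (is.null(bands)) bands <- band_tab$band
  conds <- intersect(c("social", "non-social"), names(eeg_avg))
  stop_if_not(length(conds) >= 1, "subject has no usable condition")

  # bNIRS stimulus-period windows per condition (channel x chromo x time)
  windows <- lapply(conds, function(cond) {
    ba <- bnirs_avg[[cond]]
    idx <- ba$time_s >= 0 & ba$time_s < stimulus_keep_s
    list(y = ba$mean[, , idx, drop = FALSE], time_s = ba$time_s[idx])
  })
  names(windows) <- conds

  rows <- list()
  for (ec in eeg_channels) {
    ei <- match(ec, labels)
    for (bd in bands) {
      bi <- match(bd, band_tab$band)
      regs <- list()
      ok <- TRUE
      for (cond in conds) {
        stim_idx <- which(eeg_avg[[cond]]$phase == "stimulus")
        rms_block <- eeg_avg[[cond]]$rms[ei, bi, stim_idx]
        if (any(!is.finite(rms_block)) || all(rms_block == 0)) { ok <- FALSE; break }
        regs[[cond]] <- rms_block
      }
      if (!ok) next
      lens <- vapply(conds, function(cond) length(windows[[cond]]$time_s),
                     numeric(1))
      offs <- c(0, cumsum(lens))
      for (ci in seq_along(CHROMOPHORES)) {
        chromo <- CHROMOPHORES[ci]
        rf <- rf_list[[chromo]]
        # condition-specific regressor columns, shared across bNIRS channels
        X <- NULL
        for (k in seq_along(conds)) {
          reg <- build_neural_regressor(rf, regs[[conds[k]]],
                                        windows[[conds[k]]]$time_s)
          col <- numeric(sum(lens))
          col[(offs[k] + 1):offs[k + 1]] <- reg
          X <- cbind(X, col)
        }
        colnames(X) <- conds
        for (ch in channels) {
          y <- unlist(lapply(conds, function(cond) windows[[cond]]$y[ch, ci, ]))
          if (anyNA(y)) next
          fit <- tryCatch(fit_subject_glm(y, X), error = function(e) NULL)
          if (is.null(fit)) next
          for (k in seq_along(conds)) {
            rows[[length(rows) + 1]] <- data.frame(
              subject = subject_id, bnirs_channel = ch, chromophore = chromo,
              eeg_channel = ec, band = bd, condition = conds[k],
              beta = unname(fit$beta[k]), stringsAsFactors = FALSE)
          }
        }
      }
    }
  }
  do.call(rbind, rows)
}

#' Infant response functions on a 1 s grid
#' @param basis Named list of `basis_params` (default the infant best fit).
#' @return Named list of `response_function`s per chromophore.
#' @export
infant_rf <- function(basis = infant_basis_defaults()) {
  lapply(basis, double_gamma, sample_period_s = 1)
}

#' Group-level coupling statistics with BH-FDR over bNIRS channels
#'
#' One-sample t-tests of the subject betas against zero for every (bNIRS
#' channel, chromophore, EEG channel, band, condition) cell, with
#' Benjamini-Hochberg FDR correction applied across the bNIRS channels
#' within each (EEG channel, band, chromophore, condition) family, exactly
#' the six-channel families of the analysis design.
#'
#' @param subject_results Row-bound data frame of [subject_coupling()]
#'   outputs across subjects.
#' @param channels Channel set defining each FDR family (default: all
#'   channels present).
#' @param alpha Significance level (default 0.05).
#' @return A `group_coupling_table` data frame: per cell `beta_mean`, `t`,
#'   `p`, `q`, `n`, `sig`, `sig_fdr`. Zero-variance cells carry NA t/p.
#' @export
group_coupling_stats <- function(subject_results, channels = NULL,
                                 alpha = 0.05) {
  sr <- subject_results
  if (!is.null(channels)) sr <- sr[sr$bnirs_channel %in% channels, ]
  key <- interaction(sr$eeg_channel, sr$band, sr$chromophore, sr$condition,
                     drop = TRUE)
  out <- lapply(split(sr, key), function(fam) {
    cells <- lapply(split(fam, fam$bnirs_channel), function(cell) {
      ts <- t_one_sample(cell$beta)
      data.frame(bnirs_channel = cell$bnirs_channel[1],
                 chromophore = cell$chromophore[1],
                 eeg_channel = cell$eeg_channel[1], band = cell$band[1],
                 condition = cell$condition[1], beta_mean = ts$mean,
                 t = ts$t, p = ts$p, n = ts$n, stringsAsFactors = FALSE)
    })
    fam_tab <- do.call(rbind, cells)
    fam_tab$q <- bh_adjust(fam_tab$p)
    fam_tab
  })
  tab <- do.call(rbind, out)
  rownames(tab) <- NULL
  tab$sig <- !is.na(tab$p) & tab$p < alpha
  tab$sig_fdr <- !is.na(tab$q) & tab$q < alpha
  class(tab) <- c("group_coupling_table", "data.frame")
  tab
}

#' Paired social-vs-nonsocial coupling contrast
#'
#' Paired t-tests on per-subject beta differences (social minus non-social)
#' per cell, BH-FDR corrected across the bNIRS channels within each
#' (EEG channel, band, chromophore) family. Subjects missing either condition
#' are excluded with a warning.
#'
#' @param subject_results As in [group_coupling_stats()] (must contain both
#'   conditions).
#' @param channels Channel set (default all present).
#' @param alpha Significance level.
#' @return Data frame of contrast cells with `beta_diff_mean`, `t`, `p`, `q`,
#'   `n`, `sig`, `sig_fdr`.
#' @export
condition_contrast <- function(subject_results, channels = NULL, alpha = 0.05) {
  sr <- subject_results
  if (!is.null(channels)) sr <- sr[sr$bnirs_channel %in% channels, ]
  soc <- sr[sr$condition == "social", ]
  non <- sr[sr$condition == "non-social", ]
  keycols <- c("subject", "bnirs_channel", "chromophore", "eeg_channel", "band")
  m <- merge(soc, non, by = keycols, suffixes = c("_soc", "_non"))
  dropped <- (nrow(soc) + nrow(non) - 2 * nrow(m)) / 2
  if (dropped > 0) {
    warning(sprintf("%g unpaired subject-cells excluded from the contrast",
                    dropped), call. = FALSE)
  }
  m$diff <- m$beta_soc - m$beta_non
  key <- interaction(m$eeg_channel, m$band, m$chromophore, drop = TRUE)
  out <- lapply(split(m, key), function(fam) {
    cells <- lapply(split(fam, fam$bnirs_channel), function(cell) {
      ts <- t_one_sample(cell$diff)
      data.frame(bnirs_channel = cell$bnirs_channel[1],
                 chromophore = cell$chromophore[1],
                 eeg_channel = cell$eeg_channel[1], band = cell$band[1],
                 beta_diff_mean = ts$mean, t = ts$t, p = ts$p, n = ts$n,
                 stringsAsFactors = FALSE)
    })
    fam_tab <- do.call(rbind, cells)
    fam_tab$q <- bh_adjust(fam_tab$p)
    fam_tab
  })
  tab <- do.call(rbind, out)
  rownames(tab) <- NULL
  tab$sig <- !is.na(tab$p) & tab$p < alpha
  tab$sig_fdr <- !is.na(tab$q) & tab$q < alpha
  tab
}

#' Write a group coupling table as TSV
#' @param tab A `group_coupling_table` (or contrast table).
#' @param path Output file.
#' @export
write_coupling_table <- function(tab, path) {
  utils::write.table(as.data.frame(tab), path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}
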