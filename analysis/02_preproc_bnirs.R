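#!/usr/bin/env Rscript
# Stage 2: broadband-NIRS preprocessing.
#
# Per subject: intensity-count QC (2000-40000 counts, 60% subject rule),
# wavelet motion correction (db5, alpha = 0.8) on the attenuation signals,
# UCLn multiwavelength inversion (DPF 5.13, 780-900 nm) to Delta[HbO2],
# Delta[HHb], Delta[oxCCO], band-pass 0.01-0.4 Hz (clamped below the 1.4 s
# Nyquist), and block averaging per condition. Writes the QC table and caches
# the block averages for the later stages.

suppressPackageStartupMessages(library(bnirseeg))

cfg <- pipeline_config()
ext <- synthetic_extinction()
files <- Sys.glob("results/data/sub*_bnirs.csv")
stopifnot(length(files) > 0)
dir.create("results/cache", recursive = TRUE, showWarnings = FALSE)

qc_rows <- list()
bnirs_avgs <- list()
for (f in files) {
  id <- sub("_bnirs.csv$", "", basename(f))
  rec <- read_bnirs(f)
  schedule <- read_schedule(file.path(dirname(f), paste0(id, "_schedule.tsv")))
  qc <- qc_channels(rec, cfg$qc_low_counts, cfg$qc_high_counts,
                    cfg$qc_subject_threshold)
  qc_rows[[id]] <- cbind(subject = id, qc$channels,
                         subject_excluded = qc$subject_excluded)
  if (qc$subject_excluded) {
    message(id, ": excluded (", round(100 * qc$exclusion_fraction), "% bad channels)")
    next
  }
  rec <- wavelet_motion_correct(rec, cfg$wavelet_alpha)
  chromo <- ucln_invert(rec, ext, cfg$dpf, cfg$fit_range_nm)
  chromo <- suppressWarnings(
    bandpass_bnirs(chromo, cfg$bnirs_band_hz[1], cfg$bnirs_band_hz[2],
                   cfg$bnirs_filter_order))
  if (length(qc$excluded_channels)) chromo$conc[qc$excluded_channels, , ] <- NA
  ba <- list()
  for (cond in c("social", "non-social")) {
    ba[[cond]] <- block_average_bnirs(chromo, schedule, cond,
                                      window_s = cfg$hrf_window_s)
  }
  bnirs_avgs[[id]] <- ba
  message(sprintf("%s: %d/%d channels kept, %d+%d blocks averaged", id,
                  sum(qc$channels$keep), nrow(qc$channels),
                  ba$social$n_blocks, ba$`non-social`$n_blocks))
}

qc_tab <- do.call(rbind, qc_rows)
dir.create("results", showWarnings = FALSE)
write.table(qc_tab, "results/qc_report.tsv", sep = "\t", row.names = FALSE,
            quote = FALSE)
saveRDS(bnirs_avgs, "results/cache/bnirs_block_averages.rds")
message("QC report: results/qc_report.tsv")
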