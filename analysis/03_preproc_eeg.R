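#!/usr/bin/env Rscript
# Stage 3: EEG preprocessing and condition statistics.
#
# Per subject: 0.1-100 Hz band-pass with 48-52 Hz notch, average reference,
# bad-channel interpolation, segmentation into 1 s segments (200 ms carryover
# + 800 ms, within-segment baseline correction), 200 uV artifact rejection,
# band RMS power (theta/alpha/beta/gamma/high-gamma), block baseline
# correction and trial averaging. Group level: paired t-tests per channel and
# band for the three condition contrasts with BH-FDR across channels.

suppressPackageStartupMessages(library(bnirseeg))

cfg <- pipeline_config()
files <- Sys.glob("results/data/sub*_eeg.csv")
stopifnot(length(files) > 0)
dir.create("results/cache", recursive = TRUE, showWarnings = FALSE)

eeg_avgs <- list()
for (f in files) {
  id <- sub("_eeg.csv$", "", basename(f))
  eeg <- read_eeg(f)
  schedule <- read_schedule(file.path(dirname(f), paste0(id, "_schedule.tsv")))
  eeg <- rereference_average(filter_eeg(eeg, cfg$eeg_band_hz, cfg$eeg_notch_hz))
  bad <- detect_bad_channels(eeg, cfg$artifact_uv)
  if (length(bad)) eeg <- interpolate_bad_channels(eeg, bad)
  seg <- reject_artifact_segments(
    suppressWarnings(segment_and_baseline(eeg, schedule)), cfg$artifact_uv)
  bp <- band_rms(seg, cfg$bands)
  eeg_avgs[[id]] <- block_baseline_correct_and_average(
    bp, cfg$baseline_keep_s, cfg$stimulus_keep_s)
  message(sprintf("%s: %d segments retained, %d bad channel(s)", id,
                  attr(seg, "n_retained"), length(bad)))
}

stats_tab <- eeg_condition_stats(eeg_avgs, alpha = cfg$fdr_q)
write.table(stats_tab, "results/eeg_stats.tsv", sep = "\t",
            row.names = FALSE, quote = FALSE)
saveRDS(eeg_avgs, "results/cache/eeg_band_averages.rds")

sig <- stats_tab[stats_tab$sig_fdr, ]
message(sprintf("%d FDR-significant (channel, band, contrast) cells:",
                nrow(sig)))
for (i in seq_len(nrow(sig))) {
  message(sprintf("  %s %s %s: t = %.2f, q = %.4f", sig$channel[i],
                  sig$band[i], sig$contrast[i], sig$t[i], sig$q[i]))
}
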