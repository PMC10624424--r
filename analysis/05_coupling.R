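#!/usr/bin/env Rscript
# Stage 5: neurovascular / neurometabolic coupling GLMs and group statistics.
#
# Per subject and cell (bNIRS channel x chromophore x EEG channel x band):
# the reconstructed response function is convolved with the stimulus events
# ("predicted" bNIRS signal), then with the subject's stimulus-period EEG RMS
# block, interpolated to the bNIRS grid and z-scored to form the neural
# regressor. A joint GLM over both conditions yields a beta per condition;
# one-sample t-tests across subjects with BH-FDR over the six selected bNIRS
# channels give the group coupling maps, plus the paired social-vs-nonsocial
# contrast.

suppressPackageStartupMessages(library(bnirseeg))

cfg <- pipeline_config()
bnirs_avgs <- readRDS("results/cache/bnirs_block_averages.rds")
eeg_avgs <- readRDS("results/cache/eeg_band_averages.rds")
best_params <- readRDS("results/cache/rf_best_params.rds")
rf_list <- lapply(best_params, double_gamma, sample_period_s = 1)
channels <- cfg$coupling_channels

ids <- intersect(names(bnirs_avgs), names(eeg_avgs))
betas <- lapply(ids, function(id) {
  subject_coupling(bnirs_avgs[[id]], eeg_avgs[[id]], rf_list, channels,
                   stimulus_keep_s = cfg$stimulus_keep_s, subject_id = id)
})
subject_betas <- do.call(rbind, betas)
subject_betas <- subject_betas[is.finite(subject_betas$beta), ]

coupling <- group_coupling_stats(subject_betas, channels, alpha = cfg$fdr_q)
contrast <- condition_contrast(subject_betas, channels, alpha = cfg$fdr_q)
write_coupling_table(coupling, "results/coupling.tsv")
write_coupling_table(contrast, "results/contrast.tsv")

sig <- coupling[coupling$sig_fdr, ]
message(sprintf("%d of %d cells FDR-significant:", nrow(sig), nrow(coupling)))
for (i in seq_len(nrow(sig))) {
  message(sprintf("  ch %d %s ~ %s %s (%s): beta = %.2f, t = %.2f, q = %.4f",
                  sig$bnirs_channel[i], sig$chromophore[i], sig$eeg_channel[i],
                  sig$band[i], sig$condition[i], sig$beta_mean[i], sig$t[i],
                  sig$q[i]))
}
sigc <- contrast[contrast$sig_fdr, ]
message(sprintf("%d contrast cells FDR-significant", nrow(sigc)))
for (i in seq_len(nrow(sigc))) {
  message(sprintf("  ch %d %s ~ %s %s: diff = %.2f, t = %.2f, q = %.4f",
                  sigc$bnirs_channel[i], sigc$chromophore[i],
                  sigc$eeg_channel[i], sigc$band[i], sigc$beta_diff_mean[i],
                  sigc$t[i], sigc$q[i]))
}
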