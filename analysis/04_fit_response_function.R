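#!/usr/bin/env Rscript
# Stage 4: reconstruct the infant HRF and MRF by exhaustive grid search.
#
# Grand-average HbO2 / HHb / oxCCO responses (pooled over conditions,
# averaged over the selected coupling channels and subjects) are fitted with
# every double-gamma basis in the grid: response delay 5-15 s, undershoot
# delay 5-20 s, response:undershoot ratio 2-6, step 1 (880 combinations).
# The highest significant beta picks the infant basis; offsets are reported
# against the adult canonical (6, 16, 6).

suppressPackageStartupMessages(library(bnirseeg))

cfg <- pipeline_config()
bnirs_avgs <- readRDS("results/cache/bnirs_block_averages.rds")
channels <- cfg$coupling_channels
grand <- bnirseeg:::cohort_grand_average(bnirs_avgs, channels)
message(sprintf("grand average over %d subjects, channels %s",
                grand$n_subjects, paste(channels, collapse = " ")))

events <- data.frame(onset_s = 0, duration_s = cfg$hrf_event_duration_s)
adult <- adult_basis()
best_params <- list()
for (ci in seq_along(c("HbO2", "HHb", "oxCCO"))) {
  chromo <- c("HbO2", "HHb", "oxCCO")[ci]
  g <- grid_search_hrf(grand$mean[ci, ], grand$time_s, events,
                       cfg$hrf_delays, cfg$hrf_undershoots, cfg$hrf_ratios)
  write_grid_search(g, sprintf("results/grid_search_%s.tsv", chromo),
                    sprintf("results/rf_best_%s.json", chromo))
  b <- g$best
  best_params[[chromo]] <- b
  message(sprintf(
    "%s: delay %g s (%+g s vs adult), undershoot %g s (%+g s), ratio %g%s",
    chromo, b$delay_response_s, b$delay_response_s - adult$delay_response_s,
    b$delay_undershoot_s, b$delay_undershoot_s - adult$delay_undershoot_s,
    b$ratio_response_undershoot, if (g$significant) "" else " [not significant]"))
}
saveRDS(best_params, "results/cache/rf_best_params.rds")
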