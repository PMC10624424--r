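#' bNIRS probe layout
#'
#' The default layout reproduces the infant array: 4 time-multiplexed light
#' sources and 14 spectrometer-coupled detectors forming 19 measurement
#' channels at 2.5 cm source-detector separation, positioned over the
#' occipital cortex and right hemisphere. Channel indices 1-19 follow the
#' array numbering.
#'
#' @param n_sources,n_detectors Counts of optodes.
#' @param channel_pairs Data frame with columns `source`, `detector`, one row
#'   per measurement channel; defaults to the 19-channel arrangement.
#' @param separation_cm Source-detector separation in cm.
#' @return A `probe_layout` list with fields `n_sources`, `n_detectors`,
#'   `channel_pairs`, `n_channels`, `separation_cm`.
#' @export
probe_layout <- function(n_sources = 4, n_detectors = 14,
                         channel_pairs = NULL, separation_cm = 2.5) {
  if (is.null(channel_pairs)) {
    # default 19-channel wiring: sources 1-2 over occipital cortex share the
    # first detector bank, sources 3-4 over the right hemisphere the second.
    channel_pairs <- data.frame(
      source = c(1, 1, 1, 1, 2, 2, 2, 2, 2, 3, 3, 3, 3, 3, 4, 4, 4, 4, 4),
      detector = c(1, 2, 3, 4, 3, 4, 5, 6, 7, 8, 9, 10, 11, 12, 10, 11, 12, 13, 14)
    )
  }
  stop_if_not(all(channel_pairs$source >= 1 & channel_pairs$source <= n_sources),
              "channel_pairs references a source outside 1..n_sources")
  stop_if_not(all(channel_pairs$detector >= 1 & channel_pairs$detector <= n_detectors),
              "channel_pairs references a detector outside 1..n_detectors")
  stop_if_not(separation_cm > 0, "separation_cm must be positive")
  structure(list(n_sources = as.integer(n_sources),
                 n_detectors = as.integer(n_detectors),
                 channel_pairs = channel_pairs,
                 n_channels = nrow(channel_pairs),
                 separation_cm = separation_cm),
            class = "probe_layout")
}

#' @export
print.probe_layout <- function(x, ...) {
  cat(sprintf("bNIRS probe layout: %d sources x %d detectors, %d channels, %.1f cm separation\n",
              x$n_sources, x$n_detectors, x$n_channels, x$separation_cm))
  invisible(x)
}
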