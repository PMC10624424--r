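#' @keywords internal
"_PACKAGE"

# Chromophore order is fixed everywhere: HbO2, HHb, oxCCO.
CHROMOPHORES <- c("HbO2", "HHb", "oxCCO")

#' EEG frequency bands used throughout the pipeline
#'
#' Band edges in Hz: theta 3-6, alpha 8-12, beta 13-30, gamma 20-60,
#' high-gamma 60-80. Gamma deliberately overlaps beta; both are analysed as
#' printed band definitions, not as a partition of the spectrum.
#'
#' @return Data frame with columns `band`, `low_hz`, `high_hz`.
#' @export
eeg_bands <- function() {
  data.frame(
    band = c("theta", "alpha", "beta", "gamma", "high_gamma"),
    low_hz = c(3, 8, 13, 20, 60),
    high_hz = c(6, 12, 30, 60, 80),
    stringsAsFactors = FALSE
  )
}

zscore <- function(x) {
  s <- stats::sd(x)
  if (!is.finite(s) || s == 0) {
    stop("cannot standardise a zero-variance vector", call. = FALSE)
  }
  (x - mean(x)) / s
}

# Direct-summation causal convolution truncated to length(x) ("same" length,
# onset-anchored): y[t] = sum_k h[k] * x[t - k + 1].
conv_causal <- function(x, h) {
  n <- length(x)
  y <- numeric(n)
  for (k in seq_along(h)) {
    if (k > n) break
    y[k:n] <- y[k:n] + h[k] * x[1:(n - k + 1)]
  }
  y
}

# Zero-phase filtering with reflective padding to tame the edge transients of
# signal::filtfilt (which starts from zero initial conditions).
zp_filter <- function(filt, x, pad = NULL) {
  n <- length(x)
  if (is.null(pad)) pad <- min(n - 1L, max(50L, ceiling(n / 3)))
  if (pad > 0) {
    left <- 2 * x[1] - x[seq(pad + 1, 2)]
    right <- 2 * x[n] - x[seq(n - 1, n - pad)]
    xe <- c(left, x, right)
  } else {
    xe <- x
  }
  y <- signal::filtfilt(filt, xe)
  y[seq(pad + 1, pad + n)]
}

# One-sample / paired t helper returning NA-flagged cells on zero variance.
t_one_sample <- function(x) {
  x <- x[is.finite(x)]
  n <- length(x)
  if (n < 2) return(list(t = NA_real_, p = NA_real_, n = n, mean = mean(x)))
  s <- stats::sd(x)
  if (s == 0) {
    return(list(t = NA_real_, p = NA_real_, n = n, mean = mean(x)))
  }
  tt <- mean(x) / (s / sqrt(n))
  list(t = tt, p = 2 * stats::pt(-abs(tt), df = n - 1), n = n, mean = mean(x))
}

# BH adjustment that tolerates NA cells (kept NA, excluded from the family m).
bh_adjust <- function(p) {
  q <- rep(NA_real_, length(p))
  ok <- is.finite(p)
  if (any(ok)) q[ok] <- stats::p.adjust(p[ok], method = "BH")
  q
}

stop_if_not <- function(cond, msg) {
  if (!isTRUE(cond)) stop(msg, call. = FALSE)
}
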