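# Orthogonal discrete wavelet transform (Daubechies-5, periodic) and the
# IQR-thresholding motion correction applied to bNIRS attenuation signals.

# Daubechies-5 scaling (low-pass decomposition) filter, 10 taps. These are
# standard constants of the orthonormal db5 wavelet (sum = sqrt(2)).
DB5_LO <- c(0.0033357252854737712, -0.012580751999081999,
            -0.006241490212798274, 0.07757149384004572,
            -0.032244869584638375, -0.24229488706638203,
            0.13842814590132074, 0.7243085284377729,
            0.6038292697971896, 0.16010239797419293)
# Quadrature mirror high-pass filter g[m] = (-1)^m h[L-1-m]
DB5_HI <- rev(DB5_LO) * rep_len(c(1, -1), length(DB5_LO))

# One analysis step with periodic extension: even-length x -> (approx, detail).
dwt_step <- function(x, h = DB5_LO, g = DB5_HI) {
  n <- length(x)
  half <- n %/% 2L
  L <- length(h)
  # index matrix: row k holds positions (2(k-1) + 0:(L-1)) mod n
  base <- 2L * (seq_len(half) - 1L)
  idx <- outer(base, 0:(L - 1L), `+`) %% n + 1L
  xm <- matrix(x[idx], nrow = half)
  list(a = drop(xm %*% h), d = drop(xm %*% g))
}

# Adjoint (= inverse, by orthonormality) of dwt_step.
idwt_step <- function(a, d, h = DB5_LO, g = DB5_HI) {
  half <- length(a)
  n <- 2L * half
  L <- length(h)
  x <- numeric(n)
  base <- 2L * (seq_len(half) - 1L)
  for (m in 0:(L - 1L)) {
    # within a fixed tap shift m the scatter positions are pairwise distinct
    # (even bases are distinct mod the even length n), so direct indexing is safe
    pos <- (base + m) %% n + 1L
    x[pos] <- x[pos] + a * h[m + 1L] + d * g[m + 1L]
  }
  x
}

# Multi-level periodic DWT on a power-of-two length.
dwt_multilevel <- function(x, levels) {
  details <- vector("list", levels)
  a <- x
  for (j in seq_len(levels)) {
    s <- dwt_step(a)
    details[[j]] <- s$d
    a <- s$a
  }
  list(approx = a, details = details)
}

idwt_multilevel <- function(dec) {
  a <- dec$approx
  for (j in rev(seq_along(dec$details))) {
    a <- idwt_step(a, dec$details[[j]])
  }
  a
}

next_pow2 <- function(n) 2L^ceiling(log2(n))

# Symmetric (reflective) padding of x up to length `len`.
pad_reflect <- function(x, len) {
  n <- length(x)
  if (len == n) return(x)
  extra <- len - n
  # reflect off the right edge, cycling if the deficit exceeds 2n
  c(x, rep(c(rev(x), x), length.out = extra))
}

# Motion-correct one series: DWT, zero detail coefficients outside the Tukey
# fence [Q1 - alpha*IQR, Q3 + alpha*IQR] at each level, inverse transform.
wavelet_correct_series <- function(x, alpha) {
  n <- length(x)
  np <- next_pow2(n)
  xp <- pad_reflect(x, np)
  # conventional maximum useful depth for a length-10 filter; the slow
  # physiology left in the approximation band is never thresholded
  levels <- max(1L, floor(log2(np / (length(DB5_LO) - 1))))
  dec <- dwt_multilevel(xp, levels)
  dec$details <- lapply(dec$details, function(d) {
    qs <- stats::quantile(d, c(0.25, 0.75), names = FALSE, type = 7)
    iqr <- qs[2] - qs[1]
    lo <- qs[1] - alpha * iqr
    hi <- qs[2] + alpha * iqr
    d[d < lo | d > hi] <- 0
    d
  })
  idwt_multilevel(dec)[seq_len(n)]
}

#' Wavelet-based motion correction of broadband attenuation signals
#'
#' Applies, independently to every (channel, wavelength) attenuation series, a
#' discrete wavelet decomposition (Daubechies-5, periodic, maximum depth
#' allowed by the signal length) and zeroes any detail coefficient lying
#' outside the interquartile fence `[Q1 - alpha*IQR, Q3 + alpha*IQR]` at its
#' level before inverting the transform. Motion artifacts produce sparse,
#' large-magnitude detail coefficients and are attenuated; the oscillatory
#' physiological signal passes through essentially unchanged. The tuning
#' parameter defaults to `alpha = 0.8`.
#'
#' @param rec A `bnirs_recording` (see [forward_attenuation()]).
#' @param alpha Positive tuning parameter of the interquartile fence.
#' @return A `bnirs_recording` with the same shape and time grid.
#' @export
wavelet_motion_correct <- function(rec, alpha = 0.8) {
  stop_if_not(alpha > 0, "alpha must be positive")
  stopifnot(inherits(rec, "bnirs_recording"))
  dt <- diff(rec$time_s)
  stop_if_not(all(abs(dt - dt[1]) < 1e-6 * dt[1]),
              "motion correction requires a uniform time grid")
  att <- rec$attenuation
  for (ch in seq_len(dim(att)[1])) {
    for (wl in seq_len(dim(att)[2])) {
      att[ch, wl, ] <- wavelet_correct_series(att[ch, wl, ], alpha)
    }
  }
  rec$attenuation <- att
  rec
}
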