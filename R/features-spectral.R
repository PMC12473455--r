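# Spectral descriptor bank: Welch-averaged modified periodogram (2048-point
# Hamming segments, 50% overlap) and 8 band-limited features.

.hamming <- function(L) 0.54 - 0.46 * cos(2 * pi * (seq_len(L) - 1) / (L - 1))

#' Averaged modified periodogram of a signal
#'
#' Welch estimate over 2048-sample Hamming-windowed segments with 50%
#' overlap. Signals shorter than `nfft` are analysed as a single
#' zero-padded segment (flagged via the `padded` field). The one-sided
#' amplitude spectrum is scaled so a unit sinusoid inside a segment has
#' amplitude ~1 at its bin; `power` is the squared amplitude averaged over
#' segments.
#'
#' @param x Numeric sample vector.
#' @param fs Sampling rate (Hz).
#' @param nfft FFT length (default 2048; bin width `fs/nfft`).
#' @param band Analysis band in Hz, default 0.5-50 (matching the band-pass).
#' @return Object of class `power_spectrum` with fields `freqs`,
#'   `amplitude`, `power`, `band`, `nfft`, `window`, `padded`.
#' @export
power_spectrum <- function(x, fs, nfft = 2048, band = c(0.5, 50)) {
  assert_numeric_vector(x)
  n <- length(x)
  stopifnot(band[1] >= 0, band[2] <= fs / 2, band[1] < band[2])
  L <- min(n, nfft)
  w <- .hamming(L)
  step <- max(1, floor(L / 2))
  starts <- seq(1, n - L + 1, by = step)
  nbins <- nfft %/% 2 + 1
  acc <- numeric(nbins)
  for (s in starts) {
    seg <- x[s:(s + L - 1)] * w
    X <- stats::fft(c(seg, numeric(nfft - L)))[seq_len(nbins)]
    a <- Mod(X) * 2 / sum(w)
    a[1] <- a[1] / 2
    if (nfft %% 2 == 0) a[nbins] <- a[nbins] / 2
    acc <- acc + a^2
  }
  pow <- acc / length(starts)
  structure(list(freqs = (seq_len(nbins) - 1) * fs / nfft,
                 amplitude = sqrt(pow), power = pow,
                 band = band, nfft = nfft, window = "hamming",
                 padded = n < nfft),
            class = "power_spectrum")
}

#' @export
print.power_spectrum <- function(x, ...) {
  cat(sprintf(
    "Power spectrum: %d bins, %.3f Hz resolution, band %.1f-%.1f Hz%s\n",
    length(x$freqs), x$freqs[2] - x$freqs[1], x$band[1], x$band[2],
    if (x$padded) " (zero-padded)" else ""))
  invisible(x)
}

.band_idx <- function(ps) which(ps$freqs >= ps$band[1] & ps$freqs <= ps$band[2])

#' Spectral features from a power spectrum
#'
#' Over the analysis band: amplitude spectrum area
#' (`AMSA = sum(|X(f)| * f)`), centroid frequency (`CF`, power-weighted mean
#' frequency), peak frequency (`PF`, frequency of maximum power; lowest bin
#' on ties), total energy (`ENRG`, summed band power), spectral flatness
#' (`SFM`, geometric over arithmetic mean of band power), centroid power
#' (`CP`, power at the bin nearest `CF`), maximum power (`MP`), and mean
#' band power (`PSA = ENRG / number of band bins`).
#'
#' @param ps A [power_spectrum()].
#' @return Named numeric vector of 8 values; all `NA` (with a warning) when
#'   the band carries no power.
#' @export
extract_spectral_features <- function(ps) {
  stopifnot(inherits(ps, "power_spectrum"))
  idx <- .band_idx(ps)
  if (length(idx) < 8) stopf("analysis band contains fewer than 8 bins")
  f <- ps$freqs[idx]
  P <- ps$power[idx]
  A <- ps$amplitude[idx]
  if (all(P == 0)) {
    warnf("all-zero band power: spectral features flagged missing")
    return(stats::setNames(rep(NA_real_, 8),
                           c("AMSA", "CF", "PF", "ENRG", "SFM", "CP", "MP",
                             "PSA")))
  }
  cf <- sum(f * P) / sum(P)
  gm <- if (any(P == 0)) 0 else exp(mean(log(P)))
  c(AMSA = sum(A * f),
    CF = cf,
    PF = f[which.max(P)],
    ENRG = sum(P),
    SFM = gm / mean(P),
    CP = P[which.min(abs(f - cf))],
    MP = max(P),
    PSA = sum(P) / length(P))
}

#' Normalized spectral entropy
#'
#' Shannon entropy of the band power distribution normalized by the log of
#' the number of band bins, so a single-bin spectrum scores 0 and a uniform
#' band scores exactly 1.
#'
#' @param ps A [power_spectrum()].
#' @return Value in `[0, 1]`, or `NA` (with warning) on zero band power.
#' @export
spectral_entropy <- function(ps) {
  stopifnot(inherits(ps, "power_spectrum"))
  P <- ps$power[.band_idx(ps)]
  tot <- sum(P)
  if (tot == 0) {
    warnf("zero-power spectrum: spectral entropy missing")
    return(NA_real_)
  }
  p <- P / tot
  p <- p[p > 0]
  -sum(p * log(p)) / log(length(P))
}
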