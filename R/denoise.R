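# Three-stage cleaning chain for lead II: band-pass 0.5-50 Hz, LOESS
# baseline removal, non-local-means smoothing. All stages are
# length-preserving and deterministic.

#' Band-pass filter specification
#'
#' @param low,high Passband edges in Hz (defaults 0.5 and 50).
#' @param order Butterworth order per section (applied forward-backward, so
#'   the effective magnitude response is squared). Default 6: the lowest
#'   order whose zero-phase response attenuates 60 Hz by more than 20 dB
#'   while staying numerically stable at the 0.5 Hz edge.
#' @param zero_phase Apply forward-backward (no group delay).
#' @return Object of class `filter_spec`.
#' @export
filter_spec <- function(low = 0.5, high = 50, order = 6, zero_phase = TRUE) {
  if (!(low > 0 && low < high)) stopf("need 0 < low < high")
  structure(list(low = low, high = high, order = order,
                 zero_phase = zero_phase),
            class = "filter_spec")
}

#' Band-pass filter a signal
#'
#' Butterworth band realized as a high-pass / low-pass cascade (numerically
#' safer than a direct band-pass design at a 0.5 Hz edge on a 500 Hz grid),
#' each section applied forward-backward when `zero_phase`.
#'
#' @param x Numeric sample vector.
#' @param fs Sampling rate (Hz).
#' @param spec A [filter_spec()].
#' @return Filtered vector, same length.
#' @export
bandpass <- function(x, fs, spec = filter_spec()) {
  stopifnot(inherits(spec, "filter_spec"))
  if (spec$high >= fs / 2) stopf("high cut %g Hz >= Nyquist %g Hz",
                                 spec$high, fs / 2)
  if (length(x) < 3 * spec$order)
    stopf("signal too short for filter order %d", spec$order)
  x <- x - mean(x)   # DC handled exactly; also tames filtfilt edge transients
  hp <- signal::butter(spec$order, spec$low / (fs / 2), type = "high")
  lp <- signal::butter(spec$order, spec$high / (fs / 2), type = "low")
  run <- if (spec$zero_phase) {
    function(f, v) as.numeric(signal::filtfilt(f, v))
  } else {
    function(f, v) as.numeric(signal::filter(f, v))
  }
  run(lp, run(hp, x))
}

#' LOESS baseline estimation and removal
#'
#' Local-linear tricube-weighted smoothing (via the C `lowess`
#' implementation, zero robustness iterations) with a span expressed in
#' seconds; the fit is the baseline-wander estimate, the residual the
#' detrended signal.
#'
#' @param x Numeric sample vector.
#' @param fs Sampling rate (Hz).
#' @param span_seconds Smoother span in seconds (default 1.5 s: passes
#'   wander below ~0.5 Hz into the baseline while leaving QRS complexes in
#'   the residual).
#' @return List with `baseline` and `detrended` (`x - baseline`).
#' @export
loess_baseline <- function(x, fs, span_seconds = 1.5) {
  n <- length(x)
  if (span_seconds * fs < 10)
    stopf("span of %g s covers fewer than 10 samples at %g Hz",
          span_seconds, fs)
  f <- min(1, span_seconds * fs / n)
  fit <- stats::lowess(seq_len(n), x, f = f, iter = 0)
  baseline <- fit$y
  list(baseline = baseline, detrended = x - baseline)
}

#' Non-local-means parameters
#'
#' @param patch Patch half-width in samples (>= 1).
#' @param search Search half-width in samples, or `"full"` to compare
#'   against every patch in the signal (O(N^2)).
#' @param h_scale Bandwidth as a multiple of the estimated noise SD.
#' @return Object of class `nlm_params`.
#' @export
nlm_params <- function(patch = 10, search = 500, h_scale = 0.6) {
  stopifnot(patch >= 1, h_scale > 0)
  if (!identical(search, "full")) stopifnot(search >= 1)
  structure(list(patch = patch, search = search, h_scale = h_scale),
            class = "nlm_params")
}

# robust noise-SD estimate from first differences
.estimate_noise_sd <- function(x) {
  stats::median(abs(diff(x))) / (0.6745 * sqrt(2))
}

#' Non-local-means smoothing of a 1-D signal
#'
#' Each output sample is a similarity-weighted average of samples in the
#' search window whose surrounding patches match the patch around the target
#' sample: weights are `exp(-d2 / h2)` with `d2` the squared Euclidean
#' patch distance and `h2 = 2 * (2*patch+1) * (h_scale * sigma)^2`, sigma
#' estimated from the median absolute first difference. The self-weight is
#' set to the maximum off-center weight. Weights are nonnegative and
#' normalized, so every output sample is a convex combination of input
#' samples; samples whose patch does not fit inside the signal are copied
#' through.
#'
#' @param x Numeric sample vector, longer than `2 * patch`.
#' @param params An [nlm_params()].
#' @return Smoothed vector, same length.
#' @export
nlm_denoise <- function(x, params = nlm_params()) {
  stopifnot(inherits(params, "nlm_params"))
  n <- length(x)
  P <- params$patch
  if (n <= 2 * P) stopf("signal length %d too short for patch half-width %d",
                        n, P)
  S <- if (identical(params$search, "full")) n - 1 else params$search
  sigma <- .estimate_noise_sd(x)
  if (sigma == 0) return(x)  # noiseless flat/monotone signal: nothing to do
  h2 <- 2 * (2 * P + 1) * (params$h_scale * sigma)^2
  wlen <- 2 * P + 1

  num <- numeric(n)
  den <- numeric(n)
  wmax <- numeric(n)
  # sliding-window patch distances per shift t: d2(i, i+t) via cumsum
  for (t in c(-(S:1), 1:S)) {
    m_lo <- max(1, 1 - t)
    m_hi <- min(n, n - t)
    if (m_hi - m_lo + 1 < wlen) next
    e <- (x[m_lo:m_hi] - x[(m_lo + t):(m_hi + t)])^2
    cs <- cumsum(e)
    d2 <- cs[wlen:length(e)] - c(0, cs[seq_len(length(e) - wlen)])
    i <- (m_lo + P):(m_hi - P)           # centers with full patch overlap
    w <- exp(-d2 / h2)
    num[i] <- num[i] + w * x[i + t]
    den[i] <- den[i] + w
    wmax[i] <- pmax(wmax[i], w)
  }
  # self term: maximum off-center weight
  num <- num + wmax * x
  den <- den + wmax
  out <- x
  ok <- den > 0
  out[ok] <- num[ok] / den[ok]
  out
}

#' Full denoising pipeline
#'
#' Composition in the stated order: band-pass, then LOESS baseline removal,
#' then non-local-means smoothing.
#'
#' @param x Numeric sample vector.
#' @param fs Sampling rate (Hz).
#' @param spec A [filter_spec()].
#' @param span_seconds LOESS span in seconds.
#' @param params An [nlm_params()].
#' @return Denoised vector, same length as `x`.
#' @export
denoise_pipeline <- function(x, fs, spec = filter_spec(),
                             span_seconds = 1.5, params = nlm_params()) {
  bp <- bandpass(x, fs, spec)
  det <- loess_baseline(bp, fs, span_seconds)$detrended
  nlm_denoise(det, params)
}
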