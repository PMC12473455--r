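# Time-domain descriptor bank (10 features) computed on denoised lead II.

# Teager energy psi[n] = x[n]^2 - x[n-1]*x[n+1], Bartlett-smoothed
.sneo <- function(x, smooth_len = 11) {
  n <- length(x)
  psi <- x[2:(n - 1)]^2 - x[1:(n - 2)] * x[3:n]
  w <- .bartlett_window(smooth_len)
  w <- w / sum(w)
  if (length(psi) < smooth_len) return(mean(psi))
  sm <- stats::filter(psi, w, sides = 2)       # centered moving weighted mean
  mean(sm[!is.na(sm)])
}

.bartlett_window <- function(m) {
  # triangular window, endpoints zero
  k <- seq_len(m) - 1
  1 - abs((k - (m - 1) / 2) / ((m - 1) / 2))
}

# split indices into contiguous windows of win samples (last partial kept
# when at least half a window long)
.window_index <- function(n, win) {
  starts <- seq(1, n, by = win)
  lapply(starts, function(s) s:min(s + win - 1, n))
}

#' Time-domain features of a signal
#'
#' Computes the 10 time-domain descriptors: amplitude range (AR),
#' peak-to-peak amplitude averaged over 1-s windows (PPA), mean absolute
#' amplitude (MA), median stepping increment (MSI, median absolute first
#' difference — identical up to scale to the median successive increment of
#' the identity-lagged Poincare plot), signal integral (SignInt), full-signal
#' RMS (RMS1), mean of 2-s-window RMS values (RMS2), mean slope (MS), median
#' signed slope (MdS), and the Bartlett-smoothed nonlinear (Teager) energy
#' operator mean (SNEO).
#'
#' @param x Numeric sample vector (length >= 100).
#' @param fs Sampling rate (Hz).
#' @return Named numeric vector of 10 values. On a constant signal AR = 0
#'   and a degenerate-input warning is raised.
#' @export
extract_time_features <- function(x, fs) {
  assert_numeric_vector(x)
  if (length(x) < 100) stopf("need at least 100 samples, got %d", length(x))
  n <- length(x)
  if (max(x) == min(x)) warnf("constant signal: time-domain features degenerate")
  d <- diff(x)
  ppa <- mean(vapply(.window_index(n, round(fs)),
                     function(i) max(x[i]) - min(x[i]), numeric(1)))
  rms2 <- mean(vapply(.window_index(n, round(2 * fs)),
                      function(i) sqrt(mean(x[i]^2)), numeric(1)))
  c(AR = max(x) - min(x),
    PPA = ppa,
    MA = mean(abs(x)),
    MSI = stats::median(abs(d)),
    SignInt = sum(abs(x)) / fs,
    RMS1 = sqrt(mean(x^2)),
    RMS2 = rms2,
    MS = mean(abs(d)) * fs,
    MdS = stats::median(d) * fs,
    SNEO = .sneo(x))
}
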