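# Nonlinear / complexity descriptors: rescaled-range Hurst exponent, DFA-1
# scaling exponent, log absolute autocorrelations, wavelet entropy,
# approximate and fuzzy entropy.

#' Rescaled-range Hurst exponent
#'
#' Slope of `log(R/S)` against `log(window)` over dyadic window sizes 16 ...
#' N/4 (R = range of the cumulative mean-removed sum per block, S = block
#' SD, averaged over non-overlapping blocks). The raw R/S slope has a
#' well-known upward small-sample bias (~0.55 for white noise at N = 5000),
#' so by default the Anis-Lloyd correction is applied: `0.5 + H_emp - H_AL`,
#' where `H_AL` is the slope the Anis-Lloyd expected R/S values produce over
#' the same windows.
#'
#' @param x Numeric vector, length >= 256.
#' @param correct Apply the Anis-Lloyd small-sample correction (default).
#' @return The Hurst exponent estimate; `NA` (with warning) on constant
#'   input.
#' @export
hurst_rs <- function(x, correct = TRUE) {
  assert_numeric_vector(x)
  N <- length(x)
  if (N < 256) stopf("need at least 256 samples, got %d", N)
  if (stats::sd(x) == 0) {
    warnf("constant input: Hurst exponent undefined")
    return(NA_real_)
  }
  ns <- 2^(4:floor(log2(N / 4)))
  rs <- vapply(ns, function(n) {
    nb <- N %/% n
    vals <- vapply(seq_len(nb), function(b) {
      seg <- x[((b - 1) * n + 1):(b * n)]
      s <- stats::sd(seg)
      if (s == 0) return(NA_real_)
      y <- cumsum(seg - mean(seg))
      (max(y) - min(y)) / s
    }, numeric(1))
    mean(vals, na.rm = TRUE)
  }, numeric(1))
  ok <- is.finite(rs) & rs > 0
  if (sum(ok) < 2) {
    warnf("degenerate R/S statistics: Hurst exponent undefined")
    return(NA_real_)
  }
  h <- unname(stats::coef(stats::lm(log(rs[ok]) ~ log(ns[ok])))[2])
  if (!correct) return(h)
  ers <- vapply(ns[ok], .anis_lloyd_ers, numeric(1))
  h_al <- unname(stats::coef(stats::lm(log(ers) ~ log(ns[ok])))[2])
  0.5 + h - h_al
}

# expected R/S of an i.i.d. sequence of length n (Anis & Lloyd, with the
# (n - 1/2)/n finite-sample factor)
.anis_lloyd_ers <- function(n) {
  g <- if (n <= 340) gamma((n - 1) / 2) / (sqrt(pi) * gamma(n / 2))
       else 1 / sqrt(n * pi / 2)
  i <- seq_len(n - 1)
  g * sum(sqrt((n - i) / i)) * (n - 0.5) / n
}

#' DFA-1 scaling exponent
#'
#' Detrended fluctuation analysis of order 1: integrate the mean-removed
#' signal, piecewise-linearly detrend in non-overlapping boxes of
#' log-spaced sizes, and regress `log F(n)` on `log n`.
#'
#' @param x Numeric vector, length >= 256.
#' @param box_range Smallest and largest box size (default 4 and 64).
#' @param n_sizes Number of log-spaced box sizes.
#' @return The scaling exponent alpha (0.5 for white noise, ~1.5 for
#'   integrated white noise); `NA` (with warning) on constant input.
#' @export
dfa_alpha <- function(x, box_range = c(4, 64), n_sizes = 10) {
  assert_numeric_vector(x)
  N <- length(x)
  if (N < 256) stopf("need at least 256 samples, got %d", N)
  if (stats::sd(x) == 0) {
    warnf("constant input: DFA exponent undefined")
    return(NA_real_)
  }
  y <- cumsum(x - mean(x))
  boxes <- unique(round(exp(seq(log(box_range[1]), log(box_range[2]),
                                length.out = n_sizes))))
  Fn <- vapply(boxes, function(n) {
    nb <- N %/% n
    t <- cbind(1, seq_len(n))
    res2 <- vapply(seq_len(nb), function(b) {
      seg <- y[((b - 1) * n + 1):(b * n)]
      mean(stats::.lm.fit(t, seg)$residuals^2)
    }, numeric(1))
    sqrt(mean(res2))
  }, numeric(1))
  ok <- is.finite(Fn) & Fn > 0
  unname(stats::coef(stats::lm(log(Fn[ok]) ~ log(boxes[ok])))[2])
}

#' Log of summed absolute autocorrelations
#'
#' `log10(sum_{k=1..K} |rho(k)|)` with `rho` the sample autocorrelation of
#' the mean-removed signal.
#'
#' @param x Numeric vector, longer than `K`.
#' @param K Maximum lag (default 50).
#' @return LAC value; `NA` (with warning) on zero-variance input.
#' @export
lac <- function(x, K = 50) {
  assert_numeric_vector(x)
  if (length(x) <= K) stopf("need more than K = %d samples", K)
  if (stats::sd(x) == 0) {
    warnf("zero-variance input: LAC undefined")
    return(NA_real_)
  }
  rho <- stats::acf(x, lag.max = K, plot = FALSE, demean = TRUE)$acf[-1]
  log10(sum(abs(rho)))
}

# Daubechies-4 (8-tap) decomposition low-pass filter
.db4_lo <- c(-0.010597401784997278, 0.032883011666982945,
             0.030841381835986965, -0.187034811718881140,
             -0.027983769416983850, 0.630880767929590400,
             0.714846570552541500, 0.230377813308855230)

# one periodic DWT step; returns approximation and detail at half length
.dwt_step <- function(x, lo) {
  n <- length(x)
  L <- length(lo)
  hi <- rev(lo) * (-1)^(seq_len(L) - 1)   # quadrature mirror filter
  half <- n %/% 2
  a <- numeric(half)
  d <- numeric(half)
  base <- 2 * (seq_len(half) - 1)
  for (m in seq_len(L)) {
    idx <- (base + m - 1) %% n + 1
    a <- a + lo[m] * x[idx]
    d <- d + hi[m] * x[idx]
  }
  list(a = a, d = d)
}

#' Wavelet decomposition energies
#'
#' Periodic pyramid DWT with the 8-tap Daubechies-4 filter; returns the
#' energy in each detail level and the final approximation.
#'
#' @param x Numeric vector.
#' @param levels Decomposition depth (default 5).
#' @return Numeric vector `c(d1 ... d<levels>, a<levels>)` of subband
#'   energies; they sum to the signal energy (orthogonal transform).
#' @export
wavelet_energies <- function(x, levels = 5) {
  n2 <- 2^ceiling(log2(length(x)))
  if (n2 != length(x)) x <- c(x, numeric(n2 - length(x)))  # pad to dyadic
  energies <- numeric(levels)
  cur <- x
  for (l in seq_len(levels)) {
    st <- .dwt_step(cur, .db4_lo)
    energies[l] <- sum(st$d^2)
    cur <- st$a
  }
  c(energies, sum(cur^2))
}

#' Wavelet entropy
#'
#' Shannon entropy of the relative subband energies of a 5-level
#' Daubechies-4 decomposition, normalized to `[0, 1]` by the log of the
#' number of subbands.
#'
#' @param x Numeric vector.
#' @param levels Decomposition depth (default 5).
#' @return Value in `[0, 1]`; `NA` (with warning) on zero-energy input.
#' @export
wavelet_entropy <- function(x, levels = 5) {
  en <- wavelet_energies(x, levels)
  tot <- sum(en)
  if (tot == 0) {
    warnf("zero-energy signal: wavelet entropy undefined")
    return(NA_real_)
  }
  p <- en / tot
  p <- p[p > 0]
  -sum(p * log(p)) / log(levels + 1)
}

# embed x into (N - m + 1) x m template matrix
.embed_templates <- function(x, m) {
  n <- length(x) - m + 1
  mat <- matrix(0, n, m)
  for (j in seq_len(m)) mat[, j] <- x[j:(j + n - 1)]
  mat
}

# pairwise Chebyshev distances between rows (n x n matrix)
.cheb_dist <- function(mat) {
  n <- nrow(mat)
  d <- matrix(0, n, n)
  for (j in seq_len(ncol(mat))) {
    d <- pmax(d, abs(outer(mat[, j], mat[, j], "-")))
  }
  d
}

#' Approximate entropy
#'
#' Standard ApEn: `phi_m - phi_{m+1}` with
#' `phi_m = mean_i log(C_i^m(r))`, `C_i` the fraction of templates (self
#' included) within Chebyshev distance `r` of template `i`.
#'
#' @param x Numeric vector.
#' @param m Embedding dimension (default 2).
#' @param r Tolerance; default `0.2 * sd(x)`.
#' @return ApEn value; `NA` (with warning) on constant input.
#' @export
ap_entropy <- function(x, m = 2, r = 0.2 * stats::sd(x)) {
  assert_numeric_vector(x)
  if (is.na(r) || r == 0) {
    warnf("zero tolerance (constant input?): ApEn undefined")
    return(NA_real_)
  }
  phi <- function(mm) {
    tmpl <- .embed_templates(x, mm)
    d <- .cheb_dist(tmpl)
    mean(log(rowMeans(d <= r)))
  }
  phi(m) - phi(m + 1)
}

#' Fuzzy entropy
#'
#' FuzzyEn with exponential membership `exp(-(d/r)^p)` on baseline-removed
#' templates (each template has its own mean subtracted), Chebyshev
#' distance, self-matches excluded:
#' `ln(phi_m) - ln(phi_{m+1})`.
#'
#' @param x Numeric vector.
#' @param m Embedding dimension (default 2).
#' @param r Tolerance; default `0.2 * sd(x)`.
#' @param p Membership exponent (default 2).
#' @return FuzzyEn value; `NA` (with warning) on constant input.
#' @export
fuzzy_entropy <- function(x, m = 2, r = 0.2 * stats::sd(x), p = 2) {
  assert_numeric_vector(x)
  if (is.na(r) || r == 0) {
    warnf("zero tolerance (constant input?): FuzzyEn undefined")
    return(NA_real_)
  }
  phi <- function(mm) {
    tmpl <- .embed_templates(x, mm)
    tmpl <- tmpl - rowMeans(tmpl)
    d <- .cheb_dist(tmpl)
    mu <- exp(-(d / r)^p)
    n <- nrow(mu)
    (sum(mu) - n) / (n * (n - 1))   # exclude self-matches
  }
  log(phi(m)) - log(phi(m + 1))
}

#' Entropy-family features for the feature table
#'
#' `WE` (wavelet entropy of the full-rate signal), `SpeEnt` (normalized
#' spectral entropy of `ps`), and `ApEn` / `FuzzyEn` with `m = 2`,
#' `r = 0.2 * SD`, computed on the signal decimated to 125 Hz (anti-aliased
#' via [signal::decimate()]), which keeps the template statistics
#' well-populated over a 10-s record.
#'
#' @param x Numeric sample vector (length >= 500).
#' @param ps A [power_spectrum()] of `x`.
#' @param fs Sampling rate of `x` in Hz.
#' @return Named numeric vector `c(WE, SpeEnt, ApEn, FuzzyEn)`.
#' @export
entropy_features <- function(x, ps, fs = 500) {
  if (length(x) < 500) stopf("need at least 500 samples, got %d", length(x))
  q <- max(1, round(fs / 125))
  xd <- if (q > 1) as.numeric(signal::decimate(x, q)) else x
  c(WE = wavelet_entropy(x),
    SpeEnt = spectral_entropy(ps),
    ApEn = ap_entropy(xd),
    FuzzyEn = fuzzy_entropy(xd))
}
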