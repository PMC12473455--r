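# Independent brute-force oracles: direct-formula implementations written
# with plain loops, sharing no code with the package internals.

oracle_time_features <- function(x, fs) {
  n <- length(x)
  d <- numeric(n - 1)
  for (i in seq_len(n - 1)) d[i] <- x[i + 1] - x[i]
  # windowed statistics
  win_stat <- function(win, f) {
    starts <- seq(1, n, by = win)
    vals <- numeric(length(starts))
    for (k in seq_along(starts)) {
      idx <- starts[k]:min(starts[k] + win - 1, n)
      vals[k] <- f(x[idx])
    }
    mean(vals)
  }
  # Teager energy + Bartlett smoothing, written out longhand
  psi <- numeric(n - 2)
  for (i in 2:(n - 1)) psi[i - 1] <- x[i]^2 - x[i - 1] * x[i + 1]
  m <- 11
  w <- numeric(m)
  for (k in 1:m) w[k] <- 1 - abs(((k - 1) - (m - 1) / 2) / ((m - 1) / 2))
  w <- w / sum(w)
  half <- (m - 1) / 2
  sm <- numeric(0)
  for (c_ in (half + 1):(length(psi) - half)) {
    acc <- 0
    for (k in 1:m) acc <- acc + w[k] * psi[c_ + k - 1 - half]
    sm <- c(sm, acc)
  }
  c(AR = max(x) - min(x),
    PPA = win_stat(round(fs), function(v) max(v) - min(v)),
    MA = sum(abs(x)) / n,
    MSI = median(abs(d)),
    SignInt = sum(abs(x)) / fs,
    RMS1 = sqrt(sum(x^2) / n),
    RMS2 = win_stat(round(2 * fs), function(v) sqrt(mean(v^2))),
    MS = (sum(abs(d)) / (n - 1)) * fs,
    MdS = median(d) * fs,
    SNEO = mean(sm))
}

# naive-DFT modified periodogram (single zero-padded Hamming segment; valid
# for inputs shorter than nfft) and the spectral features by direct sums
oracle_spectrum <- function(x, fs, nfft = 2048, band = c(0.5, 50)) {
  n <- length(x)
  stopifnot(n <= nfft)
  w <- numeric(n)
  for (k in 1:n) w[k] <- 0.54 - 0.46 * cos(2 * pi * (k - 1) / (n - 1))
  xs <- x * w
  nbins <- nfft %/% 2 + 1
  amp <- numeric(nbins)
  for (b in seq_len(nbins)) {
    re <- 0; im <- 0
    for (t in seq_len(n)) {
      ang <- -2 * pi * (b - 1) * (t - 1) / nfft
      re <- re + xs[t] * cos(ang)
      im <- im + xs[t] * sin(ang)
    }
    a <- sqrt(re^2 + im^2) * 2 / sum(w)
    if (b == 1 || (nfft %% 2 == 0 && b == nbins)) a <- a / 2
    amp[b] <- a
  }
  freqs <- (seq_len(nbins) - 1) * fs / nfft
  keep <- freqs >= band[1] & freqs <= band[2]
  f <- freqs[keep]; A <- amp[keep]; P <- A^2
  cf <- sum(f * P) / sum(P)
  logs <- 0
  anyzero <- FALSE
  for (p in P) if (p == 0) anyzero <- TRUE else logs <- logs + log(p)
  gm <- if (anyzero) 0 else exp(logs / length(P))
  pn <- P / sum(P)
  ent <- 0
  for (p in pn) if (p > 0) ent <- ent - p * log(p)
  list(freqs = f, power = P, amplitude = A,
       features = c(AMSA = sum(A * f), CF = cf, PF = f[which.max(P)],
                    ENRG = sum(P), SFM = gm / mean(P), MP = max(P),
                    PSA = mean(P)),
       SpeEnt = ent / log(length(P)))
}

oracle_lac <- function(x, K = 50) {
  n <- length(x)
  xb <- sum(x) / n
  denom <- sum((x - xb)^2)
  s <- 0
  for (k in 1:K) {
    num <- 0
    for (t in 1:(n - k)) num <- num + (x[t] - xb) * (x[t + k] - xb)
    s <- s + abs(num / denom)
  }
  log10(s)
}

oracle_apen <- function(x, m = 2, r = 0.2 * sd(x)) {
  n <- length(x)
  phi <- function(mm) {
    nt <- n - mm + 1
    logs <- 0
    for (i in seq_len(nt)) {
      cnt <- 0
      for (j in seq_len(nt)) {
        dmax <- 0
        for (k in 0:(mm - 1)) {
          dd <- abs(x[i + k] - x[j + k])
          if (dd > dmax) dmax <- dd
        }
        if (dmax <= r) cnt <- cnt + 1
      }
      logs <- logs + log(cnt / nt)
    }
    logs / nt
  }
  phi(m) - phi(m + 1)
}

oracle_mi_bits <- function(x, y) {
  xs <- unique(x); ys <- unique(y)
  n <- length(x)
  mi <- 0
  for (a in xs) for (b in ys) {
    pab <- sum(x == a & y == b) / n
    if (pab > 0) mi <- mi + pab * log2(pab / ((sum(x == a) / n) * (sum(y == b) / n)))
  }
  mi
}

# per-point silhouette by full pairwise enumeration
oracle_silhouette <- function(X, labels) {
  X <- as.matrix(X)
  n <- nrow(X)
  ed <- function(i, j) sqrt(sum((X[i, ] - X[j, ])^2))
  s <- numeric(n)
  for (i in seq_len(n)) {
    own <- setdiff(which(labels == labels[i]), i)
    a <- mean(vapply(own, function(j) ed(i, j), numeric(1)))
    b <- Inf
    for (cl in setdiff(unique(labels), labels[i])) {
      idx <- which(labels == cl)
      b <- min(b, mean(vapply(idx, function(j) ed(i, j), numeric(1))))
    }
    s[i] <- (b - a) / max(a, b)
  }
  mean(s)
}
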