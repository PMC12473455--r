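# Signal descriptor bank vs independent brute-force oracles, closed-form
# checks, and invariance properties.

test_that("time-domain features match the brute-force oracle to 1e-9", {
  set.seed(101)
  for (rep in 1:5) {
    x <- rnorm(200) + 0.5 * sin(2 * pi * (1:200) / 37)
    fs <- 50  # 200 samples = 4 s: 1-s and 2-s windows well defined
    expect_equal(extract_time_features(x, fs), oracle_time_features(x, fs),
                 tolerance = 1e-9)
  }
})

test_that("simple time-domain identities hold", {
  x <- rep(c(0, 1, -1, 0), 25)
  expect_equal(unname(extract_time_features(x, 50)["AR"]), 2)
  suppressWarnings(fc <- extract_time_features(rep(3, 200), 50))
  expect_equal(unname(fc["AR"]), 0)
  expect_equal(unname(fc["MA"]), 3)
  expect_equal(unname(fc["MSI"]), 0)
  expect_equal(unname(fc["RMS1"]), 3)
  expect_equal(unname(fc["MS"]), 0)
  expect_warning(extract_time_features(rep(3, 200), 50), "constant")
})

test_that("SNEO of a pure tone matches the closed form", {
  fs <- 500
  for (f0 in c(5, 17, 40)) {
    A <- 1.3
    x <- A * sin(2 * pi * f0 * (0:4999) / fs)
    sneo <- unname(extract_time_features(x, fs)["SNEO"])
    expect_equal(sneo, A^2 * sin(2 * pi * f0 / fs)^2, tolerance = 0.01)
  }
})

test_that("spectral features match the naive-DFT oracle to 1e-9", {
  set.seed(202)
  x <- rnorm(200) + sin(2 * pi * (1:200) * 10 / 500)
  fs <- 500
  ps <- suppressWarnings(power_spectrum(x, fs))
  orc <- oracle_spectrum(x, fs)
  mine <- extract_spectral_features(ps)
  for (f in c("AMSA", "CF", "PF", "ENRG", "SFM", "MP", "PSA"))
    expect_equal(unname(mine[f]), unname(orc$features[f]), tolerance = 1e-9,
                 label = f)
  expect_equal(unname(mine["CP"]),
               orc$power[which.min(abs(orc$freqs - orc$features["CF"]))],
               tolerance = 1e-9)
  expect_equal(spectral_entropy(ps), orc$SpeEnt, tolerance = 1e-9)
})

test_that("peak and centroid frequency land on a tone's bin", {
  fs <- 500
  x <- sin(2 * pi * 10 * (0:4999) / fs)
  ps <- power_spectrum(x, fs)
  feats <- extract_spectral_features(ps)
  bin <- fs / 2048
  expect_lt(abs(feats[["PF"]] - 10), bin)
  expect_lt(abs(feats[["CF"]] - 10), 1)   # sidelobes pull the centroid a bit
  expect_lt(feats[["SFM"]], 0.05)
})

test_that("spectral flatness separates noise from tones", {
  set.seed(303)
  sfm_noise <- vapply(1:20, function(s) {
    set.seed(s)
    ps <- power_spectrum(rnorm(16384), 500)
    extract_spectral_features(ps)[["SFM"]]
  }, numeric(1))
  expect_true(all(sfm_noise > 0.8))
})

test_that("flat and single-bin spectra hit the entropy/flatness endpoints", {
  ps <- power_spectrum(sin(2 * pi * 10 * (0:4999) / 500), 500)
  # synthetic spectra exercising exact endpoints
  flat <- ps; flat$power[] <- 1; flat$amplitude[] <- 1
  feats <- extract_spectral_features(flat)
  expect_identical(feats[["SFM"]], 1)
  expect_identical(spectral_entropy(flat), 1)
  f <- flat$freqs[flat$freqs >= 0.5 & flat$freqs <= 50]
  expect_equal(feats[["CF"]], mean(f))
  single <- ps; single$power[] <- 0; single$amplitude[] <- 0
  single$power[100] <- 5; single$amplitude[100] <- sqrt(5)
  expect_identical(spectral_entropy(single), 0)
  zero <- ps; zero$power[] <- 0; zero$amplitude[] <- 0
  expect_warning(sf <- extract_spectral_features(zero), "missing")
  expect_true(all(is.na(sf)))
  expect_warning(expect_true(is.na(spectral_entropy(zero))), "missing")
})

test_that("LAC matches the brute-force autocorrelation oracle", {
  set.seed(404)
  x <- as.numeric(arima.sim(list(ar = 0.5), 300))
  expect_equal(lac(x, K = 50), oracle_lac(x, K = 50), tolerance = 1e-9)
  # AR(1) with rho(1) = 0.5: K = 1 gives log10(~0.5)
  set.seed(405)
  y <- as.numeric(arima.sim(list(ar = 0.5), 20000))
  expect_equal(lac(y, K = 1), log10(0.5), tolerance = 0.05)
  # periodic signal is more autocorrelated than noise
  tone <- sin(2 * pi * (1:300) / 25)
  set.seed(406)
  expect_gt(lac(tone), lac(rnorm(300)))
  expect_warning(expect_true(is.na(lac(rep(1, 300)))), "undefined")
})

test_that("ApEn matches its brute-force oracle and orders regularity", {
  set.seed(505)
  x <- rnorm(200)
  expect_equal(ap_entropy(x), oracle_apen(x), tolerance = 1e-9)
  tone <- sin(2 * pi * (1:500) / 40)
  set.seed(506)
  noise <- rnorm(500)
  expect_gt(ap_entropy(noise), ap_entropy(tone))
  expect_gt(fuzzy_entropy(noise), fuzzy_entropy(tone))
  expect_warning(expect_true(is.na(ap_entropy(rep(2, 100)))), "undefined")
})

test_that("wavelet transform conserves energy; entropy stays in [0, 1]", {
  set.seed(606)
  x <- rnorm(4096)
  en <- wavelet_energies(x)
  expect_length(en, 6)
  expect_equal(sum(en), sum(x^2), tolerance = 1e-9)
  we <- wavelet_entropy(x)
  expect_gt(we, 0)
  expect_lte(we, 1)
  # a pure scale-localized signal concentrates energy: lower entropy
  smooth <- sin(2 * pi * (1:4096) / 1024)
  expect_lt(wavelet_entropy(smooth), we)
})

test_that("features scale as |c| or c^2, invariants stay put", {
  set.seed(707)
  g <- generate_record(default_rhythm_models()$SR, seed = 12,
                       noise = noise_spec(0.05, 0.2, 0, 50, 0.02))
  x <- select_lead(g$record, "II")
  c_ <- 3.7
  f1 <- suppressWarnings(extract_signal_features(x, 500))
  f2 <- suppressWarnings(extract_signal_features(c_ * x, 500))
  linear <- c("AR", "PPA", "MA", "MSI", "SignInt", "RMS1", "RMS2", "MS",
              "MdS", "AMSA")
  quadratic <- c("SNEO", "ENRG", "MP", "CP", "PSA")
  invariant <- c("SFM", "SpeEnt", "Hu", "ScE", "ApEn", "FuzzyEn", "WE",
                 "LAC", "CF", "PF")
  for (f in linear)
    expect_equal(f2[[f]], c_ * f1[[f]], tolerance = 1e-6, label = f)
  for (f in quadratic)
    expect_equal(f2[[f]], c_^2 * f1[[f]], tolerance = 1e-6, label = f)
  for (f in invariant)
    expect_equal(f2[[f]], f1[[f]], tolerance = 1e-6, label = f)
})

test_that("spectral features are stable under circular time shifts", {
  fs <- 500
  x <- sin(2 * pi * 10 * (0:4999) / fs) + 0.3 * sin(2 * pi * 25 * (0:4999) / fs)
  shift <- function(v, s) c(v[(s + 1):length(v)], v[1:s])
  f0 <- extract_spectral_features(power_spectrum(x, fs))
  bin <- fs / 2048
  for (s in c(137, 1911)) {
    fshift <- extract_spectral_features(power_spectrum(shift(x, s), fs))
    expect_lt(abs(fshift[["PF"]] - f0[["PF"]]), bin)
    expect_lt(abs(fshift[["CF"]] - f0[["CF"]]), bin)
  }
})
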