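# Synthetic lead-II cohort generator: 10-s, 500 Hz records built from a
# 5-Gaussian beat template placed at lognormal-sampled RR intervals, with a
# class-conditional rhythm model and an additive noise model, plus matching
# ground-truth-derived diagnostics metadata.

#' Beat template: 5-Gaussian beat morphology
#'
#' Each wave (P, Q, R, S, T) is a Gaussian kernel with an amplitude (mV), a
#' center offset relative to the R peak (s) and a width (s). Defaults give a
#' lead-II-like upright beat with dominant R.
#'
#' @param amplitude,center,width Named numeric vectors over
#'   `c("P","Q","R","S","T")`.
#' @return Object of class `beat_template`.
#' @export
beat_template <- function(
    amplitude = c(P = 0.15, Q = -0.10, R = 1.00, S = -0.20, T = 0.30),
    center = c(P = -0.180, Q = -0.035, R = 0.000, S = 0.035, T = 0.280),
    width = c(P = 0.022, Q = 0.010, R = 0.011, S = 0.010, T = 0.055)) {
  waves <- c("P", "Q", "R", "S", "T")
  stopifnot(setequal(names(amplitude), waves), setequal(names(center), waves),
            setequal(names(width), waves))
  if (any(width <= 0)) stopf("beat template widths must be positive")
  if (abs(amplitude["R"]) <= max(abs(amplitude[c("P", "T")])))
    stopf("R amplitude must dominate P and T")
  structure(list(amplitude = amplitude[waves], center = center[waves],
                 width = width[waves]),
            class = "beat_template")
}

# QRS-core support of the template in seconds (3 sigma around Q-R-S); at
# high rates P/T waves legitimately merge into neighbouring beats, but QRS
# complexes may not overlap
.template_support <- function(template) {
  w <- c("Q", "R", "S")
  c(lo = min(template$center[w] - 3 * template$width[w]),
    hi = max(template$center[w] + 3 * template$width[w]))
}

#' Class-conditional rhythm model
#'
#' Describes how beats of one rhythm class are placed: heart-rate mean/SD in
#' BPM across subjects, within-record RR coefficient of variation, whether P
#' waves are present, and optional fibrillatory baseline (band in Hz) or
#' flutter waves (rate per minute).
#'
#' @param class_code Rhythm code (e.g. `"SB"`, `"AFIB"`).
#' @param hr_mean,hr_sd Heart-rate mean and between-subject SD (BPM).
#' @param rr_cv Within-record RR coefficient of variation.
#' @param p_wave Logical; P waves present.
#' @param fib_baseline Logical; add band-limited fibrillatory oscillation.
#' @param fib_band Fibrillatory band (Hz), used when `fib_baseline`.
#' @param flutter Logical; add sawtooth flutter waves.
#' @param flutter_rate Flutter rate per minute.
#' @return Object of class `rhythm_model`.
#' @export
rhythm_model <- function(class_code, hr_mean, hr_sd, rr_cv,
                         p_wave = TRUE, fib_baseline = FALSE,
                         fib_band = c(4, 9), flutter = FALSE,
                         flutter_rate = 300) {
  stopifnot(hr_mean > 0, hr_sd >= 0, rr_cv >= 0)
  structure(list(class_code = class_code, hr_mean = hr_mean, hr_sd = hr_sd,
                 rr_cv = rr_cv, p_wave = p_wave, fib_baseline = fib_baseline,
                 fib_band = fib_band, flutter = flutter,
                 flutter_rate = flutter_rate),
            class = "rhythm_model")
}

#' Default rhythm models for the 11 rhythm codes
#'
#' Invented class parameterizations that reproduce the defining semantics of
#' each rhythm (bradycardic SB < 60 BPM, tachycardic GSVT members > 100 BPM,
#' irregular-RR AFIB with no P wave and 4-9 Hz fibrillatory baseline,
#' sawtooth flutter for AF); they are documented fixtures, not estimates of
#' the clinical database.
#'
#' @return Named list of [rhythm_model()] objects keyed by rhythm code.
#' @export
default_rhythm_models <- function() {
  list(
    SB    = rhythm_model("SB", 50, 5, 0.03),
    SR    = rhythm_model("SR", 75, 8, 0.05),
    SA    = rhythm_model("SA", 70, 8, 0.13),
    ST    = rhythm_model("ST", 120, 15, 0.04),
    SVT   = rhythm_model("SVT", 180, 20, 0.03, p_wave = FALSE),
    AT    = rhythm_model("AT", 140, 15, 0.05),
    AVNRT = rhythm_model("AVNRT", 170, 20, 0.03, p_wave = FALSE),
    AVRT  = rhythm_model("AVRT", 180, 20, 0.03, p_wave = FALSE),
    SAAWR = rhythm_model("SAAWR", 90, 10, 0.10),
    AFIB  = rhythm_model("AFIB", 110, 20, 0.25, p_wave = FALSE,
                         fib_baseline = TRUE),
    AF    = rhythm_model("AF", 130, 15, 0.06, p_wave = FALSE,
                         flutter = TRUE, flutter_rate = 300)
  )
}

#' Additive noise model
#'
#' @param wander_amp Baseline-wander amplitude (mV).
#' @param wander_freq Wander frequency (Hz, below 0.5).
#' @param powerline_amp Powerline tone amplitude (mV).
#' @param powerline_freq Powerline frequency (Hz); 50 by default (region of
#'   origin of the database), configurable.
#' @param broadband_sd White-noise SD (mV).
#' @return Object of class `noise_spec`.
#' @export
noise_spec <- function(wander_amp = 0.15, wander_freq = 0.25,
                       powerline_amp = 0.05, powerline_freq = 50,
                       broadband_sd = 0.04) {
  stopifnot(wander_amp >= 0, powerline_amp >= 0, broadband_sd >= 0,
            wander_freq < 0.5)
  structure(list(wander_amp = wander_amp, wander_freq = wander_freq,
                 powerline_amp = powerline_amp,
                 powerline_freq = powerline_freq,
                 broadband_sd = broadband_sd),
            class = "noise_spec")
}

#' Add baseline wander, powerline tone and broadband noise to a signal
#'
#' Output = signal + wander sinusoid + powerline tone + white noise. With an
#' all-zero spec the input is returned unchanged. Random phase/noise use the
#' current RNG state; seed externally for reproducibility.
#'
#' @param signal Numeric sample vector.
#' @param noise A [noise_spec()].
#' @param fs Sampling rate (Hz).
#' @return Noisy vector, same length.
#' @export
inject_noise <- function(signal, noise, fs = 500) {
  stopifnot(inherits(noise, "noise_spec"))
  n <- length(signal)
  t <- (seq_len(n) - 1) / fs
  out <- signal
  if (noise$wander_amp > 0)
    out <- out + noise$wander_amp *
      sin(2 * pi * noise$wander_freq * t + stats::runif(1, 0, 2 * pi))
  if (noise$powerline_amp > 0)
    out <- out + noise$powerline_amp *
      sin(2 * pi * noise$powerline_freq * t + stats::runif(1, 0, 2 * pi))
  if (noise$broadband_sd > 0)
    out <- out + stats::rnorm(n, sd = noise$broadband_sd)
  out
}

# place beats: RR drawn i.i.d. lognormal with given mean (s) and CV
.sample_beat_times <- function(rr_mean, rr_cv, duration) {
  sdlog <- sqrt(log(1 + rr_cv^2))
  meanlog <- log(rr_mean) - sdlog^2 / 2
  times <- c()
  t <- stats::runif(1, 0, rr_mean)  # random first-beat phase
  while (t < duration) {
    times <- c(times, t)
    t <- t + stats::rlnorm(1, meanlog, sdlog)
  }
  times
}

#' Generate one synthetic lead-II record with diagnostics
#'
#' Lead II is a sum of Gaussian waves placed at RR-sampled beat times (RR
#' i.i.d. lognormal with the model's mean and CV); P waves are suppressed
#' and a band-limited fibrillatory oscillation added when the model says so;
#' flutter models add a sawtooth at the flutter rate. The other 11 columns
#' are scaled copies of lead II (plumbing only — no vectorcardiographic
#' realism). The diagnostics row carries ground-truth-derived attributes:
#' ventricular rate = 60 / mean generated RR, QRS count = number of beats
#' placed, QT interval from the template geometry, age and sex sampled.
#'
#' @param model A [rhythm_model()].
#' @param template A [beat_template()].
#' @param noise A [noise_spec()]; use amplitudes 0 for a clean record.
#' @param seed Integer seed; the generator is a pure function of
#'   (model, template, noise, seed).
#' @param record_id Record identifier.
#' @param fs,duration Sampling rate (Hz) and record length (s).
#' @return List with `record` ([ecg_record()]) and `diagnostics` (one-row
#'   data.frame).
#' @export
generate_record <- function(model, template = beat_template(),
                            noise = noise_spec(), seed = 1,
                            record_id = sprintf("SYN%05d", seed),
                            fs = 500, duration = 10) {
  stopifnot(inherits(model, "rhythm_model"), inherits(template, "beat_template"))
  sup <- .template_support(template)
  hr_subj_max <- model$hr_mean + 3 * model$hr_sd
  if (60 / hr_subj_max < (sup["hi"] - sup["lo"]))
    stopf("infeasible model '%s': beats at %g BPM overlap the template support",
          model$class_code, hr_subj_max)

  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(seed)

  hr <- max(20, stats::rnorm(1, model$hr_mean, model$hr_sd))
  rr_mean <- 60 / hr
  beat_times <- .sample_beat_times(rr_mean, model$rr_cv, duration)
  n <- round(fs * duration)
  t <- (seq_len(n) - 1) / fs

  waves <- c(if (model$p_wave) "P", "Q", "R", "S", "T")
  x <- numeric(n)
  for (bt in beat_times)
    for (w in waves)
      x <- x + template$amplitude[w] *
        exp(-((t - bt - template$center[w])^2) / (2 * template$width[w]^2))

  if (model$fib_baseline) {
    f <- stats::runif(3, model$fib_band[1], model$fib_band[2])
    ph <- stats::runif(3, 0, 2 * pi)
    for (k in 1:3) x <- x + 0.05 * sin(2 * pi * f[k] * t + ph[k])
  }
  if (model$flutter) {
    per <- 60 / model$flutter_rate
    saw <- 2 * ((t / per) %% 1) - 1   # sawtooth in [-1, 1]
    x <- x + 0.1 * saw
  }
  x <- inject_noise(x, noise, fs)

  # other 11 leads: fixed scaled copies of lead II (plumbing)
  scales <- c(I = 0.5, II = 1, III = 0.5, aVR = -0.75, aVL = -0.1, aVF = 0.75,
              V1 = -0.3, V2 = 0.4, V3 = 0.7, V4 = 0.9, V5 = 0.8, V6 = 0.6)
  sig <- outer(x, unname(scales[.lead_names]))
  record <- ecg_record(sig, record_id, fs = fs)

  rr <- diff(beat_times)
  vrate <- if (length(rr)) 60 / mean(rr) else hr
  # interval measurements carry ~3% per-subject measurement noise, as
  # vendor-computed fiducials do
  qrs_ms <- 1000 * (template$center["S"] - template$center["Q"] +
                      2 * (template$width["Q"] + template$width["S"])) *
    stats::rnorm(1, 1, 0.03)
  qt_ms <- 1000 * (template$center["T"] + 2 * template$width["T"] -
                     (template$center["Q"] - 2 * template$width["Q"])) *
    stats::rnorm(1, 1, 0.03)
  q_onset <- round(fs * (beat_times[1] + template$center["Q"] -
                           2 * template$width["Q"]))
  diag <- data.frame(
    FileName = record_id,
    Rhythm = model$class_code,
    Age = round(min(95, max(18, stats::rnorm(1, 62, 15)))),
    Gender = sample(c("MALE", "FEMALE"), 1),
    VentricularRate = vrate,
    AtrialRate = if (model$fib_baseline) stats::runif(1, 300, 450)
                 else if (model$flutter) model$flutter_rate else vrate,
    QRSDuration = qrs_ms,
    QTInterval = qt_ms,
    QTCorrected = qt_ms / sqrt(mean(if (length(rr)) rr else rr_mean)),
    RAxis = round(stats::rnorm(1, 45, 25)),
    TAxis = round(stats::rnorm(1, 40, 25)),
    QRSCount = length(beat_times),
    QOnset = max(0, q_onset),
    QOffset = max(0, q_onset) + round(fs * qrs_ms / 1000),
    TOffset = max(0, q_onset) + round(fs * qt_ms / 1000),
    stringsAsFactors = FALSE
  )
  list(record = record, diagnostics = diag)
}

#' Generate a balanced synthetic cohort
#'
#' @param n_per_class Records per requested class (>= 1).
#' @param classes Rhythm codes to generate; must be keys of `models`.
#' @param seed Global seed; each record gets a derived sub-seed, so
#'   disjoint seeds give disjoint realizations.
#' @param models Named list of [rhythm_model()]s, default
#'   [default_rhythm_models()].
#' @param template,noise Shared beat template and noise model.
#' @return List with `records` (list of [ecg_record()]) and `diagnostics`
#'   (data.frame, one row per record, `Rhythm` = generating class code).
#' @export
generate_cohort <- function(n_per_class, classes = c("AFIB", "SB", "SR", "ST"),
                            seed = 1, models = default_rhythm_models(),
                            template = beat_template(),
                            noise = noise_spec()) {
  stopifnot(n_per_class >= 1)
  unknown <- setdiff(classes, names(models))
  if (length(unknown))
    stopf("unknown class label(s): %s", paste(unknown, collapse = ", "))
  records <- list()
  diags <- list()
  k <- 0
  for (cl in classes) {
    for (i in seq_len(n_per_class)) {
      k <- k + 1
      g <- generate_record(models[[cl]], template, noise,
                           seed = derive_seed(seed, k),
                           record_id = sprintf("SYN_%s_%03d", cl, i))
      records[[k]] <- g$record
      diags[[k]] <- g$diagnostics
    }
  }
  list(records = records, diagnostics = do.call(rbind, diags))
}

#' Generate a class-conditional Gaussian feature table
#'
#' Direct generator for the selection/classification stages: each feature is
#' Gaussian noise with SD `noise_sd`; features named in `effect` get a
#' per-class mean shift, all others are null features with zero class
#' signal.
#'
#' @param n_per_class Rows per class.
#' @param effect Named list: feature name -> numeric vector of per-class
#'   mean shifts (named by class, or in `classes` order).
#' @param noise_sd Feature noise SD.
#' @param seed Integer seed.
#' @param classes Class labels (>= 2).
#' @param n_features Total feature count; features beyond those named in
#'   `effect` are filled as `feat01`, `feat02`, ...
#' @return Data.frame of features plus a `Group` label factor column.
#' @export
generate_feature_table <- function(n_per_class, effect = list(),
                                   noise_sd = 1, seed = 1,
                                   classes = c("AFIB", "SB", "SR", "GSVT"),
                                   n_features = 20) {
  stopifnot(length(classes) >= 2, n_per_class >= 1)
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(seed)
  n <- n_per_class * length(classes)
  filler <- sprintf("feat%02d", seq_len(n_features))
  feat_names <- c(names(effect), setdiff(filler, names(effect)))
  feat_names <- feat_names[seq_len(max(n_features, length(effect)))]
  labels <- factor(rep(classes, each = n_per_class), levels = classes)
  X <- matrix(stats::rnorm(n * length(feat_names), sd = noise_sd), nrow = n,
              dimnames = list(NULL, feat_names))
  for (f in names(effect)) {
    shifts <- effect[[f]]
    if (is.null(names(shifts))) names(shifts) <- classes[seq_along(shifts)]
    X[, f] <- X[, f] + unname(shifts[as.character(labels)])
  }
  out <- as.data.frame(X)
  out$Group <- labels
  out
}
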