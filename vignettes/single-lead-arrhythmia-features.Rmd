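---
title: "Single-lead ECG arrhythmia features: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Single-lead ECG arrhythmia features: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`ecglead2` analyses 10-second, 500 Hz electrocardiograms using only lead II
(DII), the bipolar limb lead most commonly available on wearable and
single-channel devices. The pipeline runs: load records and diagnostics →
denoise lead II → compute a 38-column feature table → rank features →
quantify class separability → classify rhythms under a balanced per-class
test protocol. This vignette explains each stage's model, the tunable
parameters and their defaults, what the synthetic generator does and does
not emulate, and the numerical decisions taken where the design was open.

## Rhythm taxonomy

Records carry one of 11 rhythm codes. Three schemes are supported:

* `eleven` — the codes themselves;
* `eight` — the 11 codes minus AVNRT, SAAWR and AVRT. These three have
  fewer than 20 examples each in the large clinical cohort this layout
  models, too few for per-class testing;
* `four` — every code mapped to its major rhythm group: AFIB (atrial
  fibrillation + atrial flutter), SB (sinus bradycardia), SR (sinus rhythm
  + sinus arrhythmia), and GSVT (the supraventricular tachycardias: ST,
  SVT, AT, AVNRT, SAAWR, AVRT).

`apply_rhythm_scheme()` drops excluded codes and maps the rest; an unknown
code that is not excluded is an error rather than a silent drop.

## Denoising chain

Three length-preserving, deterministic stages, in order:

1. **Band-pass 0.5–50 Hz** (`bandpass()`). Realized as a Butterworth
   high-pass/low-pass cascade applied forward–backward (zero phase). The
   default order is 6 per section: a zero-phase 4th-order design leaves
   60 Hz attenuated by only ~15 dB, short of the 20 dB a mains-interference
   stop band needs, while an 8th-order high-pass at a 0.002 relative cutoff
   is numerically unstable under forward–backward filtering. Order 6 gives
   ~21 dB at 60 Hz with the 10 Hz passband flat within 1 dB. The signal
   mean is subtracted first, which rejects DC exactly and tames
   forward–backward edge transients.
2. **LOESS baseline removal** (`loess_baseline()`). Local-linear
   tricube-weighted smoothing (the C `lowess` implementation, zero
   robustness iterations) with the span expressed in seconds; default
   1.5 s. At that span the smoother tracks wander below roughly 0.5 Hz into
   the baseline estimate while QRS complexes (tens of milliseconds) stay in
   the residual. A local-linear fit reproduces straight-line trends
   exactly, so a linear drift is removed completely.
3. **Non-local means** (`nlm_denoise()`). Each output sample is a
   similarity-weighted average of search-window samples whose surrounding
   patches match the target's patch — this exploits the quasi-periodicity
   of ECG: every beat provides a noisy replicate of the same waveform.
   Weights are `exp(-d2/h2)` with `d2` the squared Euclidean patch distance
   and `h2 = 2 (2P+1) (0.6 σ̂)²`, where `σ̂ = median|Δx| / (0.6745 √2)` is a
   robust noise-SD estimate from first differences. Defaults: patch
   half-width 10 samples (20 ms — about a QRS half-width), search
   half-width 500 samples (1 s — at least one beat either side at any
   plausible rate; `"full"` searches the entire record at O(N²) cost). The
   self-weight is set to the maximum off-center weight, the standard remedy
   for the self-comparison's zero distance otherwise dominating the
   average. Samples whose patch does not fit inside the record are copied
   through unchanged.

All weights are nonnegative and normalized, so each output sample is a
convex combination of input samples.

## The 38-column feature table

Thirteen metadata features (age; gender coded 0 = male / 1 = female; and
the 11 vendor-computed GE-MUSE attributes: ventricular rate, atrial rate,
QRS duration, QT, QTc, R axis, T axis, QRS count, Q onset, Q offset, T
offset) are joined with 25 descriptors of the denoised lead-II signal.
MUSE attributes are trusted metadata — the package never re-detects
fiducial points. Q onset/offset/T offset are treated as opaque numeric
features since their reference grid is not defined in the source layout.

**Time domain (10).** AR (global max − min), PPA (mean over 1-s windows of
the per-window range), MA (mean |x|), MSI (median |Δx|), SignInt
(Σ|x| / fs), RMS1 (full-signal RMS), RMS2 (mean of 2-s-window RMS), MS
(mean |Δx| · fs), MdS (median signed Δx · fs), and SNEO — the Teager
energy ψ[n] = x[n]² − x[n−1]x[n+1] smoothed with an 11-sample Bartlett
window and averaged. On a pure tone of amplitude A and frequency f, ψ is
exactly A² sin²(2πf/fs), which the tests use as a closed-form oracle.

Two naming collisions in the field's usage were resolved as follows. A
"median stepping increment" and a "median increment of the Poincaré plot"
describe the same statistic up to a factor of √2 on the identity-lagged
plot, so a single MSI column is emitted (the 38-column count only balances
with one). AR and PPA are kept distinct by making AR the global range and
PPA the windowed mean range. RMS1/RMS2 and PSA/CP have no universally
fixed definitions; the package uses full-signal RMS vs 2-s windowed RMS,
and mean band power vs power at the centroid bin, respectively — explicit
stand-ins, stated here so they can be audited.

**Spectral (8).** The spectrum is a Welch-averaged modified periodogram:
2048-point Hamming-windowed segments, 50% overlap, analysis band 0.5–50 Hz
matching the filter; inputs shorter than 2048 samples become one
zero-padded segment flagged in the result. Bin width is fs/2048 ≈ 0.244 Hz
at 500 Hz. Features: AMSA (Σ|X(f)|·f — the amplitude spectrum area used in
defibrillation-outcome research), CF (power-weighted centroid), PF (argmax
power, lowest bin on ties), ENRG (Σ band power), SFM (geometric/arithmetic
mean ratio: 1 for a flat spectrum, →0 for a tone), CP (power at the bin
nearest CF), MP (max power), PSA (mean band power). An all-zero band
yields missing values, never NaN arithmetic.

**Nonlinear (7).** Hu — rescaled-range Hurst exponent over dyadic windows
16…N/4. The raw R/S slope has a well-known upward small-sample bias
(≈0.55 for white noise at N = 5000), so the default estimator applies the
Anis–Lloyd correction `0.5 + H_emp − H_AL`, which centres white noise at
0.50 and a random walk near 1; `correct = FALSE` gives the raw slope. ScE
— DFA-1 over log-spaced boxes 4…64 (0.5 for white noise, ≈1.5 for
integrated noise). LAC — log₁₀ of the summed absolute autocorrelations to
lag 50. WE — Shannon entropy of the relative subband energies of a 5-level
Daubechies-4 (8-tap) periodic pyramid DWT, normalized to [0, 1]; the
transform is implemented in-package and is verified energy-preserving.
SpeEnt — normalized spectral entropy of the band power (0 for a single
bin, exactly 1 for a uniform band). ApEn and FuzzyEn — m = 2,
r = 0.2·SD, computed on the signal decimated (anti-aliased) to 125 Hz so
the ~1250 templates of a 10-s record populate the tolerance statistics
well; FuzzyEn uses exponential membership `exp(-(d/r)²)` on
baseline-removed templates with self-matches excluded. ApEn and FuzzyEn
belong to the bank because the 25-descriptor count — and the 29-feature
subset built from it — only balances when they are included.

**Subsets.** `general4` = age, gender, ventricular rate, atrial rate;
`morph13` = the 13 metadata features; `ours29` = general4 + the 25 signal
descriptors; `all38` = everything. Descriptions of the morphological
lead-II set in the literature this models are internally inconsistent
(a "13-feature" set that enumerates 12); the registry resolves this by
defining `morph13` as the 13 metadata columns, which is the only reading
that balances the 38-column total.

Degenerate feature values (constant signal, zero band power) are stored as
missing. Imputation happens only inside classifier training, with
training-fold column medians applied to both folds: a per-class imputation
would be unusable at prediction time, when the class is unknown.

## Feature ranking

`mrmr_rank()` implements greedy MRMR on plug-in mutual information (log
base 2) after equal-frequency discretization into 10 bins — a rank-based
binning, so the ranking is invariant to strictly monotone feature
transforms and to row order. The default criterion is the MIQ quotient
(relevance / mean redundancy to the selected set), matching the common
interactive-tool implementation; MID (difference) is a flag away. Ties
break by column order; the mean redundancy is floored at 1e−12 so a
zero-redundancy candidate wins by quotient rather than dividing by zero.
Plug-in MI is biased upward at small n (roughly (r−1)(c−1)/(2N ln 2)
bits), which matters when comparing a weakly relevant candidate against a
redundant copy; at the cohort sizes used in the tests (n ≥ 400) the bias
is small relative to the planted effects.

`relieff_rank()` implements multi-class ReliefF with every observation as
an anchor (no subsampling), 10 nearest hits and misses per class under the
range-normalized Manhattan metric, and miss terms weighted by class priors
renormalized over the non-anchor classes. A class smaller than
neighbors + 1 is an error naming the class.

## Separability indices

`silhouette_mean()`, `davies_bouldin()` and `calinski_harabasz()` follow
the textbook definitions (Euclidean throughout) and are computed against
ground-truth labels — they quantify how separable the classes are in the
feature space, not the quality of any clustering. `separability_report()`
z-scores the feature matrix first (median-imputing missing entries,
zeroing constant columns with a warning) and records a standardization tag
in the report, because published index values rarely state their
preprocessing and exact reproduction can hinge on it. Coincident class
centroids make the Davies–Bouldin ratio undefined and raise an error
naming the pair. `project_2d()` provides deterministic PCA and a
seed-reproducible exact t-SNE (quadratic in n, perplexity 30 clamped to
(n−1)/3) for visualization; the embedding is pluggable via an `engine`
function and is not a quantitative surface.

## Balanced evaluation protocol

With heavily imbalanced cohorts, a fixed-percentage test split lets an
easily separable majority class inflate accuracy. `balanced_holdout()`
therefore reserves exactly n test examples per class, making chance
accuracy 1/k regardless of imbalance; `fraction_split()` provides the
80:20 variant for comparison. `run_experiment()` repeats the draw
(default 10 repetitions, seeds `seed + 0…9`) and averages accuracy,
per-class one-vs-rest AUC (computed by the Mann–Whitney rank statistic,
identical to the trapezoidal ROC area with ties counted half), and
unweighted macro precision/recall/F1 — unweighted because the balanced
test set makes weighting moot. A class never predicted gets precision 0
with a warning rather than NaN.

Classifier families are deliberate stand-ins for interactive-tool
defaults: bagged trees = 30 bootstrap-aggregated unpruned CARTs (a random
forest with `mtry = p`); narrow/wide MLP = one hidden layer of 10/100
units, 1000-iteration cap, standardized inputs (logistic units — no claim
of bit-compatibility with any other tool's ReLU networks); kNN = 10
neighbours with vote-fraction scores (implemented directly because
per-class scores are needed for one-vs-rest AUC); linear SVM with
probability outputs. Imputation and standardization statistics come from
training rows only; the test suite asserts this by corrupting a test-only
row and checking the stored statistics are unchanged.

## The synthetic cohort generator

`generate_record()` builds lead II as a sum of five Gaussian kernels
(P, Q, R, S, T) per beat, placed at beat times whose RR intervals are
i.i.d. lognormal with a class-conditional mean and coefficient of
variation. Class semantics drive the defaults (`default_rhythm_models()`):
SB 50±5 BPM regular; SR 75±8 mild variation; SA 70±8 with pronounced RR
variation; ST 120±15; SVT/AVNRT/AVRT 170–180 BPM, P waves suppressed;
AFIB 110±20 with RR CV 0.25, no P waves, and a 4–9 Hz fibrillatory
baseline; AF with 300/min sawtooth flutter waves. These parameter values
are invented fixtures chosen for class-typical plausibility — they are
documented here precisely because they are not estimates of any clinical
cohort. Noise is additive: a sub-0.5 Hz wander sinusoid, a 50 Hz powerline
tone (configurable — the modeled database originates in a 50 Hz region),
and white noise. Diagnostics are derived from generator ground truth:
ventricular rate = 60 / mean generated RR, QRS count = beats placed,
QRS/QT intervals from the template geometry with ~3% per-subject
measurement jitter (vendor measurements are never exact), age and sex
sampled. A model whose plausible RR interval is shorter than the QRS core
support is rejected as infeasible; P and T waves merging into neighbouring
beats at high rates is allowed, as it is physiologically.

The generator is a pure function of (model, template, noise, seed). What
it does **not** emulate: inter-lead vectorcardiographic consistency (the
other 11 columns are scaled copies of lead II, pure plumbing), beat
morphology variability within a record, ectopy, conduction-block wave
relationships, or realistic artefact structure (electrode pops, muscle
noise). Passing tests on synthetic cohorts therefore demonstrate that the
pipeline's machinery is correct and calibrated — not that its accuracy
numbers transfer to clinical recordings. `generate_feature_table()`
bypasses signals entirely and emits class-conditional Gaussian features
with planted mean shifts, which is the right fixture for testing selection
and classification in isolation: ground truth about which features are
informative is exact.

## Problem sizes and reproducibility

The test suite and the acceptance script run at desk scale, chosen so the
full suite completes in minutes while keeping every statistical check
well-powered: signal cohorts of 8–16 records per class, estimator
calibrations over 50 seeds at N = 5000, selection-recovery simulations
over 100 seeds at 200 rows × 20 features, and classification protocols
with 10 repetitions at 50 test examples per class. `run_pipeline()` fans a
single global seed out to per-stage seeds through a counter-based
derivation (`derive_seed()`), keeping every derived seed a valid 32-bit
integer; identical configurations produce byte-identical JSON reports, and
every output embeds an MD5 hash of the full configuration.

## Known limitations

* The package reads the per-record CSV layout only; it does not download
  or parse WFDB archives.
* Real-cohort reproduction (class counts in the thousands, separability
  indices of a 10,646-row table) requires the external database; nothing
  in the package fabricates those numbers.
* The classifier stand-ins match other tools' defaults in spirit, not
  bit-for-bit; accuracy comparisons against published figures are soft.
* Exact t-SNE is quadratic in n and intended for cohorts of at most a few
  thousand rows.
* MUSE attributes are taken on trust; a corrupted diagnostics file
  propagates into the metadata features unchecked beyond schema
  validation.
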