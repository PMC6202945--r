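---
title: "pdmotor: models, defaults and design decisions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{pdmotor: models, defaults and design decisions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

This vignette is the package's own account of its science: what each stage
assumes, which tunable parameters matter and why their defaults are what
they are, what the synthetic-data generator does and does not emulate, and
the choices we made where the design was genuinely open. It states no
empirical result that the test suite does not itself compute.

## 1. The pipeline

One *session* is a participant performing seven tasks in succession:
sustained phonation, balance, gait, alternating finger tapping, noncued
simple reaction time, rest tremor and postural tremor. The pipeline is

1. session assembly and segmentation/QC (`assemble_sessions()`,
   `segment_task()`),
2. extraction of a fixed 998-feature battery (`extract_features()`),
3. per-contrast feature ranking by a five-algorithm ensemble with
   majority voting (`rank_features()`, `majority_vote()`),
4. class-balanced random-forest cross-validation with
   sensitivity/specificity summaries, a randomized-prediction null, a
   feature-count sweep and a train/validation mismatch diagnostic
   (`run_cv()` and friends),
5. reporting (`task_salience()`, `render_report()`).

Sensitivity is the recall of the disease class: iRBD or PD against
control, and PD in the iRBD-vs-PD contrast. This positive-class
convention is a package decision (the convention is not dictated by the
problem) and is fixed everywhere, including the balanced subsampling and
the randomized baseline.

## 2. Session assembly and segmentation

Real deployments upload per-task recordings independently, so sessions
must be reassembled by timestamp. A session is emitted iff all seven
tasks by one subject occur in protocol order within a window (default 30
minutes), matched greedily nearest-in-time; partial sets are dropped and
counted. The window length, the protocol-order requirement, and all QC
thresholds below are conservative defaults of this package — the study
this design follows did not publish its segmentation algorithm — and every
one is exposed as an argument:

* voice: frame-RMS silence gate at 10% of the median active-frame RMS,
  keep the longest voiced run, fail under 1 s;
* IMU: drop the first and last 2 s (pocket/hand placement transients),
  fail if under 5 s remain or an axis is constant ("flat signal" — a
  phone on the table);
* events: drop taps/reactions in the first second.

Segmentation never extends a signal and is idempotent (a segmented
payload is tagged and passes through unchanged).

## 3. The 998-feature battery

The published total (330 voice + 60 tapping + 20 reaction + 4×147 IMU =
998) is treated as a fixed contract; the concrete catalog within each
total is a reconstruction from the standard dysphonia-measure and
accelerometry literature, because the original per-feature tables are not
public. Extractors always emit their full named block; a failed
precondition (under 10 taps, under 5 valid reaction trials, under 50%
voiced frames, failed QC) yields `NA` for the whole block rather than a
shorter vector.

**Voice (330).** An autocorrelation pitch tracker (40 ms frames, 10 ms
hop, 50–500 Hz, parabolic peak interpolation) defines voiced frames;
cycle marks are picked on the fundamental-band signal (0.6–1.5 × median
f0, brick-wall FFT band-pass) and refined by parabolic interpolation, so
cycle periods are sub-sample accurate — without this, sampling-grid
quantization alone would add ~0.3% fake jitter at 16 kHz. Jitter and
shimmer use the Praat-style local definitions on cycle periods and
endpoint-inclusive per-cycle peak amplitudes (the inclusive window makes
the amplitude multiset exactly symmetric under time reversal). Frame
harmonicity is the unbiased autocorrelation at the pitch lag — the
rectangular-window taper `(n-lag)/n` must be divided out or HNR is biased
low by several dB; the per-frame noise-to-harmonic ratios are averaged in
the *power* domain before conversion to dB because the dB mapping is
convex and heavy-tailed upward. PPE whitens the semitone f0 contour with
an AR(1) fit and takes the normalized entropy of a fixed 30-bin histogram
over ±6 semitones; RPDE embeds a ~2 kHz-decimated 2 s excerpt (m = 4,
τ = 2, ε = 0.12 on the standardized signal); DFA uses log-spaced boxes of
50–1000 samples on the raw waveform. VFER and the glottal-quotient proxy
work on the order-12 LPC residual (Levinson–Durbin). MFCCs are the
conventional 26-filter mel bank, 13 coefficients plus frame deltas, each
summarized by mean/SD/skew/kurtosis. Vocal tremor is 3–15 Hz modulation
power/frequency/entropy of the f0 contour and the amplitude envelope.
The wavelet block is a 6-level Haar analysis of those same two series
(log-energy, entropy, Teager–Kaiser statistics per level, plus level-
energy summaries).

**IMU (147 × 4).** Each task yields four signals: the three axes and the
vector magnitude, all detrended by a 0.25 Hz brick-wall high-pass that
removes gravity and slow orientation drift. Five categories: time-domain
statistics; Welch spectra (4 s Hann, 50% overlap) with band powers
0.5–3, 3–8 (tremor), 8–12 and 12–20 Hz, relative tremor-band power,
dominant frequency and prominence, spectral centroid/spread/entropy and
the 95% edge frequency; nonlinear measures (sample entropy m = 2,
r = 0.2·SD per accelerometry convention, Higuchi fractal dimension, DFA,
recurrence rate, autocorrelation decay); jerk measures including a
negated log dimensionless jerk smoothness; and cross-axis measures
(correlations, 16-bin mutual information, covariance eigenvalue ratios
and axis energy fractions). For gait, the dominant-frequency slot is the
cadence estimate, taken from the strongest autocorrelation peak of the
rectified, smoothed step-impulse envelope in the 0.25–2 s lag range — the
raw PSD peak sits on the step-impulse resonance and the raw
autocorrelation is dominated by slow sway, so neither reads out cadence.
Magnitude-signal features are invariant to any fixed axis rotation.

**Tapping (60) and reaction (20).** Inter-tap-interval statistics with a
drift line (hastening < 0), freezing (> 2× median) and hastening (< ½
median) counts, alternation failures, and a first-half/second-half
fatigue block; spatially, distance-to-center, travel, scatter, hit
fraction and centroid drift per button. Reaction features summarize press
and release latencies separately (the study does not say whether they
were pooled; we keep both) plus a 0.5 s lapse fraction and 0.1 s
anticipation fraction — conventional simple-RT bounds, stated nowhere in
the source.

## 4. Feature selection

Rankings are computed per contrast on standardized (train-only z-scored)
features. The five algorithms: LASSO ranks by order of entry along the
L1-penalized logistic path (never-entered features by absolute
correlation); mRMR greedily maximizes label mutual information minus mean
redundancy on 10 equal-frequency bins; RELIEF uses k = 10 nearest
hits/misses; GSO selects forward by absolute correlation and
Gram–Schmidt-residualizes the remainder each step; LLBFS learns
nonnegative feature weights on a probabilistic nearest-hit/miss margin
with a logistic loss. The source names only four algorithms; the fifth is
unstated and we chose RELIEF as the standard companion in this
methodology. Sequential algorithms run to a greedy depth (default 60 in
standalone ranking, 40 inside CV); past it, features keep the algorithm's
saturation-time score — with ties always broken by column order, so every
ranking is a full permutation. Constant columns are ranked last by every
algorithm.

"Majority voting" is concretized as the median of the five ranks, ties by
mean rank, then best single rank, then column order (the cited recipe is
not reproduced in the source; the rule is isolated in `majority_vote()`
so alternatives are pluggable).

## 5. Cross-validation and its hygiene

At each repetition the two contrast groups are first downsampled to the
minority recording count (balanced subsampling), then split: `kfold10`
partitions into 10 folds, `loso` holds out each subject once, `loo` holds
out one random recording (with an optional first-recording-per-subject
mode). *Within every iteration*, imputation medians, standardization
moments, the feature ranking and the forest are all fitted on the
training split only; the held-out split flows through the fitted
transforms into predictions and nothing else. The test suite enforces
this with a mutation test: corrupting the validation split's features and
labels must leave every training artifact bit-identical.

Missing features are filled with training-column medians (the source
mentions imputation without a method; median is the robust default); an
all-missing column is zero-filled with a warning. The classifier is a
random forest — 500 Gini CART trees on bootstrap samples with √p features
per split, compiled in C++ because no forest implementation is available
in the deployment environment; size and mtry are configurable. Undefined
rates (a validation fold without one class) are recorded as missing and
excluded from means/SDs with a count — scoring them 0 would bias the
summaries downward.

The randomized baseline predicts uniformly at random on the same splits;
real-vs-random per-iteration accuracies are compared with a two-sided
asymptotic Kolmogorov–Smirnov test. The feature-count sweep evaluates
n = 2, 4, …, 30 (15 points, higher-ranked features first); since the
training split of an iteration does not change with n, the ranking is
fitted once per iteration and only the forest is retrained per count.
The mismatch diagnostic reports, per feature, the percentage of
validation values outside the training min–max range; above a 25% mean
(configurable) the scheme is flagged statistically unreliable — with
repeated sessions per subject and stable subject signatures, LOSO shows
systematically higher mismatch than 10-fold, which is the expected
subject-identity effect, and the flag is how the package surfaces it.

Everything is a pure function of the supplied seed: cohort generation,
subsampling, folds, the forest, and the baseline. Derived seeds stay
below 2^31.

## 6. What the generator emulates — and what it does not

The generator states a world; it is not calibrated to any clinical
dataset (the source reports no per-task effect sizes, and its recordings
are access-controlled). Documented defaults, with the PD-vs-control
deltas applied at one third magnitude for iRBD:

| dial | control | PD | carries |
|---|---|---|---|
| jitter_frac | 0.005 | 0.018 | cycle-period CV of phonation |
| shimmer_frac | 0.03 | 0.09 | cycle-amplitude CV |
| hnr_db | 25 | 14 | additive-noise floor (dB) |
| tremor_amp rest/postural (m/s²) | 0.02 | 0.9 / 0.7 | 3–8 Hz oscillation |
| tremor_freq_hz | 5 | 5 | within the 3–8 Hz band |
| sway_rms_ms2 | 0.05 | 0.14 | pink-noise sway per axis |
| cadence_hz | 1.9 | 1.55 | gait step rate |
| iti_mean_s / iti_cv | 0.35 / 0.08 | 0.55 / 0.22 | tapping slowing/variability |
| iti_drift | 0 | −0.0015 | hastening |
| tap_scatter_px | 12 | 28 | spatial accuracy |
| rt_mu_s / rt_sigma_s / rt_tau_s | 0.30/0.04/0.06 | 0.38/0.07/0.12 | ex-Gaussian latency |

Magnitudes are round numbers in physiologically plausible ranges chosen
once, before any acceptance measurement, to make the PD contrast clearly
separable and the iRBD contrast intermediate. Mechanics: voice is a
five-harmonic source with fixed rolloff, built cycle by cycle (so planted
jitter/shimmer are exact), plus white noise scaled to the target HNR;
sway is 1/f (pink) noise, the standard posturography assumption; tremor
is a slowly amplitude-modulated sinusoid projected on all three axes (a
tremor orthogonal to gravity would vanish from the magnitude signal to
first order); gait is a decaying-impulse train with 2% interval jitter;
tapping intervals follow `iti_mean·(1 + drift·k)` times mean-one
lognormal noise; latencies are ex-Gaussian with rejection of non-positive
draws. Subjects get a stable lognormal signature on the positive dials
(`subject_cv`, default 0.12) and their own baseline f0; session counts
are Poisson truncated at one; task start times are spaced 10–60 s so
assembly windows are exercised.

Not emulated: real vowel acoustics and formant structure, smartphone
sensor quirks (clock drift, dropped samples), medication ON/OFF cycles,
and any claim about clinical effect sizes. A green discrimination test
therefore establishes that the pipeline recovers what the generator
plants at the stated magnitudes — no more.

**The null configuration.** `null_cohort_config()` gives all three groups
the control parameters *and* removes every stable subject signature
(`subject_cv = 0`, under which the per-subject fundamental frequency is
also redrawn per session). The second part matters: the chance-level
expectation for cross-validated accuracy assumes recordings are
exchangeable across labels. With stable subject signatures and repeated
sessions, a classifier scores above chance on a zero-effect cohort simply
by recognizing subjects — a real confound, not a bug, and exactly what
the LOSO mismatch diagnostic is designed to expose. The null
configuration is for calibrating the no-signal case, so it removes that
channel by construction, making recordings exchangeable for any session
count.

## 7. Numerical choices and degenerate inputs

* Brick-wall FFT filters throughout (high-pass detrend, fundamental-band
  pass): zero-phase, exactly reversal-symmetric, and adequate for
  long-enough segments; not suitable for streaming.
* Welch band powers partition total power exactly (one-sided density,
  `sum(psd)·df` = windowed variance), so the Parseval check is testable
  at 1e-6 on toy signals.
* Equal-frequency binning for mRMR collapses gracefully on ties; mutual
  information uses plug-in estimates (consistent with the small-n
  regime; no bias correction).
* Degenerate folds: single-class validation folds record missing rates;
  constant columns are z-scored to zero and ranked last; eigenvalue
  ratios guard against zero denominators; all-missing columns impute to
  zero with a warning.
* Sub-sample cycle marks cap the parabolic offset at ±0.5 sample;
  non-positive ex-Gaussian draws are rejected and redrawn (bounded
  retries).
* Runtime scaling in tests shortens task *durations* only; generator
  effect sizes, acceptance thresholds and seeds are never adjusted to
  test outcomes.

## 8. Known limitations

* The 998-name catalog is a documented reconstruction; one-to-one
  correspondence with the unpublished original tables cannot be
  verified, only the per-task totals.
* The fifth selection algorithm and the exact majority-voting recipe are
  package choices (flagged above); both are isolated behind single
  functions.
* The segmentation gate is a stand-in for an unpublished algorithm.
* LOSO with per-iteration re-ranking over hundreds of subjects is
  expensive; `repetitions` and greedy depth are the intended controls.
* The asymptotic KS p-value is approximate in the presence of ties
  (per-iteration accuracies are discrete); at the sample sizes used for
  the separable/null comparisons the conclusion is robust to this.
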