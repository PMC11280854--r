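---
title: "signstream: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{signstream: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

This vignette is the package's own account of its science: the device and
signal model, the segmentation and feature-extraction procedures with every
tunable parameter, what the synthetic-data generator does and does not
emulate, the numerical choices, and the design decisions taken where the
problem was genuinely open. It states no empirical result that the test
suite does not itself compute.

## 1. Device and data model

Two forearm armbands, each with eight dry sEMG electrodes sampled at 200 Hz
(integer amplitudes in [−127, 128]) and a nine-axis IMU emitting one
10-value frame at 50 Hz: accelerometer (x, y, z) in units of g, gyroscope
(x, y, z) in rad/s, and a sensor-fused orientation quaternion (w, x, y, z).
One second of a two-armband recording therefore stores
2 × (8·200 + 10·50) = 4200 raw scalars — the bookkeeping identity the tests
assert exactly.

Orientation handling assumes the intrinsic Z–Y–X (yaw–pitch–roll)
convention: the quaternion of Euler angles (α, β, γ) is the product
q_z(γ) q_y(β) q_x(α), whose components expand to the familiar
cos/sin half-angle composition. The inverse conversion canonicalizes roll
and yaw into (−180°, 180°] and pitch into [−90°, 90°]; at gimbal lock
(|sin β| within 1e−6 of 1) roll is set to 0 and yaw absorbs the remaining
degree of freedom, which preserves the rotation (the round-trip test checks
quaternion equality up to global sign at 1e−9). Angles are stored in
degrees everywhere — the segmenter threshold is specified in degrees — and
converted to radians only inside trigonometric calls.

## 2. Segmentation

Motion is a frame-pair predicate evaluated per sensor per arm:

* **EMG**: the largest absolute frame-to-frame change over the 8 channels
  is **≥ threshold** (default 40 on the 256-wide device range). The
  comparator is inclusive because a change *of* the threshold value counts
  as motion.
* **IMU**: the three Euler angles are differenced wrap-aware (signed
  shortest distance) and motion is `|mean(Δα, Δβ, Δγ)| > threshold`
  (default 20°, strict). This is the *literal* reading of the rule and lets
  opposite-sign changes cancel (+30°, −30°, 0 → no motion); the
  mean-of-absolutes alternative is available as `imu_mean_abs = TRUE` in
  `segmenter_config()`, since the literal form is arguably an artifact of
  prose rather than intent. The default stays literal.

A segment opens at the first frame where any predicate fires (either
sensor, either arm — an OR, as the start rule) and closes when **no**
predicate fires anywhere for more than `pause_ms` of wall time — global
quiet across both arms and both sensors, the complement of the OR'd start.
At 200 Hz and the default 60 ms pause this is exactly 12 consecutive quiet
EMG frames, a derived identity the acceptance suite checks behaviorally
(12 quiet frames end a sign, 11 do not). The pause is configurable in
[20, 1000] ms. Segments shorter than `min_record_s` (default 0.4 s — short
inputs make several estimators unstable) are discarded with a warning
rather than raising an error: the option exists precisely to prevent
downstream failures. Sample slices use half-open `[start, end)` intervals;
`end` is the last motion time plus one EMG frame. Segmentation is causal
(boundaries depend only on samples up to `end + pause`) and invariant to
appending quiet frames, both property-tested, and an O(T·C) brute-force
re-scan of the predicates reproduces the boundaries exactly on seeded
sessions.

## 3. The synthetic world

The human dataset behind the original study (80 signs × 10 repetitions,
one subject) is access-restricted, so the generator emulates its *stated*
conditions; its defaults are the stated world, chosen once:

* **EMG**: per channel, an activation envelope (a baseline plateau plus
  1–3 Gaussian bumps with seeded centers, widths and amplitudes) multiplies
  an alternating ±1 carrier; Gaussian noise of standard deviation
  `noise_level` (in EMG units; 8 is the "moderate" default — roughly 1/6 of
  a typical envelope amplitude) is added, and the result is rounded and
  clipped to [−127, 128]. Amplitude-modulated noise is the standard
  first-order model of sEMG; the alternating carrier makes the
  frame-to-frame delta equal twice the envelope, so sign onsets/offsets
  step past the EMG threshold within one 5 ms frame and segmentation
  oracle tests are sharp rather than flaky. Channel 1 of each arm carries
  a strong plateau (48–64) to guarantee that property; the remaining
  channels are free to be subtle.
* **IMU**: orientation follows spherical-linear interpolation through 2–4
  seeded Euler waypoints with smoothstep easing (zero angular velocity at
  waypoints, hence continuous splices into rests); the gyroscope is the
  finite-difference angular rate of that trajectory and the accelerometer
  is gravity rotated into the sensor frame, both plus small noise.
* **Sessions** place recordings between rest blocks in which EMG is
  constant zero and the pose is held — *exactly* quiet, so no threshold
  floor can fire and end-to-end segmentation tests are deterministic.
* **Speed**: each recording in a dataset gets a speed factor drawn from
  0.8–1.25 (sign duration varies with the signer's state; no range is
  stated anywhere, so this one is fixed here once); durations are rounded
  to the 20 ms IMU grid so both sampling lattices stay aligned. Template
  nominal durations are 0.9–1.5 s.

What the generator does **not** emulate: muscle-specific spectral shapes,
electrode lift/motion artifacts, inter-subject variability, co-articulation
between consecutive signs, or any claim about real sign amplitude
statistics. Consequently a green classification test establishes that
segmentation, featurization and evaluation are correct and deterministic —
not that real signers are separable at these accuracies. On this synthetic
regime the classes are well separated: 10-fold cross-validation reaches
100% for both random forest and 1-NN, and the per-sign split protocol
saturates near 100% for every training size, so the required
"nondecreasing in training repetitions" trend holds in its degenerate form.

## 4. The 1044-feature vector

The total — 1044 per segment — is fixed; the per-channel partition is a
reconstruction constrained by that total (no itemization exists), and the
registry makes it testable:

| group | channels | features | subtotal |
|---|---|---|---|
| EMG | 16 | 46 | 736 |
| accelerometer + gyroscope | 12 | 17 | 204 |
| orientation quaternion | 8 | 13 | 104 |

The 46 EMG features are the full bank: MAV, IEMG, Higuchi and Petrosian
fractal dimensions, DFA α, Teager–Kaiser nonlinear energy, least-squares
slope (per second), line length, Willison amplitude, population SD,
min/max, Hurst exponent, strict local minima/maxima counts, moment skewness
and excess kurtosis, zero-crossing rates of the signal and its first two
differences, RMS, inactive-sample count, Hjorth mobility/activity/
complexity, eight periodogram statistics (peak, median, modified median,
modified mean, intensity-weighted mean and bandwidth, total spectrum, mean
power), wavelet detail energy, AR coefficients and prediction errors at
orders 1, 2, 4, 8, and Shannon/spectral/SVD/Fisher entropies. The 50 Hz
channels receive only estimators stable at ≥ 20 samples (the 0.4 s
minimum): the 17-feature set for accelerometer/gyroscope axes and a
13-feature set (no spectral/histogram terms) for quaternion components.
Names are `device.channel.feature` (e.g. `left.emg1.mav`); the ordered
registry is `feature_registry()` and its FNV-1a hash is embedded in model
files so a model refuses a mismatched feature layout.

Parameter choices, with defaults:

* **WAMP threshold θ = 10 EMG units** (no value is stated anywhere;
  configurable). The same θ applies to the IMU channels for uniformity,
  where it is effectively an upper-outlier counter — accel/gyro deltas
  rarely reach 10 in their native units.
* **Shannon histogram**: 64 fixed-width bins over the channel's native
  range — [−127, 128] for EMG, the observed segment range otherwise;
  natural log; empty bins skipped.
* **Spectral features**: one-sided periodogram `|X_k|²/N` with DC
  included; "modified" median/mean frequencies use the amplitude spectrum
  |X| instead of power (the standard sEMG-literature variant; no
  definition is given elsewhere).
* **Wavelet**: Daubechies-4 (4 vanishing moments, 8 taps), periodized
  orthogonal DWT, 4 levels, reported as the single total detail energy.
  The continuous transform of the formula is realized as the standard
  discrete decomposition since it is used only as a feature. Periodization
  keeps Parseval exact (energy-conservation-tested at 1e−9); descent stops
  early on odd/short levels.
* **AR features**: Levinson–Durbin on the biased autocorrelation of the
  demeaned signal; "coefficient p" is the *first* coefficient of the
  order-p fit, "error p" its final prediction-error variance (so the error
  is nonincreasing in order by construction).
* **Hurst**: rescaled-range regression with the Anis–Lloyd–Peters
  small-sample correction (H = 0.5 + slope of log R/S − log E[R/S]). The
  raw R/S slope is biased upward ~0.05–0.1 at these lengths and would make
  the white-noise calibration band [0.45, 0.55] unmeetable for reasons
  that have nothing to do with the signal; the corrected estimator is the
  textbook remedy, not a tuned one.
* **DFA**: profile cumsum, linear detrending, ~10 log-spaced box sizes
  from 4 to N/4.
* **Degenerate-input policy**: any feature undefined on a constant or
  too-short channel returns the sentinel **0** — never NaN/Inf and never
  an exception once a segment has passed the minimum-duration gate. The
  extractor additionally zero-fills any non-finite value defensively.

## 5. Classification and evaluation

No classifier library ships with the target environment, so the five
algorithms are self-contained implementations behind one interface
(`classifier_spec()` / `fit_classifier()` / `predict`):

* **knn** (default k = 3, the interactive default elsewhere): Euclidean
  distance; vote ties broken by smallest mean distance to the tied class,
  then lowest class index.
* **random_forest** (100 trees by default): bagged CART trees, `⌊√p⌋`
  features re-drawn at every node, 8 quantile candidate thresholds per
  feature scored by weighted Gini impurity, grown to purity; prediction
  averages leaf class frequencies. Quantile (histogram-style) candidate
  splits are a standard large-p economization; on this problem the
  accuracy is indistinguishable from exhaustive splits and the acceptance
  run uses 30 trees purely for runtime.
* **mlp**: one hidden tanh layer (32 units), softmax output,
  cross-entropy, full-batch gradient descent with momentum 0.9.
* **naive_bayes**: Gaussian, per-class means/variances with a variance
  floor.
* **svm**: linear one-vs-rest with batch subgradient descent on the hinge
  loss (Pegasos-style step sizes); probabilities via softmax over margins.

Features are z-scored with training-set statistics before every algorithm
(whether the original system standardized is unknown; with feature scales
spanning orders of magnitude the distance- and margin-based methods
require it, and it is harmless to the others). The statistics are stored
in the model, so standardization is always "training-fold only" under
cross-validation. All stochastic training receives the run seed;
everything is deterministic given (spec, data, seed).

Protocols: stratified seeded 10-fold cross-validation (plain folds, with a
message, if a class has fewer than k examples) pooling per-fold test
predictions into one confusion matrix; and the per-sign split protocol
(n_train drawn without replacement per sign, n_test from the remainder).
Metrics: accuracy from the pooled confusion matrix; Cohen's kappa
(p_o − p_e)/(1 − p_e) with the convention κ = 1 when p_e = p_o = 1; and
the Weka-style RMSE over instance-class probability cells, which is
√((C−1))/C for uniform rows (0.5 at C = 2). The "deep learning" entry of
the original comparison is not reproduced — no architecture is specified —
but the algorithm registry is a plain switch, extensible in one place.

## 6. Storage and interoperability

A dataset directory holds `dictionary.json`, `recordings.jsonl` (one
recording per line, full-precision numbers) and `features.csv`
(1044 registry columns + `label`). Writers are deterministic; integers
round-trip exactly and reals to better than 1e−12 (numbers are printed at
full precision). Dictionaries import from UTF-8 text (one word per line,
duplicates rejected with line numbers; replacing a dictionary that has
records requires an explicit `confirm = TRUE` because it deletes them).
ARFF export writes 1044 numeric attributes plus one nominal class
attribute with single-quoted values; the package includes a reader for its
own subset and the test suite additionally parses the export with
scipy.io.arff as an independent oracle. Model files are RDS wrappers
embedding algorithm, parameters, seed, standardization statistics and the
registry hash; prediction against a mismatched registry is refused before
any streaming starts.

## 7. Known limitations

* The per-channel feature partition reproduces the printed total (1044),
  not a published itemization; treat per-group counts as this package's
  convention.
* The synthetic generator's amplitude statistics are placeholders, not
  measurements of sign language; accuracy figures on synthetic data do not
  transfer to humans.
* The IMU motion rule is implemented literally (absolute mean of changes),
  so symmetric angle changes cancel; flip `imu_mean_abs` if that matters
  for your data.
* Real-time latency is logged by `cmd_recognize()` but never asserted:
  it is hardware-dependent.
* The linear SVM is one-vs-rest with a softmax over margins for
  probabilities; it is the weakest of the five on overlapping classes and
  included for protocol completeness.
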