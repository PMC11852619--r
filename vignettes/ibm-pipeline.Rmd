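---
title: "Measuring involuntary breathing movements: model, pipeline and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring involuntary breathing movements: model, pipeline and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ibmkit)
```

## The measurement problem

During a prolonged breath hold the urge to breathe eventually produces
involuntary contractions of the diaphragm and intercostal muscles —
involuntary breathing movements (IBMs). The hold divides into an *easy
phase* with no IBMs, the *physiological breaking point* at the first IBM,
a *struggle phase* in which IBMs grow in rate and magnitude, and the
*conventional breaking point* when breathing resumes. A differential
accelerometer — xiphoid process minus sternum, both on the midsagittal
plane — captures these chest-wall movements while cancelling postural
motion that is common to both sites. The logger averages the differential
in 10-sample blocks (roughly 1000 Hz down to a 100 Hz record) and writes
4-column CSV lines (`tick,diff_accel,heart_rate,spo2`) with
interrupt-counter timestamps; pulse-oximeter columns update at 1 Hz at
best and are frequently missing, so they are encoded as empty fields,
never zeros.

## What the simulator emulates — and what it does not

Human-subject recordings of this kind are not generally redistributable,
so `ibmkit` treats the simulator as a first-class, tested component. Its
defaults are the study conditions the pipeline is designed for:

* **Phases** (`pre_hold_s = 30`, `easy_s = 100`, `struggle_s = 80`):
  mirror a pilot recording in which the hold started ~30 s into
  acquisition, the struggle phase began ~100 s later, and the subject
  sustained roughly 80 s of struggle. The recording ends at the
  conventional breaking point.
* **Cardiac component**: a pure sinusoid at `cardiac_freq = 2.09` Hz
  (~125 BPM, an elevated apnea heart rate). It is deliberately coupled
  *unequally* to the two sites (`xiphoid_cardiac_gain = 1`,
  `sternum_cardiac_gain = 0.3`): the heart sits closer to the xiphoid
  sensor, and an equal-gain model would cancel the cardiac tone in the
  differential — contradicting the clean cardiac peak that real
  differential recordings show in the easy phase. The difference of two
  in-phase sinusoids of unequal gain is still a sinusoid, so the model
  stays minimal.
* **IBM bursts**: raised-cosine (Hann) pulses of width
  `ibm_burst_width_s = 0.5` s. Burst morphology is not standardized in
  the literature; a Hann pulse is smooth, compactly supported, and has a
  predictable spectrum, which makes ground-truth spectral checks exact.
  Event rate and peak amplitude grow linearly across the struggle phase
  (`ibm_f0_start = 0.6 → ibm_f0_end = 0.75` Hz; amplitudes 1 → 3 in
  arbitrary sensor units, several times the cardiac amplitude, as IBMs
  dominate the raw trace). The first event *is* the physiological
  breaking point. A fixed-rate option (`ibm_f0_start = ibm_f0_end =
  0.68`) puts the burst-train fundamental at a known bin for spectral
  tests, with its first harmonic at ~1.36 Hz.
* **Postural artifacts**: raised-cosine disturbances added *identically*
  to both sites (common mode). The default places one 3 s adjustment in
  the pre-hold interval. The force-plate companion trace
  (`simulate_force_plate()`) shows these events with inverted sign —
  a subject arching off the plate unloads it while lifting the chest
  sensors — and shares the IBM event times exactly.
* **Noise**: independent white Gaussian noise per site
  (`noise_sd = 0.05`), reduced by √10 by the logger's block averaging.

What the generator does **not** model: breath-by-breath respiratory
motion before the hold, heart-rate variability and cardiac waveform
morphology (a single tone stands in for the seismocardiographic
complex), nonstationary IBM shapes, sensor nonlinearity, clock drift,
and any biomechanics of the thorax. Passing tests therefore demonstrate
that the pipeline recovers the *structure* this model encodes —
landmarks, spectral peaks, trend growth, common-mode rejection — not
that it is validated on real physiology. IBM amplitudes are arbitrary
sensor units throughout; no claim about physical acceleration magnitudes
is made.

## Pipeline stages and parameter choices

`analyze_recording()` runs, in order: truncation → anti-alias lowpass +
decimation (only when the input rate exceeds the 100 Hz working rate; a
log already at 100 Hz skips both, since a 50 Hz corner is not meaningful
at a 100 Hz rate) → easy-phase normalization → per-phase FFT → bandpass →
squaring → SSA trend → spectrogram → phase segmentation. All report
times are seconds from the hold start; the conversion from
acquisition-start time happens once, at report assembly.

**Zero-phase Butterworth filters.** "12th-order lowpass (50 Hz)" and
"5th-order bandpass (0.5–3.5 Hz)" are *design* orders, applied forward
and backward (`filtfilt` style), so the effective magnitude response is
the squared design response and the net phase is zero. High-order
designs are factored into cascaded biquads — the expanded polynomial
form of a 12th-order filter is numerically unreliable in double
precision — and each pass initializes every section at its steady-state
response to the first sample. Edges are extended by odd reflection of
one settle length (`3 × order × rate / corner` samples, the corner being
the lowest one for a bandpass) before filtering; as in any
reflection-padded forward-backward filter, samples within roughly one
settle length of the record ends are less attenuated than the interior,
so tests and downstream consumers evaluate attenuation claims on the
interior.

**Normalization.** The easy-phase window for `mean(y_easy)` must be
supplied explicitly (`easy_baseline_s`, default the first 20 s after the
hold start): how such windows are chosen on real data is an experimental
decision, not something the pipeline can infer. The denominator is the
maximum *absolute* deviation, so the normalized signal is bipolar in
[−1, 1] with at least one sample at ±1; a constant record equal to its
baseline mean is rejected as an error rather than returning NaN.
`baseline_mean` and `scale` are retained so the transform inverts.

**Spectra.** Whole-phase FFTs use a rectangular window (the phases are
long and the components near-stationary within a phase, so leakage is
acceptable and amplitudes stay directly interpretable); the amplitude
convention — unit tone at a bin center gives amplitude 1 — makes tests
exact. Spectrogram slices use a Hann window (default 10 s, 50 %
overlap): short slices are effectively windowed data where leakage
matters. Peak finding reports local maxima with a topographic-prominence
floor (5 % of the in-band maximum), ties broken toward the lower
frequency. Heart-rate conversion rounds `60 f` to the nearest integer,
halves away from zero.

**SSA trend.** The envelope is block-averaged to `trend_rate = 10` Hz
before SSA. This is the package's own choice of problem size: the
embedding window must span several IBM periods (default
`trend_window_s = 20` s, capped at half the series), and a 20 s window
at 10 Hz gives a 200-row trajectory matrix whose exact SVD is fast and
reproducible, while the trend of interest lives far below 1 Hz.
Grouping is automatic: components whose dominant FFT frequency is below
`trend_cutoff = 0.1` Hz form the trend `L`; remaining components holding
at least `energy_floor = 0.05` of the squared-singular-value energy form
`S`; the rest is `R`. Automatic grouping trades some flexibility of
interactive eigentriple pairing for strict reproducibility. Every
grouping partitions all elementary components, so `L + S + R`
reconstructs the input to floating-point accuracy — this additivity is
asserted, not assumed.

**Breaking-point detection.** The landmark that practitioners annotate
by eye is made algorithmic: the squared band-passed envelope, smoothed
by a centered 2 s moving average, must exceed
`mean + k·sd` (`detect_k = 3`) of the easy-phase baseline continuously
for `detect_dwell_s = 2` s. The dwell requirement rejects single
transients (e.g. a postural spike); the 2 s smoothing bridges the gaps
between early IBM bursts (~1.5 s apart) so the dwell test holds from the
first burst. Detection runs on this short-window envelope rather than on
the SSA trend deliberately: the 20 s SSA embedding smears the onset by
several seconds, which would defeat a ±2 s landmark contract, while the
2 s smoother locates the onset to within about one smoothing half-width
(detections land ~1–1.5 s early on simulated data, inside the ±2 s
contract). The SSA trend is still computed and reported — it is the
magnitude trendline, not the onset detector. The conventional breaking
point is taken as the end of the record (an input marker, not detected
from signal).

## Numerical and degenerate-input decisions

* Ticks are milliseconds by default (`tick_rate = 1000`); gap tolerance
  in `to_uniform_series()` is ±5 % of the nominal period, a single
  dropped sample is repaired by neighbor-mean interpolation, anything
  larger is an error listing the gap positions — silent resampling of
  corrupt logs is worse than failure.
* Decimation keeps sample index 0; the retained-grid phase is a free
  convention and is fixed for reproducibility.
* `write_log()` prints each value with the shortest decimal
  representation that parses back to the same double, so
  write → read → write is a byte-identical fixed point.
* SSA eigenvalues are the squared singular values of the trajectory
  matrix; their sum equals its squared Frobenius norm (asserted to
  1e-9 relative). Components are reconstructed by FFT-based
  convolution of the singular-vector pairs, which equals anti-diagonal
  averaging exactly; a naive reference implementation cross-checks this
  on short series.
* Degenerate singular values (e.g. the two components of a pure tone)
  make individual singular vectors rotation-ambiguous; comparisons are
  therefore made on sums over groups of equal singular values.

## Test problem sizes

Module and acceptance tests simulate 90 s recordings (10 s pre-hold,
40 s easy, 40 s struggle) at the full 1000 Hz raw rate — long enough for
sub-0.7 Hz spectral resolution and a meaningful struggle trend, small
enough that the whole suite (including a 20-seed landmark-recovery
study) completes in well under a minute. The defaults of `sim_config()`
remain the longer study-condition durations.

## Known limitations

* The detector assumes the easy-phase baseline window is IBM-free; an
  early IBM inside `easy_baseline_s` inflates the threshold and delays
  detection.
* Phase spectra inherit the detected breaking point, so a detection
  error shifts the FFT windows by the same amount (at most a bin's worth
  of peak movement for the long phases used here).
* SSA trend values within about one embedding window of the record edges
  are extrapolations of the diagonal averaging and should not be
  over-interpreted.
* The CSV reader is strict by design: it accepts the logger's dialect
  (with or without a header), not arbitrary delimited files.
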