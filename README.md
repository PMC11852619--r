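# ibmkit

Tools for measuring **involuntary breathing movements (IBMs)** — the
diaphragm and intercostal contractions that appear late in a maximal
breath hold — from a chest-worn *differential accelerometer*: two
single-axis accelerometers placed on the midsagittal plane, one on the
xiphoid process (measurement site, directly over the contracting
diaphragm) and one on the sternum (reference site). Subtracting the
reference from the measurement cancels motion common to both sensors
(postural adjustments), leaving the breathing-related signal. The package
is aimed at physiologists and instrumentation engineers studying
free-diving apnea who need a reproducible software path from the logger's
CSV files to phase landmarks and spectra.

A maximal breath hold has four landmarks: the **hold start**, the **easy
phase** (no involuntary movements), the **physiological breaking point**
(the first IBM), the **struggle phase** (IBMs growing in rate and
magnitude), and the **conventional breaking point** (breathing resumes).

Since subject recordings are typically not shareable, `ibmkit` also ships
a first-class simulator of the whole measurement chain: two-site
acceleration synthesis with ground-truth annotations, and an emulator of
the logger's data path (xiphoid − sternum differencing, 10-sample block
averaging from ~1000 Hz to the 100 Hz log, 4-column CSV with millisecond
ticks and intermittent 1 Hz pulse-oximeter columns).

## The processing pipeline

For a raw differential record `y_raw` the pipeline computes, in order:

1. **Truncation** at the hold start (removes sitting motion).
2. **Zero-phase lowpass**: 12th-order Butterworth (50 Hz corner) applied
   forward and backward, then **decimation** to 100 Hz (applied only when
   the input rate is above the working rate).
3. **Normalization** against the easy-phase baseline:
   `y = (y_raw − mean(y_easy)) / max |y_raw − mean(y_easy)|`,
   a dimensionless signal in [−1, 1].
4. **Per-phase FFT** amplitude spectra with peak identification; the
   cardiac peak converts to a heart rate as `BPM = round(60 f)`.
5. **Zero-phase bandpass**, 5th-order Butterworth (0.5–3.5 Hz), and
   **squaring** `y_filt ← y_filt²` to obtain a non-negative envelope.
6. **Singular spectrum analysis (SSA)** of the envelope — Hankel
   trajectory embedding, SVD, anti-diagonal averaging — grouped into the
   additive decomposition `A = L + S + R` (long-term trend, oscillations,
   remainder); `L` is the magnitude trendline of the struggle phase.
7. **Spectrogram** (Hann short-time FFT) of the envelope, and automatic
   **phase segmentation**: the physiological breaking point is the
   earliest time the smoothed envelope exceeds a k-sigma threshold of the
   easy-phase baseline for a sustained dwell time.

## Worked example

```r
library(ibmkit)

cfg <- sim_config(pre_hold_s = 10, easy_s = 40, struggle_s = 40,
                  ibm_f0_start = 0.68, ibm_f0_end = 0.68, seed = 1)
rec <- simulate_breath_hold(cfg)
log <- emulate_device(rec$sternum, rec$xiphoid,
                      vitals = simulate_vitals(rec$truth, cfg))
log
#> <device_log> 9000 records @ 100 Hz nominal (ticks at 1000/s) from emulated device

report <- analyze_recording(log, analysis_config(hold_start_s = 10))
report
#> <analysis_report>
#> <breath_hold_phases>
#>   hold start:                   0.00 s
#>   physiological breaking point: 38.84 s
#>   conventional breaking point:  79.99 s
#>   easy-phase peaks (Hz):      2.085
#>   struggle-phase peaks (Hz):  0.680, 1.361, 2.041, 2.089, 2.721

hz_to_bpm(report$easy_peaks$freq_hz[1])
#> [1] 125
```

Reading the output: the configured hold starts 10 s into the recording
and all report times are referenced to it. The easy phase shows a single
spectral peak at the cardiac frequency (2.085 Hz ≈ the configured
2.09 Hz heart tone, i.e. 125 BPM); the struggle phase adds the IBM
fundamental at 0.680 Hz and its harmonic near 1.36 Hz. The detected
physiological breaking point (38.84 s) recovers the simulator's ground
truth (40 s) within the pipeline's ±2 s contract, and `report$trend`
holds the SSA trendline that rises as IBM magnitude grows.

The same workflows are available from a shell via the installed
dispatcher:

```sh
ibmkit=$(Rscript -e 'cat(system.file("exec", "ibmkit", package = "ibmkit"))')
Rscript $ibmkit simulate --out run1 --seed 1
Rscript $ibmkit process --log run1/device_log.csv --out run1/report
Rscript $ibmkit report --dir run1/report
```

Device-side arithmetic is included: `battery_runtime(700, 200)` gives
3.5 h for the logger's 9 V battery, and `bom_total(read_bom(...))` totals
the packaged bill of materials (USD 105.02), reporting any rows whose
cost disagrees with quantity × unit price.

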