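Package: ibmkit
Title: Measurement and Analysis of Involuntary Breathing Movements from
    Differential Accelerometry
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Toolkit for studying involuntary breathing movements (IBMs)
    during maximal breath holds with a dual-site chest accelerometer.
    Provides a simulator of two-site (xiphoid/sternum) acceleration
    recordings with ground-truth phase annotations, an emulator of the
    logger's differential-averaging data path and CSV log dialect, and a
    complete processing pipeline: zero-phase Butterworth filtering,
    decimation, easy-phase baseline normalization, per-phase FFT spectra
    with heart-rate conversion, singular spectrum analysis trend
    decomposition, spectrogram computation, and automatic segmentation of
    the easy phase, physiological breaking point, and struggle phase.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    stats,
    utils,
    grDevices,
    graphics,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
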