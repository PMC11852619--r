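#' Single-sided amplitude spectrum
#'
#' FFT amplitude spectrum with the scaling convention that a unit-amplitude
#' sinusoid located exactly at a bin center yields amplitude 1.0 at that
#' bin: the DC bin is `|X_0|/n`, interior bins `2|X_k|/n`, and (for even
#' `n`) the Nyquist bin `|X_{n/2}|/n`.
#'
#' @param series a [uniform_series()] with at least 2 samples.
#' @return An object of class `spectrum_amp` with fields `freqs` (Hz, from 0
#'   to Nyquist), `amps`, `n` (source length) and `rate`.
#' @examples
#' s <- uniform_series(sin(2 * pi * 5 * (0:199) / 100), 100)
#' sp <- amplitude_spectrum(s)
#' sp$freqs[which.max(sp$amps)]  # 5 Hz
#' @export
amplitude_spectrum <- function(series) {
  x <- series$values
  n <- length(x)
  if (n < 2L) stop("amplitude_spectrum needs at least 2 samples")
  X <- stats::fft(x)
  nh <- floor(n / 2)
  amps <- Mod(X[seq_len(nh + 1L)]) / n
  if (nh >= 1L) {
    mid <- 2:(nh + if (n %% 2 == 0) 0L else 1L)
    amps[mid] <- 2 * amps[mid]
  }
  structure(
    list(freqs = (0:nh) * series$rate / n, amps = amps, n = n,
         rate = series$rate),
    class = "spectrum_amp"
  )
}

#' @export
print.spectrum_amp <- function(x, ...) {
  cat(sprintf("<spectrum_amp> %d bins, resolution %g Hz, Nyquist %g Hz\n",
              length(x$freqs), x$rate / x$n, max(x$freqs)))
  invisible(x)
}

# Topographic prominence of local maxima of `a` (indices `peaks`): height
# above the higher of the two key saddles, where each saddle is the lowest
# value between the peak and the nearest higher value on that side (or the
# lowest value to the interval edge when no higher value exists).
peak_prominence <- function(a, peaks) {
  vapply(peaks, function(p) {
    lo_l <- a[p]; i <- p - 1L
    while (i >= 1L && a[i] <= a[p]) { lo_l <- min(lo_l, a[i]); i <- i - 1L }
    lo_r <- a[p]; j <- p + 1L
    while (j <= length(a) && a[j] <= a[p]) { lo_r <- min(lo_r, a[j]); j <- j + 1L }
    a[p] - max(lo_l, lo_r)
  }, numeric(1))
}

#' Find spectral peaks in a frequency band
#'
#' Local maxima of the amplitude spectrum within `band`, retained if their
#' topographic prominence is at least `min_prominence_fraction` of the
#' largest in-band amplitude, sorted by amplitude (descending; frequency
#' ties broken toward the lower frequency). At most `k` peaks are returned.
#'
#' @param spec a `spectrum_amp` from [amplitude_spectrum()].
#' @param band `c(low, high)` in Hz, inside the spectrum's range.
#' @param k maximum number of peaks to report.
#' @param min_prominence_fraction prominence floor as a fraction of the
#'   maximum in-band amplitude.
#' @return An object of class `spectral_peaks`: a data frame with columns
#'   `freq_hz`, `amplitude`, `prominence`.
#' @export
find_peaks <- function(spec, band, k = 3L, min_prominence_fraction = 0.05) {
  stopifnot(inherits(spec, "spectrum_amp"))
  if (length(band) != 2L || band[1L] >= band[2L])
    stop("`band` must be c(low, high) with low < high")
  inb <- which(spec$freqs >= band[1L] & spec$freqs <= band[2L])
  if (!length(inb)) stop("`band` contains no spectrum bins")
  a <- spec$amps[inb]
  n <- length(a)
  if (n < 3L) {
    cand <- integer(0)
  } else {
    core <- 2:(n - 1L)
    # rising then non-rising: plateaus credited to their lower-frequency edge
    cand <- core[a[core] > a[core - 1L] & a[core] >= a[core + 1L]]
  }
  if (length(cand)) {
    prom <- peak_prominence(a, cand)
    keep <- prom >= min_prominence_fraction * max(a)
    cand <- cand[keep]; prom <- prom[keep]
  } else prom <- numeric(0)
  ord <- order(-a[cand], spec$freqs[inb][cand])
  ord <- utils::head(ord, k)
  structure(
    data.frame(freq_hz = spec$freqs[inb][cand][ord],
               amplitude = a[cand][ord],
               prominence = prom[ord]),
    class = c("spectral_peaks", "data.frame")
  )
}

#' Convert a spectral frequency to beats per minute
#'
#' The cardiac spectral peak expressed as an integer heart rate:
#' `round(f * 60)`, halves rounded away from zero (2.090 Hz -> 125 BPM).
#'
#' @param f frequency in Hz, non-negative (vectorized).
#' @return Integer BPM values.
#' @export
hz_to_bpm <- function(f) {
  if (any(f < 0)) stop("frequency must be non-negative")
  x <- f * 60
  as.integer(sign(x) * floor(abs(x) + 0.5))
}

#' Spectrogram (short-time Fourier magnitude)
#'
#' Hann-windowed short-time Fourier transform magnitude, for visualizing
#' time-dependent changes in the spectral content of a recording (e.g. the
#' growth of the IBM fundamental across the struggle phase). Window center
#' times are referenced to the series' own time axis, i.e. seconds from
#' acquisition start (`t0` included).
#'
#' @param series a [uniform_series()].
#' @param window_s window length in seconds (`window_s * rate >= 4`).
#' @param overlap_fraction fraction of the window shared by consecutive
#'   slices, in `[0, 1)`.
#' @return An object of class `time_freq_map` with fields `times` (s,
#'   window centers), `freqs` (Hz), `magnitude` (matrix, times x freqs),
#'   `window_s`, `overlap_fraction`.
#' @export
spectrogram <- function(series, window_s = 10, overlap_fraction = 0.5) {
  nwin <- round(window_s * series$rate)
  if (nwin < 4L) stop("window must span at least 4 samples")
  if (nwin > length(series$values))
    stop("window (", window_s, " s) is longer than the series")
  if (overlap_fraction < 0 || overlap_fraction >= 1)
    stop("`overlap_fraction` must be in [0, 1)")
  nov <- floor(nwin * overlap_fraction)
  sg <- signal::specgram(series$values, n = nwin, Fs = series$rate,
                         window = signal::hanning(nwin), overlap = nov)
  # signal::specgram reports the 1-based start sample / Fs; shift to centers
  centers <- series$t0 + (sg$t * series$rate - 1 + (nwin - 1) / 2) / series$rate
  structure(
    list(times = as.numeric(centers), freqs = as.numeric(sg$f),
         magnitude = t(Mod(sg$S)), window_s = window_s,
         overlap_fraction = overlap_fraction),
    class = "time_freq_map"
  )
}

#' @export
print.time_freq_map <- function(x, ...) {
  cat(sprintf(
    "<time_freq_map> %d slices x %d bins, window %g s, overlap %g\n",
    length(x$times), length(x$freqs), x$window_s, x$overlap_fraction))
  invisible(x)
}

#' Ridge frequency per spectrogram slice
#'
#' @param map a `time_freq_map`.
#' @return Numeric vector: the frequency of maximum magnitude per slice.
#' @export
ridge_frequencies <- function(map) {
  map$freqs[apply(map$magnitude, 1L, which.max)]
}
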