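#' @name phases
#' @title Breath-hold phase segmentation
#'
#' @description
#' A maximal breath hold has four landmarks: the hold start, the easy
#' phase (no involuntary movements), the physiological breaking point
#' (first involuntary breathing movement, IBM), the struggle phase (IBMs
#' growing in rate and magnitude) and the conventional breaking point
#' (breathing resumes). The detector makes the segmentation algorithmic:
#' the squared band-passed envelope, smoothed over a short window, is
#' compared against a k-sigma threshold computed on the easy-phase
#' baseline, and the physiological breaking point is the earliest time the
#' envelope stays above threshold for a minimum dwell time (so isolated
#' postural spikes do not trigger it).
NULL

#' Phase landmarks of a breath hold
#'
#' @param t_hold_start,t_physio_break,t_conv_break landmark times in
#'   seconds (`t_physio_break` may be `NA` when no struggle phase was
#'   detected); must be non-decreasing when present.
#' @return An object of class `breath_hold_phases`.
#' @export
breath_hold_phases <- function(t_hold_start, t_physio_break = NA_real_,
                               t_conv_break = NA_real_) {
  tt <- c(t_hold_start, t_physio_break, t_conv_break)
  tp <- tt[!is.na(tt)]
  if (length(tp) > 1L && any(diff(tp) < 0))
    stop("phase landmarks must be ordered: hold start <= physiological ",
         "breaking point <= conventional breaking point")
  structure(list(t_hold_start = t_hold_start, t_physio_break = t_physio_break,
                 t_conv_break = t_conv_break),
            class = "breath_hold_phases")
}

#' @export
print.breath_hold_phases <- function(x, ...) {
  fmt <- function(v) if (is.na(v)) "not detected" else sprintf("%.2f s", v)
  cat("<breath_hold_phases>\n",
      "  hold start:                   ", fmt(x$t_hold_start), "\n",
      "  physiological breaking point: ", fmt(x$t_physio_break), "\n",
      "  conventional breaking point:  ", fmt(x$t_conv_break), "\n", sep = "")
  invisible(x)
}

# Centered moving average over a window of `n` samples.
moving_average <- function(x, n) {
  n <- max(1L, as.integer(n))
  if (n == 1L) return(x)
  k <- rep(1 / n, n)
  as.numeric(stats::filter(x, k, sides = 2))  # NA at both edges
}

#' Detect the physiological breaking point
#'
#' Finds the earliest time at which `trend` exceeds
#' `mean + k * sd` of its values over the easy-phase baseline window,
#' continuously for at least `min_hold_s` seconds. The dwell requirement
#' rejects short transients (e.g. a single postural spike).
#'
#' @param trend a [uniform_series()] — an envelope or trend signal, e.g. a
#'   smoothed [square_signal()] output or an SSA trend.
#' @param easy_baseline an [easy_window()] inside the trend span; the
#'   search starts at its end.
#' @param k threshold in baseline standard deviations above the baseline
#'   mean.
#' @param min_hold_s minimum dwell above threshold, seconds.
#' @return Detection time in seconds from acquisition start, or `NA` if
#'   the trend never sustains the threshold.
#' @export
detect_physio_break <- function(trend, easy_baseline, k = 3, min_hold_s = 2) {
  stopifnot(inherits(easy_baseline, "easy_window"))
  tt <- series_times(trend)
  if (easy_baseline$start_s < tt[1L] - 1e-9 ||
      easy_baseline$end_s > tt[length(tt)] + 1e-9)
    stop("easy baseline window lies outside the trend span")
  base <- series_window(trend, easy_baseline$start_s, easy_baseline$end_s)
  bv <- base$values[!is.na(base$values)]
  thr <- mean(bv) + k * stats::sd(bv)
  search <- which(tt >= easy_baseline$end_s & !is.na(trend$values))
  if (!length(search)) return(NA_real_)
  above <- trend$values[search] > thr
  need <- max(1L, ceiling(min_hold_s * trend$rate))
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  hit <- which(r$values & r$lengths >= need)
  if (!length(hit)) return(NA_real_)
  tt[search[starts[hit[1L]]]]
}

#' Default pipeline configuration
#'
#' Parameters of [analyze_recording()] and [segment_phases()] with the
#' processing pipeline's standard values.
#'
#' @param hold_start_s time of the hold start in seconds from acquisition
#'   start (everything before it is truncated away).
#' @param easy_baseline_s length of the baseline window (s) taken right
#'   after the hold start, assumed to lie inside the easy phase; used for
#'   normalization and the detection threshold.
#' @param lowpass_corner,lowpass_order anti-alias lowpass design (Hz /
#'   order), applied only when the input rate exceeds `target_rate`.
#' @param target_rate working rate in Hz after decimation.
#' @param bandpass_low,bandpass_high,bandpass_order band of interest (Hz)
#'   and design order.
#' @param detect_k,detect_dwell_s,smooth_s breaking-point detector
#'   parameters: threshold in baseline SDs, dwell time (s) and the
#'   envelope-smoothing window (s).
#' @param trend_window_s,trend_cutoff,trend_energy_floor,trend_rate SSA
#'   trend parameters: embedding window (s), trend/oscillation frequency
#'   boundary (Hz), oscillatory energy floor (fraction), and the rate (Hz)
#'   to which the envelope is block-averaged before SSA.
#' @param spect_window_s,spect_overlap spectrogram window (s) and overlap
#'   fraction.
#' @param peak_band,peak_k,peak_min_prominence per-phase FFT peak search:
#'   band (Hz), maximum number of peaks, prominence floor.
#' @return A list of class `analysis_config`.
#' @export
analysis_config <- function(hold_start_s = 0, easy_baseline_s = 20,
                            lowpass_corner = 50, lowpass_order = 12L,
                            target_rate = 100,
                            bandpass_low = 0.5, bandpass_high = 3.5,
                            bandpass_order = 5L,
                            detect_k = 3, detect_dwell_s = 2, smooth_s = 2,
                            trend_window_s = 20, trend_cutoff = 0.1,
                            trend_energy_floor = 0.05, trend_rate = 10,
                            spect_window_s = 10, spect_overlap = 0.5,
                            peak_band = c(0.3, 3.5), peak_k = 5L,
                            peak_min_prominence = 0.05) {
  structure(as.list(environment()), class = "analysis_config")
}

# Reduce the front half of the pipeline to a normalized series:
# truncate -> (lowpass + decimate when needed) -> normalize.
preprocess_front <- function(series, cfg) {
  stage <- function(name, expr) tryCatch(expr, error = function(e)
    stop("pipeline stage '", name, "': ", conditionMessage(e), call. = FALSE))
  s <- stage("truncate", truncate_start(series, cfg$hold_start_s))
  if (s$rate > cfg$target_rate) {
    s <- stage("lowpass",
               lowpass_zero_phase(s, cfg$lowpass_corner, cfg$lowpass_order))
    s <- stage("decimate", decimate_series(s, round(s$rate / cfg$target_rate)))
  }
  easy <- easy_window(cfg$hold_start_s,
                      min(cfg$hold_start_s + cfg$easy_baseline_s,
                          s$t0 + series_duration(s)))
  norm <- stage("normalize", normalize_easy(s, easy))
  list(norm = norm, easy = easy)
}

# Smoothed squared band-passed envelope used by the detector.
detection_envelope <- function(norm, cfg) {
  bp <- bandpass_zero_phase(norm, cfg$bandpass_low, cfg$bandpass_high,
                            cfg$bandpass_order)
  env <- square_signal(bp)
  sm <- moving_average(env$values, round(cfg$smooth_s * env$rate))
  list(bandpassed = bp, envelope = env,
       smoothed = uniform_series(ifelse(is.na(sm), 0, sm), env$rate, env$t0))
}

#' Segment a recording into breath-hold phases
#'
#' Runs the front half of the pipeline (truncation, anti-alias filtering
#' and decimation when the input is above the working rate, easy-phase
#' normalization, band-pass, squaring, smoothing) and applies
#' [detect_physio_break()]. The easy phase is
#' `[hold_start, t_physio_break)` and the struggle phase runs from the
#' physiological breaking point to the end of the recording (the
#' conventional breaking point, taken as an end-of-record marker).
#'
#' @param x a [device_log()] or [uniform_series()].
#' @param config an [analysis_config()]; `config$hold_start_s` marks the
#'   start of the hold.
#' @return A [breath_hold_phases()] in seconds from acquisition start;
#'   `t_physio_break` is `NA` when no struggle phase is detected.
#' @export
segment_phases <- function(x, config = analysis_config()) {
  series <- if (inherits(x, "device_log")) to_uniform_series(x) else x
  front <- preprocess_front(series, config)
  det <- detection_envelope(front$norm, config)
  t_pb <- detect_physio_break(det$smoothed, front$easy,
                              k = config$detect_k,
                              min_hold_s = config$detect_dwell_s)
  t_end <- det$smoothed$t0 + series_duration(det$smoothed)
  breath_hold_phases(config$hold_start_s, t_pb, t_end)
}

#' Analyze a complete breath-hold recording
#'
#' Full pipeline orchestration: truncation at the hold start, zero-phase
#' anti-alias lowpass and decimation (when the log rate exceeds the
#' working rate), easy-phase normalization, automatic phase segmentation,
#' per-phase FFT amplitude spectra with peak identification, zero-phase
#' band-pass and squaring, SSA trend of the envelope, and a spectrogram of
#' the squared band-passed signal. All report times are in seconds from
#' the hold start; the acquisition-to-hold conversion happens once, here.
#'
#' @param log a [device_log()] (or a raw [uniform_series()]).
#' @param config an [analysis_config()].
#' @return An object of class `analysis_report`: list with `phases`
#'   (hold-referenced [breath_hold_phases()]), `normalized`, `easy_peaks`,
#'   `struggle_peaks` ([find_peaks()] outputs; struggle peaks `NULL` when
#'   no struggle phase exists), `trend` (SSA trend of the envelope),
#'   `envelope`, `spectrogram`, and `provenance` (every stage parameter).
#' @export
analyze_recording <- function(log, config = analysis_config()) {
  series <- if (inherits(log, "device_log")) to_uniform_series(log) else log
  front <- preprocess_front(series, config)
  det <- detection_envelope(front$norm, config)
  t_pb <- detect_physio_break(det$smoothed, front$easy,
                              k = config$detect_k,
                              min_hold_s = config$detect_dwell_s)
  t_end <- det$smoothed$t0 + series_duration(det$smoothed)
  stage <- function(name, expr) tryCatch(expr, error = function(e)
    stop("pipeline stage '", name, "': ", conditionMessage(e), call. = FALSE))

  easy_end <- if (is.na(t_pb)) t_end else t_pb
  easy_seg <- stage("easy-phase FFT",
                    series_window(front$norm, config$hold_start_s, easy_end))
  easy_spec <- amplitude_spectrum(easy_seg)
  easy_peaks <- stage("easy-phase peaks",
                      find_peaks(easy_spec, config$peak_band, config$peak_k,
                                 config$peak_min_prominence))
  struggle_peaks <- NULL; struggle_spec <- NULL
  if (!is.na(t_pb) && t_end - t_pb > 2 / config$bandpass_low) {
    seg <- stage("struggle-phase FFT", series_window(front$norm, t_pb, t_end))
    struggle_spec <- amplitude_spectrum(seg)
    struggle_peaks <- stage("struggle-phase peaks",
                            find_peaks(struggle_spec, config$peak_band,
                                       config$peak_k,
                                       config$peak_min_prominence))
  }

  # SSA trend on the block-averaged envelope (keeps the 20 s embedding
  # window tractable); reported at trend_rate.
  fac <- max(1L, round(det$envelope$rate / config$trend_rate))
  env_ds <- stage("trend", {
    v <- det$envelope$values
    nb <- length(v) %/% fac
    uniform_series(colMeans(matrix(v[seq_len(nb * fac)], nrow = fac)),
                   det$envelope$rate / fac, det$envelope$t0)
  })
  trend <- stage("trend", trend_of(
    env_ds,
    window_len = min(round(config$trend_window_s * env_ds$rate),
                     floor(length(env_ds$values) / 2)),
    trend_cutoff = config$trend_cutoff,
    energy_floor = config$trend_energy_floor))

  sgram <- stage("spectrogram",
                 spectrogram(det$envelope, config$spect_window_s,
                             config$spect_overlap))

  # convert every reported time to seconds from the hold start
  h0 <- config$hold_start_s
  shift <- function(s) { s$t0 <- s$t0 - h0; s }
  sgram$times <- sgram$times - h0
  phases <- breath_hold_phases(0, t_pb - h0, t_end - h0)
  structure(
    list(phases = phases,
         normalized = shift(front$norm),
         easy_peaks = easy_peaks, struggle_peaks = struggle_peaks,
         easy_spectrum = easy_spec, struggle_spectrum = struggle_spec,
         bandpassed = shift(det$bandpassed),
         envelope = shift(det$envelope),
         trend = shift(trend),
         spectrogram = sgram,
         provenance = c(unclass(config),
                        list(input_rate = series$rate,
                             input_samples = length(series$values),
                             hold_reference_s = h0))),
    class = "analysis_report")
}

#' @export
print.analysis_report <- function(x, ...) {
  cat("<analysis_report>\n")
  print(x$phases)
  cat("  easy-phase peaks (Hz):     ",
      paste(sprintf("%.3f", x$easy_peaks$freq_hz), collapse = ", "), "\n")
  if (!is.null(x$struggle_peaks))
    cat("  struggle-phase peaks (Hz): ",
        paste(sprintf("%.3f", x$struggle_peaks$freq_hz), collapse = ", "), "\n")
  invisible(x)
}

#' Write an analysis report to a directory
#'
#' Serializes the report as plain-text files: `phases.csv`,
#' `peaks_easy.csv`, `peaks_struggle.csv`, `trend.csv`,
#' `spectrogram.csv` (long format `time_s,freq_hz,magnitude`) and
#' `provenance.yaml`.
#'
#' @param report an `analysis_report`.
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  w <- function(df, f) utils::write.csv(df, file.path(dir, f),
                                        row.names = FALSE, quote = FALSE)
  p <- report$phases
  w(data.frame(landmark = c("hold_start", "physio_break", "conv_break"),
               time_s = c(p$t_hold_start, p$t_physio_break, p$t_conv_break)),
    "phases.csv")
  pk <- function(x) if (is.null(x)) data.frame(freq_hz = numeric(0),
                                               amplitude = numeric(0),
                                               prominence = numeric(0)) else x
  w(pk(report$easy_peaks), "peaks_easy.csv")
  w(pk(report$struggle_peaks), "peaks_struggle.csv")
  w(data.frame(time_s = series_times(report$trend),
               trend = report$trend$values), "trend.csv")
  sg <- report$spectrogram
  w(data.frame(time_s = rep(sg$times, times = length(sg$freqs)),
               freq_hz = rep(sg$freqs, each = length(sg$times)),
               magnitude = as.vector(sg$magnitude)), "spectrogram.csv")
  prov <- report$provenance
  prov <- prov[!vapply(prov, is.null, logical(1))]
  yaml::write_yaml(prov, file.path(dir, "provenance.yaml"))
  invisible(dir)
}
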