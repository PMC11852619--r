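#' Uniformly sampled time series
#'
#' The basic container used throughout the pipeline: a numeric vector of
#' samples at a fixed rate, with a time offset `t0` giving the time of the
#' first sample relative to the start of acquisition.
#'
#' @param values numeric vector of samples; must be finite.
#' @param rate sampling rate in Hz; must be positive.
#' @param t0 time of the first sample in seconds from acquisition start.
#' @param units free-text unit label carried along for printing.
#' @return An object of class `uniform_series`.
#' @examples
#' s <- uniform_series(sin(2 * pi * 1 * (0:99) / 100), rate = 100)
#' series_duration(s)
#' @export
uniform_series <- function(values, rate, t0 = 0, units = "sensor units") {
  values <- as.numeric(values)
  if (!is.numeric(rate) || length(rate) != 1L || !is.finite(rate) || rate <= 0)
    stop("`rate` must be a single positive number (Hz)")
  if (length(values) && any(!is.finite(values)))
    stop("`values` must be finite")
  structure(
    list(values = values, rate = rate, t0 = as.numeric(t0), units = units),
    class = "uniform_series"
  )
}

#' @export
print.uniform_series <- function(x, ...) {
  cat(sprintf(
    "<uniform_series> %d samples @ %g Hz, t0 = %g s (%.3g s span), units: %s\n",
    length(x$values), x$rate, x$t0, series_duration(x), x$units
  ))
  invisible(x)
}

#' Sample times of a uniform series
#'
#' @param series a [uniform_series()].
#' @return Numeric vector of sample times in seconds from acquisition start.
#' @export
series_times <- function(series) {
  series$t0 + (seq_along(series$values) - 1L) / series$rate
}

#' Duration of a uniform series
#'
#' Span from the first to the last sample, `(n - 1) / rate` seconds.
#'
#' @param series a [uniform_series()].
#' @return Duration in seconds (0 for a single sample or empty series).
#' @export
series_duration <- function(series) {
  n <- length(series$values)
  if (n < 2L) return(0)
  (n - 1L) / series$rate
}

#' Extract a time window of a series
#'
#' @param series a [uniform_series()].
#' @param start_s,end_s window bounds in seconds from acquisition start;
#'   the window is `[start_s, end_s)` except that `end_s` at the series end
#'   includes the final sample.
#' @return A [uniform_series()] covering the window.
#' @export
series_window <- function(series, start_s, end_s) {
  if (start_s >= end_s) stop("window start must precede window end")
  tt <- series_times(series)
  keep <- tt >= start_s - 1e-9 & (tt < end_s - 1e-9 | abs(tt - end_s) < 1e-9)
  if (!any(keep)) stop("window [", start_s, ", ", end_s, "] contains no samples")
  idx <- which(keep)
  uniform_series(series$values[idx], series$rate, t0 = tt[idx[1L]],
                 units = series$units)
}

#' Remove the start of a recording
#'
#' Drops everything before `t_start`, e.g. to cut the sitting motion
#' recorded before the breath hold begins.
#'
#' @param series a [uniform_series()].
#' @param t_start seconds from acquisition start; must lie within the series.
#' @return A [uniform_series()] with `t0 = t_start` and
#'   `round((t_start - t0) * rate)` samples removed.
#' @export
truncate_start <- function(series, t_start) {
  rel <- t_start - series$t0
  if (rel < 0) stop("`t_start` precedes the series start")
  if (rel > series_duration(series))
    stop("`t_start` (", t_start, " s) is beyond the series end")
  drop <- round(rel * series$rate)
  uniform_series(series$values[seq.int(drop + 1L, length(series$values))],
                 series$rate, t0 = series$t0 + drop / series$rate,
                 units = series$units)
}

#' Decimate a band-limited series
#'
#' Keeps every `factor`-th sample starting from the first one. The caller
#' is responsible for low-pass filtering below the new Nyquist frequency
#' first (the pipeline applies [lowpass_zero_phase()] before decimating).
#'
#' @param series a [uniform_series()].
#' @param factor integer decimation factor (>= 1).
#' @return A [uniform_series()] at `rate / factor`.
#' @export
decimate_series <- function(series, factor = 10L) {
  factor <- as.integer(factor)
  if (is.na(factor) || factor < 1L) stop("`factor` must be an integer >= 1")
  if (factor == 1L) return(series)
  idx <- seq.int(1L, length(series$values), by = factor)
  uniform_series(series$values[idx], series$rate / factor, t0 = series$t0,
                 units = series$units)
}
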