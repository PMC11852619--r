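#' Easy-phase baseline window
#'
#' A time window, in seconds from acquisition start, taken to lie inside
#' the easy phase of the breath hold. Its mean defines the baseline used
#' for normalization and its statistics the threshold for breaking-point
#' detection.
#'
#' @param start_s,end_s window bounds in seconds; `start_s < end_s`.
#' @return An object of class `easy_window`.
#' @export
easy_window <- function(start_s, end_s) {
  if (!(is.finite(start_s) && is.finite(end_s) && start_s < end_s))
    stop("easy window must have start_s < end_s")
  structure(list(start_s = start_s, end_s = end_s), class = "easy_window")
}

#' Normalize a recording against its easy-phase baseline
#'
#' Subtracts the mean of the easy-phase window and divides by the maximum
#' absolute deviation of the whole series from that mean:
#' `y = (y_raw - mean(y_easy)) / max(|y_raw - mean(y_easy)|)`.
#' The result is dimensionless, lies in `[-1, 1]`, and touches +1 or -1 at
#' the sample of largest excursion. The baseline mean and scale are kept so
#' the original units can be recovered
#' (`values * scale + baseline_mean`).
#'
#' @param series a [uniform_series()].
#' @param easy an [easy_window()] inside the series span.
#' @return A `normalized_series` (also a [uniform_series()]) with extra
#'   fields `baseline_mean` and `scale` in the original units.
#' @examples
#' s <- uniform_series(c(0, 1, 2), rate = 1)
#' normalize_easy(s, easy_window(-0.5, 0.5))$values  # 0, 0.5, 1
#' @export
normalize_easy <- function(series, easy) {
  stopifnot(inherits(easy, "easy_window"))
  base <- series_window(series, easy$start_s, easy$end_s)
  mu <- mean(base$values)
  dev <- series$values - mu
  sc <- max(abs(dev))
  if (sc == 0)
    stop("normalize_easy: signal is constant and equal to the easy-phase ",
         "mean; normalization denominator is zero")
  out <- uniform_series(dev / sc, series$rate, series$t0, units = "normalized")
  out$baseline_mean <- mu
  out$scale <- sc
  class(out) <- c("normalized_series", class(out))
  out
}

#' Square a band-limited signal into a non-negative envelope
#'
#' Element-wise squaring of the band-passed signal removes negative
#' components and yields an energy-like envelope whose trend tracks the
#' growth of involuntary breathing movements through the struggle phase.
#'
#' @param series a [uniform_series()] (typically the output of
#'   [bandpass_zero_phase()]).
#' @return An `envelope_signal` (also a [uniform_series()]), all values >= 0.
#' @export
square_signal <- function(series) {
  out <- uniform_series(series$values^2, series$rate, series$t0,
                        units = paste0("(", series$units, ")^2"))
  class(out) <- c("envelope_signal", class(out))
  out
}
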