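# Shared fixtures: small, fast simulation configs used across test files.

short_sim_config <- function(seed = 1L, ...) {
  sim_config(pre_hold_s = 10, easy_s = 40, struggle_s = 40, seed = seed, ...)
}

# fixed-rate IBM train so spectral peaks sit at a known fundamental
fixed_f0_config <- function(seed = 1L, f0 = 0.68, ...) {
  short_sim_config(seed = seed, ibm_f0_start = f0, ibm_f0_end = f0, ...)
}

make_sine_series <- function(freq, rate, duration, amp = 1, phase = 0) {
  t <- (0:(round(duration * rate) - 1)) / rate
  uniform_series(amp * sin(2 * pi * freq * t + phase), rate)
}

# lag (in samples) of the cross-correlation maximum between two equal-length
# signals; 0 means zero phase shift
xcorr_peak_lag <- function(x, y, max_lag = 50L) {
  lags <- -max_lag:max_lag
  cc <- vapply(lags, function(L) {
    if (L >= 0) sum(x[seq_len(length(x) - L)] * y[seq_len(length(y) - L) + L])
    else sum(x[seq_len(length(x) + L) - L] * y[seq_len(length(y) + L)])
  }, numeric(1))
  lags[which.max(cc)]
}

rms <- function(x) sqrt(mean(x^2))
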