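#' @name simulator
#' @title Synthetic dual-site breath-hold recordings
#'
#' @description
#' The simulator stands in for undeposited human-subject recordings. It
#' synthesizes single-axis acceleration at the two sensor sites (xiphoid
#' process = measurement, sternum = reference) across three intervals:
#' a pre-hold interval with postural/sitting motion, the easy phase
#' carrying only the cardiac component plus noise, and the struggle phase
#' adding involuntary breathing movements (IBMs) as raised-cosine bursts
#' whose rate and amplitude grow linearly until the conventional breaking
#' point. Postural artifacts are common-mode (identical on both sites) and
#' cancel in the device's xiphoid-minus-sternum differential; the cardiac
#' sinusoid couples more strongly at the xiphoid (nearer the heart) so a
#' cardiac spectral peak survives differencing, as observed in real
#' recordings. Sign convention: inward chest contraction is positive on
#' the differential channel.
NULL

# Evaluate f with a temporary RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()))
  }
  set.seed(seed)
  force(expr)
}

#' Simulation configuration
#'
#' @param pre_hold_s,easy_s,struggle_s phase durations in seconds. The
#'   hold starts at `pre_hold_s`; the physiological breaking point (first
#'   IBM) at `pre_hold_s + easy_s`; the conventional breaking point (end of
#'   hold and of the recording) at `pre_hold_s + easy_s + struggle_s`.
#'   Defaults mirror the pilot recording: hold start 30 s, struggle onset
#'   100 s later, about 80 s of struggle.
#' @param raw_rate raw per-sensor sampling rate in Hz (default 1000,
#'   block-averaged 10:1 to the 100 Hz log by [emulate_device()]).
#' @param cardiac_freq heart frequency in Hz (default 2.09, i.e. ~125 BPM).
#' @param cardiac_amp cardiac sinusoid amplitude in sensor units.
#' @param xiphoid_cardiac_gain,sternum_cardiac_gain cardiac coupling per
#'   site; unequal so the differential retains a cardiac component.
#' @param ibm_f0_start,ibm_f0_end IBM event rate in Hz at the start/end of
#'   the struggle phase (linear growth).
#' @param ibm_amp_start,ibm_amp_end burst peak amplitude at the start/end
#'   of the struggle phase (linear growth).
#' @param ibm_burst_width_s duration of each raised-cosine burst (s).
#' @param xiphoid_ibm_gain,sternum_ibm_gain IBM coupling per site; the
#'   xiphoid sits over the contracting diaphragm so it couples strongly.
#' @param artifact_events list of common-mode postural disturbances, each
#'   `c(time_s, amplitude, duration_s)`; default one adjustment during the
#'   pre-hold interval.
#' @param noise_sd per-sensor white Gaussian noise standard deviation.
#' @param spo2_dropout probability that a 1 Hz pulse-oximeter update is
#'   missed (the sensor reads intermittently).
#' @param seed integer RNG seed; identical configs give identical output.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(pre_hold_s = 30, easy_s = 100, struggle_s = 80,
                       raw_rate = 1000,
                       cardiac_freq = 2.09, cardiac_amp = 0.2,
                       xiphoid_cardiac_gain = 1.0, sternum_cardiac_gain = 0.3,
                       ibm_f0_start = 0.6, ibm_f0_end = 0.75,
                       ibm_amp_start = 1.0, ibm_amp_end = 3.0,
                       ibm_burst_width_s = 0.5,
                       xiphoid_ibm_gain = 1.0, sternum_ibm_gain = 0.2,
                       artifact_events = list(c(10, 5, 3)),
                       noise_sd = 0.05, spo2_dropout = 0.3, seed = 1L) {
  cfg <- structure(as.list(environment()), class = "sim_config")
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  with(cfg, {
    if (pre_hold_s < 0 || easy_s < 0 || struggle_s < 0)
      stop("durations must be >= 0")
    if (raw_rate <= 2 * cardiac_freq)
      stop("raw_rate must exceed twice the cardiac frequency")
    if (ibm_f0_start <= 0 || ibm_f0_end <= 0)
      stop("IBM event rates must be positive")
    if (ibm_burst_width_s <= 0) stop("ibm_burst_width_s must be positive")
    if (xiphoid_ibm_gain < 0 || sternum_ibm_gain < 0 ||
        xiphoid_cardiac_gain < 0 || sternum_cardiac_gain < 0)
      stop("site gains must be >= 0")
    if (noise_sd < 0) stop("noise_sd must be >= 0")
    for (ev in artifact_events)
      if (length(ev) != 3L || ev[3L] <= 0)
        stop("each artifact event must be c(time_s, amplitude, duration_s)")
  })
  invisible(cfg)
}

# IBM event times across the struggle phase: successive inter-event
# intervals follow the instantaneous rate interpolated f0_start -> f0_end.
ibm_event_schedule <- function(t_break, t_end, f0_start, f0_end) {
  if (t_end <= t_break) return(numeric(0))
  times <- numeric(0)
  t <- t_break
  while (t <= t_end + 1e-9) {
    times <- c(times, t)
    frac <- (t - t_break) / (t_end - t_break)
    f <- f0_start + (f0_end - f0_start) * frac
    t <- t + 1 / f
  }
  times
}

# Raised-cosine (Hann) pulse train: events at `times` with peak amplitudes
# `amps`, width `w` seconds, evaluated on time grid `tt`.
burst_train <- function(tt, times, amps, w) {
  y <- numeric(length(tt))
  if (!length(times)) return(y)
  dt <- tt[2L] - tt[1L]
  for (i in seq_along(times)) {
    lo <- max(1L, ceiling((times[i] - w / 2 - tt[1L]) / dt) + 1L)
    hi <- min(length(tt), floor((times[i] + w / 2 - tt[1L]) / dt) + 1L)
    if (hi < lo) next
    seg <- tt[lo:hi] - times[i]
    y[lo:hi] <- y[lo:hi] + amps[i] * 0.5 * (1 + cos(2 * pi * seg / w))
  }
  y
}

artifact_signal <- function(tt, events) {
  y <- numeric(length(tt))
  for (ev in events) {
    w <- ev[3L]
    idx <- which(tt >= ev[1L] - w / 2 & tt <= ev[1L] + w / 2)
    if (length(idx))
      y[idx] <- y[idx] + ev[2L] * 0.5 * (1 + cos(2 * pi * (tt[idx] - ev[1L]) / w))
  }
  y
}

#' Simulate a dual-site breath-hold recording
#'
#' @param config a [sim_config()].
#' @return A list with elements `sternum` and `xiphoid` (each a
#'   [uniform_series()] at `raw_rate`) and `truth`, a `sim_truth` object
#'   holding the ground-truth landmark times (`t_hold_start`,
#'   `t_physio_break`, `t_conv_break`, all seconds from acquisition
#'   start), the IBM event times, the cardiac frequency and the mean IBM
#'   burst rate (`ibm_spectrum_fundamental`).
#' @examples
#' rec <- simulate_breath_hold(sim_config(pre_hold_s = 2, easy_s = 10,
#'                                        struggle_s = 10, seed = 7))
#' rec$truth$t_physio_break  # 12
#' @export
simulate_breath_hold <- function(config) {
  validate_sim_config(config)
  c0 <- config
  total <- c0$pre_hold_s + c0$easy_s + c0$struggle_s
  n <- round(total * c0$raw_rate)
  tt <- (seq_len(n) - 1L) / c0$raw_rate
  t_hold <- c0$pre_hold_s
  t_break <- c0$pre_hold_s + c0$easy_s
  t_end <- total
  ev_times <- ibm_event_schedule(t_break, t_end, c0$ibm_f0_start, c0$ibm_f0_end)
  frac <- if (t_end > t_break) (ev_times - t_break) / (t_end - t_break) else numeric(0)
  ev_amps <- c0$ibm_amp_start + (c0$ibm_amp_end - c0$ibm_amp_start) * frac
  ibm <- burst_train(tt, ev_times, ev_amps, c0$ibm_burst_width_s)
  cardiac <- c0$cardiac_amp * sin(2 * pi * c0$cardiac_freq * tt)
  artifact <- artifact_signal(tt, c0$artifact_events)
  noise <- with_seed(c0$seed, list(stern = stats::rnorm(n, sd = c0$noise_sd),
                                   xiph = stats::rnorm(n, sd = c0$noise_sd)))
  sternum <- uniform_series(
    c0$sternum_cardiac_gain * cardiac + c0$sternum_ibm_gain * ibm +
      artifact + noise$stern, c0$raw_rate)
  xiphoid <- uniform_series(
    c0$xiphoid_cardiac_gain * cardiac + c0$xiphoid_ibm_gain * ibm +
      artifact + noise$xiph, c0$raw_rate)
  truth <- structure(
    list(t_hold_start = t_hold, t_physio_break = t_break,
         t_conv_break = t_end, ibm_event_times = ev_times,
         cardiac_freq = c0$cardiac_freq,
         ibm_spectrum_fundamental = (c0$ibm_f0_start + c0$ibm_f0_end) / 2),
    class = "sim_truth")
  list(sternum = sternum, xiphoid = xiphoid, truth = truth)
}

#' Simulate 1 Hz pulse-oximeter vitals
#'
#' Auxiliary heart-rate / SpO2 readings: heart rate is the cardiac
#' frequency in BPM with small jitter; SpO2 sits near 98% until the
#' physiological breaking point then falls linearly to ~86% at the
#' conventional breaking point. Updates drop out with probability
#' `config$spo2_dropout` (the sensor reads intermittently).
#'
#' @param truth a `sim_truth` from [simulate_breath_hold()].
#' @param config the matching [sim_config()].
#' @return Data frame `time_s`, `heart_rate`, `spo2` at 1 Hz (NA where
#'   dropped out).
#' @export
simulate_vitals <- function(truth, config) {
  t_end <- truth$t_conv_break
  tv <- seq(0, floor(t_end))
  with_seed(config$seed + 1L, {
    hr <- round(truth$cardiac_freq * 60 + stats::rnorm(length(tv), sd = 1))
    spo2 <- ifelse(
      tv < truth$t_physio_break, 98,
      round(97 - 11 * (tv - truth$t_physio_break) /
              max(t_end - truth$t_physio_break, 1), 1))
    drop <- stats::runif(length(tv)) < config$spo2_dropout
  })
  hr[drop] <- NA_real_
  spo2[drop] <- NA_real_
  data.frame(time_s = tv, heart_rate = pmax(hr, 1), spo2 = pmin(spo2, 100))
}

#' Emulate the device's differential-averaging data path
#'
#' Computes the xiphoid-minus-sternum differential sample-wise, averages
#' consecutive non-overlapping blocks of `block` samples (trailing partial
#' block dropped), and packs the result into a [device_log()] with
#' millisecond ticks. Common-mode content (postural artifacts) cancels in
#' the subtraction.
#'
#' @param sternum,xiphoid [uniform_series()] of equal length and rate.
#' @param block samples per average (default 10: 1000 Hz -> 100 Hz).
#' @param vitals optional data frame from [simulate_vitals()]; readings are
#'   attached to the log record nearest each update time.
#' @return A [device_log()] at `rate / block` Hz.
#' @export
emulate_device <- function(sternum, xiphoid, block = 10L, vitals = NULL) {
  block <- as.integer(block)
  if (is.na(block) || block < 1L) stop("`block` must be an integer >= 1")
  if (length(sternum$values) != length(xiphoid$values))
    stop("sternum and xiphoid streams must have equal length")
  if (sternum$rate != xiphoid$rate)
    stop("sternum and xiphoid streams must have equal rates")
  d <- xiphoid$values - sternum$values
  nb <- length(d) %/% block
  if (nb == 0L) stop("fewer samples than one block")
  avg <- colMeans(matrix(d[seq_len(nb * block)], nrow = block))
  log_rate <- sternum$rate / block
  t_rec <- (seq_len(nb) - 1L) / log_rate
  hr <- rep(NA_real_, nb); sp <- rep(NA_real_, nb)
  if (!is.null(vitals) && nrow(vitals)) {
    idx <- round(vitals$time_s * log_rate) + 1L
    ok <- idx >= 1L & idx <= nb
    hr[idx[ok]] <- vitals$heart_rate[ok]
    sp[idx[ok]] <- vitals$spo2[ok]
  }
  device_log(data.frame(tick = round(t_rec * 1000), diff_accel = avg,
                        heart_rate = hr, spo2 = sp),
             tick_rate = 1000, sample_rate = log_rate,
             source_name = "emulated device")
}

#' Simulate a force-plate comparison trace
#'
#' Generates the dorsal-side view of the same hold for comparison plots:
#' IBM bursts occur at exactly the truth's event times, while large
#' postural events appear with the opposite sign to the ventral
#' (accelerometer) convention — a subject arching off the plate unloads it
#' while lifting the chest sensor.
#'
#' @param truth a `sim_truth` from [simulate_breath_hold()].
#' @param config the matching [sim_config()].
#' @param rate output sampling rate in Hz (default 100).
#' @return A [uniform_series()] in arbitrary force units.
#' @export
simulate_force_plate <- function(truth, config, rate = 100) {
  validate_sim_config(config)
  n <- round(truth$t_conv_break * rate)
  tt <- (seq_len(n) - 1L) / rate
  t_break <- truth$t_physio_break
  frac <- if (truth$t_conv_break > t_break)
    (truth$ibm_event_times - t_break) / (truth$t_conv_break - t_break)
  else numeric(0)
  amps <- config$ibm_amp_start + (config$ibm_amp_end - config$ibm_amp_start) * frac
  ibm <- burst_train(tt, truth$ibm_event_times, amps, config$ibm_burst_width_s)
  artifact <- artifact_signal(tt, config$artifact_events)
  noise <- with_seed(config$seed + 2L,
                     stats::rnorm(n, sd = config$noise_sd))
  uniform_series(ibm - artifact + noise, rate, units = "force units")
}

#' Write ground-truth annotations as a sidecar CSV
#'
#' Columns `time_s,event_type` with rows for the hold start, the
#' physiological breaking point, the conventional breaking point, and each
#' IBM event.
#'
#' @param truth a `sim_truth`.
#' @param dest file path.
#' @return `dest`, invisibly.
#' @export
write_truth <- function(truth, dest) {
  df <- data.frame(
    time_s = c(truth$t_hold_start, truth$t_physio_break, truth$t_conv_break,
               truth$ibm_event_times),
    event_type = c("hold_start", "physio_break", "conv_break",
                   rep("ibm_event", length(truth$ibm_event_times))))
  utils::write.csv(df, dest, row.names = FALSE, quote = FALSE)
  invisible(dest)
}
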