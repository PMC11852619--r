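test_that("null model: zero amplitudes give identically zero streams", {
  cfg <- short_sim_config(cardiac_amp = 0, ibm_amp_start = 0, ibm_amp_end = 0,
                          artifact_events = list(), noise_sd = 0)
  rec <- simulate_breath_hold(cfg)
  expect_true(all(rec$sternum$values == 0))
  expect_true(all(rec$xiphoid$values == 0))
})

test_that("same config and seed give bit-identical streams", {
  cfg <- short_sim_config(seed = 42L)
  a <- simulate_breath_hold(cfg)
  b <- simulate_breath_hold(cfg)
  expect_identical(a$xiphoid$values, b$xiphoid$values)
  expect_identical(a$sternum$values, b$sternum$values)
  # and the caller's RNG state is untouched
  set.seed(7); x1 <- runif(1)
  set.seed(7); invisible(simulate_breath_hold(cfg)); x2 <- runif(1)
  expect_identical(x1, x2)
})

test_that("stream length and truth landmarks follow the configured durations", {
  cfg <- sim_config(pre_hold_s = 5, easy_s = 20, struggle_s = 15,
                    raw_rate = 500, seed = 2)
  rec <- simulate_breath_hold(cfg)
  expect_equal(length(rec$xiphoid$values), round(40 * 500))
  expect_equal(rec$truth$t_hold_start, 5)
  expect_equal(rec$truth$t_physio_break, 25)
  expect_equal(rec$truth$t_conv_break, 40)
  expect_true(all(rec$truth$ibm_event_times >= 25 - 1e-9 &
                    rec$truth$ibm_event_times <= 40 + 1e-9))
})

test_that("IBM event count matches rate x duration for a fixed rate", {
  cfg <- sim_config(pre_hold_s = 0, easy_s = 0, struggle_s = 60,
                    ibm_f0_start = 0.68, ibm_f0_end = 0.68, seed = 1)
  rec <- simulate_breath_hold(cfg)
  expect_lte(abs(length(rec$truth$ibm_event_times) - 0.68 * 60), 1.2)
})

test_that("invalid configs error before synthesis", {
  expect_error(sim_config(easy_s = -1), "durations")
  expect_error(sim_config(raw_rate = 3, cardiac_freq = 2), "twice the cardiac")
  expect_error(sim_config(ibm_f0_start = 0), "positive")
  expect_error(sim_config(sternum_ibm_gain = -0.1), ">= 0")
  expect_error(sim_config(artifact_events = list(c(1, 2))), "artifact")
})

test_that("emulate_device averages the differential in 10-sample blocks", {
  # pure common-mode input cancels exactly
  common <- uniform_series(sin(1:1000), 1000)
  log <- emulate_device(common, common)
  expect_true(all(log$records$diff_accel == 0))
  # floor division: 25 samples, block 10 -> 2 records
  a <- uniform_series(rep(0, 25), 1000)
  b <- uniform_series(c(1:10, 11:20, 21:25), 1000)
  log2 <- emulate_device(a, b)
  expect_equal(nrow(log2$records), 2)
  expect_equal(log2$records$diff_accel, c(5.5, 15.5))
  expect_error(emulate_device(a, uniform_series(1:10, 1000)), "equal length")
})

test_that("common-mode artifact energy is rejected by > 120 dB", {
  cfg <- short_sim_config(cardiac_amp = 0, ibm_amp_start = 0, ibm_amp_end = 0,
                          noise_sd = 0,
                          artifact_events = list(c(5, 10, 3), c(30, 4, 2)))
  rec <- simulate_breath_hold(cfg)
  single_energy <- sum(rec$xiphoid$values^2)
  expect_gt(single_energy, 0)
  log <- emulate_device(rec$sternum, rec$xiphoid)
  diff_energy <- sum(log$records$diff_accel^2)
  expect_lt(diff_energy, 1e-12 * single_energy)
})

test_that("struggle-phase differential spectrum peaks at the IBM fundamental", {
  cfg <- fixed_f0_config(seed = 5)
  rec <- simulate_breath_hold(cfg)
  log <- emulate_device(rec$sternum, rec$xiphoid)
  s <- to_uniform_series(log)
  struggle <- series_window(s, rec$truth$t_physio_break,
                            rec$truth$t_conv_break)
  spec <- amplitude_spectrum(struggle)
  sub_cardiac <- find_peaks(spec, c(0.2, 1.5), k = 1)
  bin <- s$rate / spec$n
  expect_lte(abs(sub_cardiac$freq_hz[1] - 0.68), bin + 1e-9)
})

test_that("vitals are 1 Hz with dropouts, positive HR and SpO2 in range", {
  cfg <- short_sim_config(seed = 9)
  rec <- simulate_breath_hold(cfg)
  v <- simulate_vitals(rec$truth, cfg)
  expect_equal(v$time_s, 0:90)
  expect_true(any(is.na(v$heart_rate)))
  expect_true(all(v$heart_rate > 0, na.rm = TRUE))
  expect_true(all(v$spo2 >= 0 & v$spo2 <= 100, na.rm = TRUE))
  # SpO2 declines through the struggle phase
  easy_spo2 <- v$spo2[v$time_s < rec$truth$t_physio_break]
  late_spo2 <- v$spo2[v$time_s > rec$truth$t_conv_break - 10]
  expect_gt(mean(easy_spo2, na.rm = TRUE), mean(late_spo2, na.rm = TRUE))
})

test_that("force-plate trace has bursts at truth event times with inverted artifacts", {
  cfg <- sim_config(pre_hold_s = 10, easy_s = 20, struggle_s = 30,
                    noise_sd = 0, cardiac_amp = 0,
                    artifact_events = list(c(5, 3, 2)), seed = 4)
  rec <- simulate_breath_hold(cfg)
  fp <- simulate_force_plate(rec$truth, cfg)
  tt <- series_times(fp)
  # artifact excursion sign is opposite to the xiphoid stream's
  xi_at <- rec$xiphoid$values[which.min(abs(series_times(rec$xiphoid) - 5))]
  fp_at <- fp$values[which.min(abs(tt - 5))]
  expect_gt(xi_at, 0)
  expect_lt(fp_at, 0)
  # every truth event time is a local burst argmax within one sample
  w <- cfg$ibm_burst_width_s
  for (te in rec$truth$ibm_event_times[1:5]) {
    idx <- which(tt >= te - w / 2 & tt <= te + w / 2)
    t_peak <- tt[idx][which.max(fp$values[idx])]
    expect_lte(abs(t_peak - te), 1 / fp$rate + 1e-9)
  }
  # zero-amplitude config gives a zero series
  cfg0 <- sim_config(pre_hold_s = 1, easy_s = 2, struggle_s = 3,
                     cardiac_amp = 0, ibm_amp_start = 0, ibm_amp_end = 0,
                     artifact_events = list(), noise_sd = 0)
  rec0 <- simulate_breath_hold(cfg0)
  expect_true(all(simulate_force_plate(rec0$truth, cfg0)$values == 0))
})
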