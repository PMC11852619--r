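test_that("phase landmark ordering is enforced", {
  expect_error(breath_hold_phases(10, 5, 20), "ordered")
  p <- breath_hold_phases(10, NA, 50)
  expect_true(is.na(p$t_physio_break))
})

test_that("detector stays silent on a flat trend", {
  tr <- uniform_series(rep(0.5, 2000), 10)
  expect_true(is.na(detect_physio_break(tr, easy_window(0, 60))))
  expect_error(detect_physio_break(tr, easy_window(-50, -10)), "outside")
})

test_that("detector fires at a sustained step and ignores short spikes", {
  rate <- 10
  set.seed(41)
  base <- rnorm(3000, sd = 0.01)
  x <- base
  x[seq(501, 510)] <- x[seq(501, 510)] + 10     # 1 s spike at t = 50 s
  x[1001:3000] <- x[1001:3000] + 10 * sd(base)  # sustained step at t = 100 s
  tr <- uniform_series(x, rate)
  t_det <- detect_physio_break(tr, easy_window(0, 40), k = 3, min_hold_s = 2)
  expect_lte(abs(t_det - 100), 1 / rate + 1e-9)
})

test_that("breaking point is recovered within 2 s on a seeded simulation", {
  cfg <- fixed_f0_config(seed = 8)
  rec <- simulate_breath_hold(cfg)
  log <- emulate_device(rec$sternum, rec$xiphoid)
  ph <- segment_phases(log, analysis_config(hold_start_s = 10))
  expect_false(is.na(ph$t_physio_break))
  expect_lte(abs(ph$t_physio_break - rec$truth$t_physio_break), 2)
  expect_equal(ph$t_hold_start, 10)
})

test_that("a recording ending before any IBM yields an absent breaking point", {
  cfg <- sim_config(pre_hold_s = 5, easy_s = 60, struggle_s = 0, seed = 3)
  rec <- simulate_breath_hold(cfg)
  log <- emulate_device(rec$sternum, rec$xiphoid)
  ph <- segment_phases(log, analysis_config(hold_start_s = 5))
  expect_true(is.na(ph$t_physio_break))
})

test_that("full pipeline recovers cardiac and IBM spectral peaks", {
  cfg <- fixed_f0_config(seed = 12)
  rec <- simulate_breath_hold(cfg)
  log <- emulate_device(rec$sternum, rec$xiphoid,
                        vitals = simulate_vitals(rec$truth, cfg))
  rep <- analyze_recording(log, analysis_config(hold_start_s = 10))
  # easy-phase top peak at the cardiac frequency
  easy_bin <- rep$easy_spectrum$rate / rep$easy_spectrum$n
  expect_lte(abs(rep$easy_peaks$freq_hz[1] - cfg$cardiac_freq), easy_bin + 1e-9)
  # struggle-phase peak list contains the IBM fundamental
  st_bin <- rep$struggle_spectrum$rate / rep$struggle_spectrum$n
  expect_true(any(abs(rep$struggle_peaks$freq_hz - 0.68) <= st_bin + 1e-9))
  # phases are hold-referenced
  expect_equal(rep$phases$t_hold_start, 0)
  expect_lte(abs(rep$phases$t_physio_break -
                   (rec$truth$t_physio_break - 10)), 2)
})

test_that("pipeline is deterministic: identical log and config, identical report", {
  cfg <- fixed_f0_config(seed = 2)
  rec <- simulate_breath_hold(cfg)
  log <- emulate_device(rec$sternum, rec$xiphoid)
  a <- analyze_recording(log, analysis_config(hold_start_s = 10))
  b <- analyze_recording(log, analysis_config(hold_start_s = 10))
  expect_identical(a$phases, b$phases)
  expect_identical(a$trend$values, b$trend$values)
  expect_identical(a$easy_peaks, b$easy_peaks)
})

test_that("struggle-phase trend grows with the IBM amplitude ramp", {
  cfg <- fixed_f0_config(seed = 6)
  rec <- simulate_breath_hold(cfg)
  log <- emulate_device(rec$sternum, rec$xiphoid)
  rep <- analyze_recording(log, analysis_config(hold_start_s = 10))
  tt <- series_times(rep$trend)
  st <- !is.na(rep$phases$t_physio_break) & tt >= rep$phases$t_physio_break &
    tt <= rep$phases$t_conv_break
  rho <- cor(tt[st], rep$trend$values[st], method = "spearman")
  expect_gt(rho, 0.8)
})

test_that("zero-signal logs fail in the normalization stage by name", {
  n <- 2000
  log <- device_log(data.frame(tick = seq(0, by = 10, length.out = n),
                               diff_accel = rep(0, n),
                               heart_rate = NA_real_, spo2 = NA_real_))
  expect_error(analyze_recording(log, analysis_config(easy_baseline_s = 5)),
               "normalize")
})

test_that("stage errors carry the stage name", {
  s <- uniform_series(rnorm(100), 100)
  expect_error(analyze_recording(s, analysis_config(hold_start_s = 50)),
               "truncate")
})

test_that("landmark recovery holds across 20 seeded simulations", {
  hits <- 0L
  for (seed in 1:20) {
    cfg <- short_sim_config(seed = seed)
    rec <- simulate_breath_hold(cfg)
    log <- emulate_device(rec$sternum, rec$xiphoid)
    ph <- segment_phases(log, analysis_config(hold_start_s = 10))
    if (!is.na(ph$t_physio_break) &&
        abs(ph$t_physio_break - rec$truth$t_physio_break) <= 2)
      hits <- hits + 1L
  }
  expect_gte(hits, 18L)  # >= 90% of runs
})

test_that("write_report serializes all six artifact files", {
  cfg <- fixed_f0_config(seed = 13)
  rec <- simulate_breath_hold(cfg)
  log <- emulate_device(rec$sternum, rec$xiphoid)
  rep <- analyze_recording(log, analysis_config(hold_start_s = 10))
  dir <- withr::local_tempdir()
  write_report(rep, dir)
  expect_true(all(file.exists(file.path(
    dir, c("phases.csv", "peaks_easy.csv", "peaks_struggle.csv",
           "trend.csv", "spectrogram.csv", "provenance.yaml")))))
  ph <- read.csv(file.path(dir, "phases.csv"))
  expect_equal(ph$time_s[ph$landmark == "physio_break"],
               rep$phases$t_physio_break)
})
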