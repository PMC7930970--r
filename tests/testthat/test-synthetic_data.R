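test_that("RR series honours its deterministic limit and configured mean", {
  cfg <- ecg_sim_config(mean_hr = 60, rr_sd = 0)
  beats <- simulate_rr_series(cfg, 20)
  expect_equal(diff(beats), rep(1, length(beats) - 1), tolerance = 1e-12)

  cfg80 <- ecg_sim_config(mean_hr = 80, rr_sd = 0.01, seed = 5)
  b <- simulate_rr_series(cfg80, 120)
  rri <- diff(b)
  expect_lt(abs(mean(rri) - 0.75), 3 * 0.01 / sqrt(length(rri)))
  expect_true(all(rri > 0.25))

  expect_error(simulate_rr_series(cfg, 2), "duration")
  expect_error(
    simulate_rr_series(ecg_sim_config(mean_hr = 60, lf_mod = c(0.1, 0.6),
                                      hf_mod = c(0.25, 0.5)), 60),
    "depths")
})

test_that("RR modulation appears at the injected frequency in the tachogram spectrum", {
  cfg <- ecg_sim_config(mean_hr = 70, rr_sd = 0, hf_mod = c(0.25, 0.02),
                        seed = 2)
  tach <- tachogram(simulate_rr_series(cfg, 240))
  sp <- amplitude_spectrum(tach$samples - mean(tach$samples), fs = tach$fs)
  peak_f <- sp$frequency[which.max(sp$amplitude)]
  expect_lt(abs(peak_f - 0.25), 0.02)
})

test_that("the ECG template puts its extremum at the R apex with the configured amplitude", {
  cfg <- ecg_sim_config(mean_hr = 60, rr_sd = 0, r_amp = 100e-6)
  one <- synth_ecg(5, cfg, fs = 1000, duration = 10)
  i_max <- which.max(abs(one$ts$samples))
  expect_lt(abs(ts_times(one$ts)[i_max] - 5), 1.5 / 1000)
  expect_equal(max(abs(one$ts$samples)), 100e-6, tolerance = 1e-3)

  # distorted profile: T bump dominates by construction
  cfg_e <- ecg_sim_config(r_amp = 30e-6, t_amp = 60e-6)
  e <- synth_ecg(5, cfg_e, fs = 1000, duration = 10)
  i_max_e <- which.max(abs(e$ts$samples))
  t_apex <- 5 + cfg_e$offsets[["t"]]
  expect_lt(abs(ts_times(e$ts)[i_max_e] - t_apex), 0.01)
})

test_that("capacitive distortion follows a first-order low-pass response", {
  fs <- 2000
  tt <- seq(0, 4 - 1 / fs, by = 1 / fs)
  tone <- time_series(sin(2 * pi * 40 * tt), fs)

  ident <- synth_cecg(tone, hf_attenuation = NULL)
  expect_identical(ident$samples, tone$samples)

  lp <- synth_cecg(tone, hf_attenuation = 15)
  mid <- seq(fs, 3 * fs)
  ratio <- sqrt(mean(lp$samples[mid]^2) / mean(tone$samples[mid]^2))
  expect_equal(ratio, 1 / sqrt(1 + (40 / 15)^2), tolerance = 0.02)

  # attenuation lowers the R/T amplitude ratio relative to the source
  cfg <- ecg_sim_config(mean_hr = 60, rr_sd = 0)
  beat <- synth_ecg(5, cfg, fs = 2000, duration = 10)
  blurred <- synth_cecg(beat$ts, hf_attenuation = 15)
  rt_ratio <- function(ts) {
    r <- max(abs(slice_series(ts, 4.9, 5.1)$samples))
    t_bump <- max(abs(slice_series(ts, 5.2, 5.45)$samples))
    r / t_bump
  }
  expect_lt(rt_ratio(blurred), rt_ratio(beat$ts))
})

test_that("cough sessions follow the two-cough protocol with valid ground truth", {
  ss <- make_cough_session(seed = 42)
  cc <- ss$cough_cfg
  expect_equal(nrow(ss$truth_cough_windows), 7)
  expect_equal(nrow(ss$annotations), 7)

  # annotations at cycle midpoints, inside their windows
  expect_true(all(ss$annotations$time_s > ss$truth_cough_windows$start &
                    ss$annotations$time_s < ss$truth_cough_windows$end))

  # truth events inside the record; R count equals beats in record
  expect_true(all(ss$truth_rpeaks >= 0 & ss$truth_rpeaks <= ss$duration))

  # burst windows are louder than rest in both EMG channels
  for (ch in c("EMG_ref", "cEMG")) {
    x <- ss$channels[[ch]]
    inside <- unlist(mapply(function(s, e) {
      slice_series(x, s, e)$samples
    }, ss$truth_cough_windows$start, ss$truth_cough_windows$end))
    rest <- slice_series(x, 5, ss$rest_pre - 5)$samples
    expect_gt(sqrt(mean(inside^2)), 3 * sqrt(mean(rest^2)))
  }

  # burst energy is concentrated in the 40-500 Hz band (DFT check)
  b1 <- slice_series(ss$channels$EMG_ref, ss$truth_cough_windows$start[1],
                     ss$truth_cough_windows$start[1] + cc$burst_duration)
  sp <- amplitude_spectrum(b1)
  in_band <- total_spectral_amplitude(sp, 40, 500)
  out_band <- sum(sp$amplitude) - in_band
  expect_gt(in_band, 5 * out_band)
})

test_that("equal seeds give bit-identical sessions", {
  a <- make_cough_session(seed = 9)
  b <- make_cough_session(seed = 9)
  for (ch in names(a$channels)) {
    expect_identical(a$channels[[ch]]$samples, b$channels[[ch]]$samples)
  }
  expect_identical(a$truth_rpeaks, b$truth_rpeaks)
  c2 <- make_cough_session(seed = 10)
  expect_false(identical(a$channels$EMG_ref$samples,
                         c2$channels$EMG_ref$samples))
})

test_that("sessions round-trip through the on-disk artifact set", {
  ss <- make_cough_session(seed = 4)
  dir <- withr::local_tempdir()
  paths <- write_session(ss, dir)
  expect_true(all(file.exists(paths)))
  back <- read_signal_table(paths[["signals"]])
  expect_named(back, c("ECG_ref", "cECG", "EMG_ref", "cEMG"))
  ann <- read_annotations(paths[["annotations"]])
  expect_equal(ann$time_s, ss$annotations$time_s)
  truth <- jsonlite::read_json(paths[["truth"]], simplifyVector = TRUE)
  expect_equal(truth$rpeaks, ss$truth_rpeaks, tolerance = 1e-9)
})
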