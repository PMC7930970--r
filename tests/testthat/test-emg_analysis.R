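test_that("EMG band-pass passes 100 Hz and rejects DC and 10 Hz", {
  fs <- 2000
  cfg <- emg_preprocess_config()
  tt <- seq(0, 4 - 1 / fs, by = 1 / fs)
  mid <- seq(fs, 3 * fs)

  dc <- preprocess_emg(time_series(rep(1, length(tt)), fs), cfg)
  expect_lt(max(abs(dc$samples[mid])), 1e-6)

  in_band <- preprocess_emg(time_series(sin(2 * pi * 100 * tt), fs), cfg)
  g100 <- sqrt(mean(in_band$samples[mid]^2) / 0.5)
  expect_gt(20 * log10(g100), -3)

  low <- preprocess_emg(time_series(sin(2 * pi * 10 * tt), fs), cfg)
  g10 <- sqrt(mean(low$samples[mid]^2) / 0.5)
  expect_lt(20 * log10(g10), -20)
})

test_that("cough segments are located from the envelope around each stamp", {
  ss <- make_cough_session(seed = 7)
  bp <- preprocess_emg(ss$channels$EMG_ref)
  cfg <- segment_selection_config()
  rstats <- rest_envelope_stats(bp, c(0, ss$rest_pre), cfg)

  for (k in c(1, 4, 7)) {
    seg <- locate_cough_segment(bp, ss$annotations$time_s[k], rstats, cfg,
                                cycle_index = k)
    expect_lt(abs(seg$start - ss$truth_cough_windows$start[k]),
              cfg$envelope_window + 0.01)
    expect_lt(abs(seg$end - ss$truth_cough_windows$end[k]),
              cfg$envelope_window + 0.01)
    expect_equal(seg$middle, (seg$start + seg$end) / 2)
    # the two bursts (0.3 s apart < merge span 0.5 s) form one segment
    expect_gt(seg$duration,
              2 * ss$cough_cfg$burst_duration +
                ss$cough_cfg$intra_pair_gap - 2 * cfg$envelope_window)
  }

  expect_error(locate_cough_segment(bp, 30, rstats, cfg), "activity")
  expect_error(locate_cough_segment(bp, 1e6, rstats, cfg), "outside")
})

test_that("mean duration excludes the first and last cycles", {
  mk <- function(durs) lapply(seq_along(durs), function(k) {
    structure(list(start = 10 * k, end = 10 * k + durs[k],
                   middle = 10 * k + durs[k] / 2, duration = durs[k],
                   cycle_index = k), class = "cough_segment")
  })
  segs <- mk(c(2.0, 2.2, 1.8, 2.1, 1.9, 2.0, 2.3))
  expect_equal(mean_duration(segs), 2.0)
  expect_equal(mean_duration(mk(rep(1.5, 5))), 1.5)
  expect_error(mean_duration(mk(c(1, 2))), ">= 3")

  # extension: window of 1.2 * MD centred on the middle point
  one <- mk(c(2, 2, 2))
  ext <- extend_segments(one, 2.0)
  expect_equal(nrow(ext), 1)
  expect_equal(ext$end - ext$start, 2.4)
  expect_equal((ext$start + ext$end) / 2, one[[2]]$middle)

  # factor 1 with equal durations reproduces the detected segments
  cfg1 <- segment_selection_config(extension_factor = 1)
  ext1 <- extend_segments(one, 2.0, cfg1)
  expect_equal(ext1$start, one[[2]]$start)
  expect_equal(ext1$end, one[[2]]$end)

  seven <- mk(rep(2, 7))
  expect_equal(nrow(extend_segments(seven, 2)), 5)
  expect_error(extend_segments(one, 2.0, record_span = c(20, 22)),
               "clipped")
})

test_that("resting segments are tiled and unstable tiles excluded", {
  fs <- 2000
  cfg <- segment_selection_config()
  set.seed(5)
  quiet <- preprocess_emg(time_series(rnorm(60 * fs, sd = 20e-6), fs))
  rstats <- rest_envelope_stats(quiet, c(0, 60), cfg)
  segs <- select_resting_segments(quiet, c(0, 60), 2.0, rstats, cfg)
  expect_equal(nrow(segs), 5)
  expect_equal(segs$start, seq(0, 8, by = 2))

  # inject a burst into the third tile: it must be skipped
  noisy <- quiet
  idx <- round(4.5 * fs):round(5.0 * fs)
  noisy$samples[idx] <- noisy$samples[idx] +
    sin(2 * pi * 120 * seq_along(idx) / fs) * 400e-6
  segs2 <- select_resting_segments(noisy, c(0, 60), 2.0, rstats, cfg)
  expect_false(any(segs2$start == 4))
  expect_equal(nrow(segs2), 5)

  expect_error(select_resting_segments(quiet, c(0, 60), 100, rstats, cfg),
               "exceeds")
})

test_that("the amplitude spectrum is single-sided, exact on bin tones, and Parseval-consistent", {
  fs <- 1000
  tt <- seq(0, 1 - 1 / fs, by = 1 / fs)
  sp <- amplitude_spectrum(sin(2 * pi * 100 * tt), fs)
  expect_equal(sp$amplitude[sp$frequency == 100], 1, tolerance = 1e-9)
  expect_lt(max(sp$amplitude[sp$frequency != 100]), 1e-9)

  expect_equal(max(amplitude_spectrum(rep(0, 256), fs)$amplitude), 0)

  set.seed(8)
  x <- rnorm(999)  # odd length: no Nyquist bin
  for (sig in list(x, rnorm(1000))) {
    s <- amplitude_spectrum(sig, fs)
    a <- s$amplitude
    energy <- a[1]^2 + sum(a[-1]^2) / 2
    if (length(sig) %% 2 == 0) {
      energy <- energy + a[length(a)]^2 / 2  # move Nyquist to full weight
    }
    expect_equal(energy, mean(sig^2), tolerance = 1e-9)
  }
})

test_that("TSA is a band-limited bin sum with inclusive edges", {
  fs <- 2000
  tt <- seq(0, 2 - 1 / fs, by = 1 / fs)
  in_band <- amplitude_spectrum(0.7 * sin(2 * pi * 250 * tt), fs)
  expect_equal(total_spectral_amplitude(in_band), 0.7, tolerance = 1e-6)

  out_band <- amplitude_spectrum(sin(2 * pi * 20 * tt), fs)
  expect_lt(total_spectral_amplitude(out_band), 1e-6)

  set.seed(2)
  noisy <- amplitude_spectrum(rnorm(4096), fs)
  expect_equal(total_spectral_amplitude(noisy, 40, 500),
               total_spectral_amplitude(noisy, 40, 200) +
                 total_spectral_amplitude(noisy, 200 + 1e-9, 500),
               tolerance = 1e-12)
})

test_that("TSA is shift-invariant for stationary signals up to leakage", {
  fs <- 2000
  set.seed(12)
  bf <- signal::butter(2, c(40, 500) / (fs / 2), "pass")
  x <- signal::filtfilt(bf, rnorm(8 * fs))
  tsa <- function(seg) total_spectral_amplitude(amplitude_spectrum(seg, fs))
  a <- tsa(x[1:(2 * fs)])
  b <- tsa(x[(fs / 2):(fs / 2 + 2 * fs - 1)])
  expect_lt(abs(a - b) / a, 0.15)
})

test_that("the normality-gated comparison picks a test and a direction", {
  rest <- c(1, 2, 3, 4, 5)
  cough <- c(5, 4, 3, 2, 1)  # same values, zero mean difference
  cmp <- compare_tsa(rest, cough, alternative = "two.sided")
  expect_gte(cmp$p_value, 0.05)
  if (cmp$test_name == "paired-t") expect_equal(cmp$statistic, 0)

  # direction flips under group swap
  up <- compare_tsa(rest, rest * 10)
  expect_equal(up$direction, "coughing>resting")
  expect_lt(up$p_value, 0.05)
  down <- compare_tsa(rest * 10, rest)
  expect_equal(down$direction, "resting>coughing")

  # degenerate: all paired differences zero
  same <- compare_tsa(rest, rest)
  expect_true(is.na(same$p_value))

  expect_error(compare_tsa(1:2, 3:4), "length")
})

test_that("the full cough analysis finds higher TSA during coughing", {
  ss <- make_cough_session(seed = 31)
  for (ch in c("EMG_ref", "cEMG")) {
    res <- analyze_cough_emg(ss$channels[[ch]], ss$annotations$time_s,
                             rest_window = c(0, ss$rest_pre))
    expect_equal(nrow(res$coughing), 5)  # 7 cycles minus first and last
    expect_length(res$tsa_rest, 5)
    expect_gt(mean(res$tsa_cough), mean(res$tsa_rest))
    expect_lt(res$comparison$p_value, 0.05)
    expect_equal(res$comparison$direction, "coughing>resting")
  }
})
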