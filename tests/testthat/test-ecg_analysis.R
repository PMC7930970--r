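test_that("the preprocessing chain removes DC, passes 15 Hz and rejects 50 Hz", {
  fs <- 1000
  cfg <- ecg_preprocess_config()
  const <- preprocess_ecg(time_series(rep(0.5, 5 * fs), fs), cfg)
  expect_lt(max(abs(const$samples)), 1e-9)

  tt <- seq(0, 5 - 1 / fs, by = 1 / fs)
  mid <- seq(2 * fs, 3 * fs)
  out15 <- preprocess_ecg(time_series(sin(2 * pi * 15 * tt), fs), cfg)
  a15 <- sqrt(2 * mean(out15$samples[mid]^2))
  # closed-form oracle: moving-average sinc gain x (near-unity band-pass)
  # x pure-difference gain 2|sin(pi f D/fs)|
  ma_gain <- abs(sin(pi * 15 * 0.020) / (pi * 15 * 0.020))
  diff_gain <- 2 * abs(sin(pi * 15 * round(0.010 * fs) / fs))
  expected <- ma_gain * diff_gain
  expect_lt(abs(20 * log10(a15 / expected)), 3)

  out50 <- preprocess_ecg(time_series(sin(2 * pi * 50 * tt), fs), cfg)
  a50 <- sqrt(mean(out50$samples[mid]^2))
  expect_gt(20 * log10(sqrt(mean(out15$samples[mid]^2)) / a50), 20)

  expect_error(
    preprocess_ecg(time_series(rnorm(100), 30),
                   ecg_preprocess_config(band = c(10, 20))),
    "Nyquist")
})

test_that("threshold estimation is 80% of the mean assumed R-wave amplitude", {
  # five equal troughs of -1 V
  eq <- bump_series(seq(1, 5), rep(-1, 5))
  thr <- estimate_threshold(eq, candidate_floor = 0)
  expect_equal(thr, -0.8, tolerance = 1e-6)

  # magnitudes 1..5 V, largest mode: 0.8 * mean = 2.4 V
  mag <- bump_series(seq(1, 5), 1:5)
  thr2 <- estimate_threshold(mag, candidate_floor = 0)
  expect_equal(thr2, 0.8 * 3, tolerance = 1e-6)

  # random mode is seeded and draws without replacement
  r1 <- estimate_threshold(mag, mode = "random", candidate_floor = 0,
                           seed = 1)
  r2 <- estimate_threshold(mag, mode = "random", candidate_floor = 0,
                           seed = 1)
  expect_identical(r1, r2)
  expect_equal(r1, 0.8 * 3, tolerance = 1e-6)  # n_waves = all candidates

  expect_error(estimate_threshold(bump_series(1:3, rep(1, 3)),
                                  candidate_floor = 0),
               "candidate")
})

test_that("run-extremum detection suppresses refractory violations", {
  quiet <- time_series(rnorm(1000, sd = 1e-3), 1000)
  expect_length(detect_rpeaks(quiet, 1)$times, 0)

  two <- bump_series(c(2.0, 2.1), c(1, 0.9), width = 0.005)
  det <- detect_rpeaks(two, 0.5, refractory = 0.25)
  expect_length(det$times, 1)
  expect_lt(abs(det$times - 2.0), 0.002)  # keeps the larger bump

  apart <- bump_series(c(2.0, 2.5), c(1, 0.9), width = 0.005)
  expect_length(detect_rpeaks(apart, 0.5, refractory = 0.25)$times, 2)
})

test_that("detection on a clean synthetic record recovers every truth beat", {
  clean <- make_clean_ecg(seed = 11, fs = 2000)
  train <- detect_ecg(clean$ts)
  expect_length(train$times, length(clean$rpeaks))
  # constant preprocessing offset, aligned within the pairing window
  offs <- train$times - clean$rpeaks
  expect_lt(max(abs(offs - stats::median(offs))), 0.005)
  expect_lt(max(abs(offs)), 0.15)

  # random five-wave selection gives the same result on a clean record
  for (s in c(1, 2)) {
    tr <- detect_ecg(clean$ts, mode = "random", seed = s)
    m <- detection_metrics(match_beats(tr, rpeak_train(clean$rpeaks)))
    expect_equal(m$p_acc, 100)
  }
})

test_that("detection counts are invariant to uniform gain scaling", {
  clean <- make_clean_ecg(seed = 21, fs = 2000, duration = 60)
  n1 <- length(detect_ecg(clean$ts)$times)
  scaled <- clean$ts
  scaled$samples <- scaled$samples * 37
  expect_equal(length(detect_ecg(scaled)$times), n1)
})

test_that("RR intervals attach to the latter beat", {
  expect_equal(compute_rri(rpeak_train(c(1, 2, 3)))$rri, c(1, 1))
  expect_equal(compute_rri(rpeak_train(c(1, 2, 3)))$time, c(2, 3))
  expect_equal(nrow(compute_rri(rpeak_train(5))), 0)

  clean <- make_clean_ecg(seed = 3, fs = 2000, duration = 60,
                          mean_hr = 60, rr_sd = 0)
  rri <- compute_rri(detect_ecg(clean$ts))$rri
  expect_true(all(abs(rri - 1) <= 1 / 2000 + 1e-9))
})

test_that("beat matching follows the RR-interval agreement rule", {
  k <- 20
  tt <- cumsum(c(1, runif(k - 1, 0.7, 1.0)))
  ident <- match_beats(rpeak_train(tt), rpeak_train(tt))
  expect_equal(ident$n_tp, k - 1)
  expect_equal(ident$n_fp, 0)
  expect_equal(ident$n_fn, 0)

  empty <- match_beats(rpeak_train(numeric(0)), rpeak_train(tt))
  expect_equal(empty$n_fn, k - 1)
  expect_equal(empty$n_tp + empty$n_fp, 0)

  # one beat shifted +20 ms breaks its two adjacent RR intervals
  shifted <- tt
  shifted[10] <- shifted[10] + 0.020
  sh <- match_beats(rpeak_train(shifted), rpeak_train(tt))
  expect_equal(sh$n_tp, k - 1 - 2)
  expect_equal(sh$n_fp, 2)
  expect_equal(sh$n_fn, 2)

  # identity is exact for arbitrary random trains, and counts conserve
  set.seed(99)
  for (rep in 1:10) {
    n <- sample(2:40, 1)
    x <- rpeak_train(cumsum(runif(n, 0.4, 1.5)))
    m <- match_beats(x, x)
    expect_equal(m$n_fp + m$n_fn, 0)
    expect_equal(m$n_tp, n - 1)
  }
})

test_that("detection metrics reproduce the validation-table arithmetic", {
  e <- detection_metrics(detection_counts(39, 154, 79))
  expect_equal(unname(e$rounded), c(33.1, 14.3, 20.2))

  a <- detection_metrics(detection_counts(163, 0, 0))
  expect_equal(unname(a$rounded), c(100, 100, 100))

  degenerate <- detection_metrics(detection_counts(0, 0, 5))
  expect_equal(degenerate$p_sns, 0)
  expect_equal(degenerate$p_acc, 0)
  expect_true(is.na(degenerate$p_ppv))

  # with n_tn = 0, accuracy can never exceed sensitivity or PPV
  set.seed(42)
  for (rep in 1:50) {
    cts <- detection_counts(sample(0:200, 1), sample(0:200, 1),
                            sample(0:200, 1))
    m <- detection_metrics(cts)
    ok <- !is.na(m$p_acc)
    if (ok && !is.na(m$p_sns)) expect_lte(m$p_acc, m$p_sns + 1e-12)
    if (ok && !is.na(m$p_ppv)) expect_lte(m$p_acc, m$p_ppv + 1e-12)
  }

  expect_error(detection_counts(1, 2, 3, n_tn = 4), "convention")
  expect_error(detection_counts(-1, 0, 0), "non-negative")
})
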