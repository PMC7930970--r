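test_that("quantization maps to the nearest level, clips, and stays within half an LSB", {
  fs <- 1000
  q <- quantizer_spec(16, -10, 10)
  lsb <- 20 / (2^16 - 1)

  zero <- quantize(time_series(rep(0, 100), fs), q)
  expect_true(all(abs(zero$samples) <= lsb))

  clipped <- quantize(time_series(c(15, -12, 9.999), fs), q)
  expect_equal(clipped$samples[1], 10)
  expect_equal(clipped$samples[2], -10)

  ramp <- time_series(seq(-10, 10, length.out = 5000), fs)
  err <- abs(quantize(ramp, q)$samples - ramp$samples)
  expect_true(max(err) <= lsb / 2 + 1e-12)

  # brute-force oracle over all levels at 8 bits
  q8 <- quantizer_spec(8, -10, 10)
  levels <- -10 + (0:(2^8 - 1)) * (20 / (2^8 - 1))
  set.seed(19)
  x <- time_series(runif(300, -9.99, 9.99), fs)  # ties have measure zero
  got <- quantize(x, q8)$samples
  oracle <- vapply(x$samples,
                   function(v) levels[which.min(abs(levels - v))], 0)
  expect_equal(got, oracle, tolerance = 1e-12)

  # random signals: half-LSB bound holds in-range
  set.seed(7)
  for (k in 1:5) {
    xr <- time_series(runif(500, -10, 10), fs)
    expect_true(max(abs(quantize(xr, q)$samples - xr$samples)) <=
                  lsb / 2 + 1e-12)
  }
  expect_error(quantizer_spec(16, 10, -10), "vmax")
  expect_error(quantizer_spec(1), "bits")
})

test_that("slicing uses half-open intervals and partitions exactly", {
  fs <- 10000
  ts <- time_series(rnorm(10 * fs), fs)
  expect_identical(slice_series(ts, 0, 10)$samples, ts$samples)

  s <- slice_series(ts, 1.0, 1.5)
  expect_length(s$samples, 5000)
  expect_equal(s$t0, 1.0)

  a <- slice_series(ts, 0.7, 3.2)
  b <- slice_series(ts, 3.2, 6.1)
  whole <- slice_series(ts, 0.7, 6.1)
  expect_identical(concat_series(a, b)$samples, whole$samples)

  # non-aligned boundaries round inward to sample times
  odd <- slice_series(ts, 1.00003, 1.00017)
  expect_equal(odd$t0, 1.0001)
  expect_length(odd$samples, 1)

  expect_error(slice_series(ts, 5, 5), "start")
  expect_error(slice_series(ts, -1, 2), "outside")
})

test_that("signal tables and annotations round-trip losslessly", {
  fs <- 1000
  set.seed(3)
  chans <- list(
    ECG_ref = time_series(rnorm(fs, sd = 1e-4), fs, label = "ECG_ref"),
    cECG = time_series(rnorm(fs, sd = 1e-4), fs, label = "cECG"),
    EMG_ref = time_series(rnorm(fs, sd = 1e-4), fs, label = "EMG_ref"),
    cEMG = time_series(rnorm(fs, sd = 1e-4), fs, label = "cEMG"))
  path <- withr::local_tempfile(fileext = ".csv")
  write_signal_table(chans, path)
  back <- read_signal_table(path)
  expect_named(back, names(chans))
  for (nm in names(chans)) {
    expect_equal(back[[nm]]$fs, fs)
    expect_length(back[[nm]]$samples, length(chans[[nm]]$samples))
    expect_true(max(abs(back[[nm]]$samples - chans[[nm]]$samples)) < 1e-9)
  }

  apath <- withr::local_tempfile(fileext = ".csv")
  ann <- event_annotations(seq(10, 70, by = 10), "two_cough")
  write_annotations(ann, apath)
  back_ann <- read_annotations(apath)
  expect_equal(nrow(back_ann), 7)
  expect_equal(back_ann$time_s, ann$time_s)

  writeLines(c("time_s,label", "5,x", "3,x"), apath)
  expect_error(read_annotations(apath), "increasing")
  writeLines(c("a,b", "1,2"), apath)
  expect_error(read_annotations(apath), "time_s")
})
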