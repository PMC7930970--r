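#' Uniformly sampled voltage signal
#'
#' Container for a single channel of a uniformly sampled real-valued voltage
#' recording. The time of sample `i` (1-based) is exactly
#' `t0 + (i - 1) / fs`; all downstream operations rely on this convention,
#' with intervals treated as half-open `[start, end)`.
#'
#' @param samples Numeric vector of sample values, in volts.
#' @param fs Sampling rate in Hz (scalar, > 0).
#' @param t0 Time of the first sample in seconds from record start.
#' @param label Channel name, e.g. `"ECG_ref"` or `"cECG"`.
#' @return An object of class `time_series` with fields `samples`, `fs`,
#'   `t0` and `label`.
#' @examples
#' ts <- time_series(sin(2 * pi * 5 * seq(0, 1, by = 1e-3)), fs = 1000)
#' ts_duration(ts)
#' @export
time_series <- function(samples, fs, t0 = 0, label = "signal") {
  if (!is.numeric(samples) || length(samples) == 0L) {
    stop("`samples` must be a non-empty numeric vector", call. = FALSE)
  }
  if (!is.numeric(fs) || length(fs) != 1L || !is.finite(fs) || fs <= 0) {
    stop("`fs` must be a single positive number (Hz)", call. = FALSE)
  }
  if (!is.numeric(t0) || length(t0) != 1L || !is.finite(t0)) {
    stop("`t0` must be a single finite number (s)", call. = FALSE)
  }
  structure(
    list(samples = as.numeric(samples), fs = as.numeric(fs),
         t0 = as.numeric(t0), label = as.character(label)[1L]),
    class = "time_series"
  )
}

#' @export
print.time_series <- function(x, ...) {
  cat(sprintf("<time_series> %s: %d samples @ %g Hz, t = [%.6g, %.6g) s\n",
              x$label, length(x$samples), x$fs, x$t0, ts_end(x)))
  invisible(x)
}

#' Sample times, duration and end time of a signal
#'
#' `ts_times()` returns the time stamp of every sample; `ts_duration()` the
#' record length `n / fs`; `ts_end()` the half-open end time `t0 + n / fs`.
#'
#' @param ts A [time_series()].
#' @return Numeric vector (`ts_times`) or scalar, in seconds.
#' @export
ts_times <- function(ts) {
  stopifnot(inherits(ts, "time_series"))
  ts$t0 + (seq_along(ts$samples) - 1) / ts$fs
}

#' @rdname ts_times
#' @export
ts_duration <- function(ts) length(ts$samples) / ts$fs

#' @rdname ts_times
#' @export
ts_end <- function(ts) ts$t0 + length(ts$samples) / ts$fs

#' Uniform quantizer specification
#'
#' Describes an ideal analog-to-digital converter with `2^bits` uniformly
#' spaced levels spanning `[vmin, vmax]`; the defaults correspond to a
#' 16-bit, +/-10 V acquisition front end.
#'
#' @param bits Number of bits (integer >= 2).
#' @param vmin,vmax Input range bounds in volts, `vmax > vmin`.
#' @return An object of class `quantizer_spec`.
#' @export
quantizer_spec <- function(bits = 16L, vmin = -10, vmax = 10) {
  bits <- as.integer(bits)
  if (is.na(bits) || bits < 2L) {
    stop("`bits` must be an integer >= 2", call. = FALSE)
  }
  if (!is.finite(vmin) || !is.finite(vmax) || vmax <= vmin) {
    stop("quantizer range requires vmax > vmin", call. = FALSE)
  }
  structure(list(bits = bits, vmin = vmin, vmax = vmax),
            class = "quantizer_spec")
}

#' Quantize a signal to uniformly spaced levels
#'
#' Maps every sample to the nearest of the `2^bits` uniformly spaced
#' levels spanning `[vmin, vmax]` inclusive (so both bounds are exact
#' levels); values outside the range are clipped to the nearest bound.
#' For in-range inputs the quantization error is bounded by half of one
#' level spacing, `(vmax - vmin) / (2^bits - 1) / 2`.
#'
#' @param ts A [time_series()].
#' @param q A [quantizer_spec()].
#' @return A `time_series` whose samples all lie on quantizer levels.
#' @export
quantize <- function(ts, q = quantizer_spec()) {
  stopifnot(inherits(ts, "time_series"))
  if (!inherits(q, "quantizer_spec")) {
    stop("`q` must be a quantizer_spec", call. = FALSE)
  }
  n_levels <- 2^q$bits
  lsb <- (q$vmax - q$vmin) / (n_levels - 1)
  idx <- round((ts$samples - q$vmin) / lsb)
  idx <- pmin(pmax(idx, 0), n_levels - 1)
  out <- ts
  out$samples <- q$vmin + idx * lsb
  out
}

#' Extract a time slice of a signal
#'
#' Returns the samples falling in the half-open interval `[start, end)`.
#' Boundaries that are not sample-aligned are rounded inward: the start is
#' rounded up and the end down to sample times.
#'
#' @param ts A [time_series()].
#' @param start,end Slice boundaries in seconds; must satisfy
#'   `t0 <= start < end <= ts_end(ts)` (up to one-sample numerical slack).
#' @return A `time_series` whose `t0` is the time of the first included
#'   sample. Two adjacent slices `[a, b)` and `[b, c)` partition `[a, c)`
#'   exactly.
#' @export
slice_series <- function(ts, start, end) {
  stopifnot(inherits(ts, "time_series"))
  if (start >= end) stop("`start` must be < `end`", call. = FALSE)
  eps <- 1e-9 / ts$fs
  if (start < ts$t0 - eps || end > ts_end(ts) + eps) {
    stop("slice [", start, ", ", end, ") outside record [",
         ts$t0, ", ", ts_end(ts), ")", call. = FALSE)
  }
  i0 <- ceiling((start - ts$t0) * ts$fs - 1e-9)  # first sample with t >= start
  i1 <- ceiling((end - ts$t0) * ts$fs - 1e-9)    # first sample with t >= end
  i0 <- max(i0, 0L)
  i1 <- min(i1, length(ts$samples))
  if (i1 <= i0) stop("slice contains no samples", call. = FALSE)
  out <- ts
  out$samples <- ts$samples[(i0 + 1):i1]
  out$t0 <- ts$t0 + i0 / ts$fs
  out
}

#' Concatenate two contiguous slices
#'
#' Joins a slice ending at time `t` with one starting at `t`; used to check
#' the partition property of [slice_series()].
#'
#' @param a,b `time_series` objects with equal `fs` and
#'   `ts_end(a) == b$t0` (to within one nanosample).
#' @return A `time_series` covering `[a$t0, ts_end(b))`.
#' @export
concat_series <- function(a, b) {
  stopifnot(inherits(a, "time_series"), inherits(b, "time_series"))
  if (abs(a$fs - b$fs) > 0) stop("sampling rates differ", call. = FALSE)
  if (abs(ts_end(a) - b$t0) > 1e-9 / a$fs) {
    stop("series are not contiguous", call. = FALSE)
  }
  out <- a
  out$samples <- c(a$samples, b$samples)
  out
}

#' Event annotations
#'
#' Ordered list of time-stamped events, e.g. the recorded stamp of each
#' "two-cough" cycle in a recording session. Times must be strictly
#' increasing within each label.
#'
#' @param time_s Numeric vector of event times in seconds.
#' @param label Character vector of event labels (recycled to length).
#' @return A data.frame of class `event_annotations` with columns
#'   `time_s` and `label`.
#' @export
event_annotations <- function(time_s, label = "event") {
  time_s <- as.numeric(time_s)
  label <- rep_len(as.character(label), length(time_s))
  for (lab in unique(label)) {
    tt <- time_s[label == lab]
    if (length(tt) > 1L && any(diff(tt) <= 0)) {
      stop("event times for label '", lab,
           "' must be strictly increasing", call. = FALSE)
    }
  }
  structure(data.frame(time_s = time_s, label = label,
                       stringsAsFactors = FALSE),
            class = c("event_annotations", "data.frame"))
}
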