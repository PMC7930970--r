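#' EMG preprocessing configuration
#'
#' Band-pass for surface-EMG burst analysis; the 40-500 Hz default is the
#' analysis band of the cough statistic (components below 40 Hz are
#' suppressed so ECG R-waves do not leak into the EMG channel).
#'
#' @param band Length-2 pass band in Hz.
#' @param filter_order Butterworth order (even).
#' @return An object of class `emg_preprocess_config`.
#' @export
emg_preprocess_config <- function(band = c(40, 500), filter_order = 4L) {
  stopifnot(length(band) == 2L, band[1] > 0, band[1] < band[2],
            filter_order %% 2 == 0)
  structure(list(band = band, filter_order = as.integer(filter_order)),
            class = "emg_preprocess_config")
}

#' Band-pass an EMG channel
#'
#' Zero-phase Butterworth band-pass; length preserved.
#'
#' @param ts A [time_series()].
#' @param cfg An [emg_preprocess_config()].
#' @return A `time_series`.
#' @export
preprocess_emg <- function(ts, cfg = emg_preprocess_config()) {
  stopifnot(inherits(ts, "time_series"),
            inherits(cfg, "emg_preprocess_config"))
  if (cfg$band[2] >= ts$fs / 2) {
    stop("pass band must lie below the Nyquist frequency ", ts$fs / 2,
         " Hz", call. = FALSE)
  }
  bf <- signal::butter(cfg$filter_order / 2L, cfg$band / (ts$fs / 2),
                       type = "pass")
  out <- ts
  out$samples <- signal::filtfilt(bf, ts$samples)
  out$label <- paste0(ts$label, "_bp")
  out
}

#' Cough-segment selection configuration
#'
#' Parameters of the automated two-cough segment selection: RMS-envelope
#' onset detection around each recorded time stamp, exclusion of the first
#' and last cycles, extension of the interior segments to a common
#' duration (`extension_factor` times the mean duration), and selection of
#' stable resting segments.
#'
#' @param extension_factor Common-duration factor applied to the mean
#'   duration (>= 1; default 1.2).
#' @param exclude_first_last Drop the first and last cycles before
#'   averaging durations (default `TRUE`).
#' @param n_rest_segments Number of resting segments to select (default 5).
#' @param envelope_window Short-time RMS window, seconds (default 0.05).
#' @param onset_k Activity threshold in rest-envelope SDs above the rest
#'   mean (default 5).
#' @param search_halfwidth Half-width of the search window around each
#'   time stamp, seconds (default 3).
#' @param merge_span Gaps in the activity mask shorter than this are
#'   bridged so the two coughs of a cycle form one segment (default 0.5 s).
#' @return An object of class `segment_selection_config`.
#' @export
segment_selection_config <- function(extension_factor = 1.2,
                                     exclude_first_last = TRUE,
                                     n_rest_segments = 5L,
                                     envelope_window = 0.05,
                                     onset_k = 5, search_halfwidth = 3,
                                     merge_span = 0.5) {
  if (extension_factor < 1) {
    stop("`extension_factor` must be >= 1", call. = FALSE)
  }
  structure(list(extension_factor = extension_factor,
                 exclude_first_last = isTRUE(exclude_first_last),
                 n_rest_segments = as.integer(n_rest_segments),
                 envelope_window = envelope_window, onset_k = onset_k,
                 search_halfwidth = search_halfwidth,
                 merge_span = merge_span),
            class = "segment_selection_config")
}

# Short-time RMS envelope (centered window).
rms_envelope <- function(ts, window) {
  sqrt(rolling_mean(ts$samples^2, round(window * ts$fs)))
}

#' Envelope statistics of a resting period
#'
#' Mean and SD of the short-time RMS envelope over a rest interval; used
#' as the reference for cough-onset and resting-stability thresholds.
#'
#' @param ts Band-passed EMG [time_series()].
#' @param rest_window Length-2 vector `c(start, end)` in seconds of a
#'   known rest period, or `NULL` to use the whole record.
#' @param cfg A [segment_selection_config()].
#' @return List with `mu`, `sigma` (volts) and the window used.
#' @export
rest_envelope_stats <- function(ts, rest_window = NULL,
                                cfg = segment_selection_config()) {
  stopifnot(inherits(ts, "time_series"))
  r <- if (is.null(rest_window)) ts else
    slice_series(ts, rest_window[1], rest_window[2])
  env <- rms_envelope(r, cfg$envelope_window)
  list(mu = mean(env), sigma = stats::sd(env),
       window = c(r$t0, ts_end(r)))
}

#' Locate a two-cough segment around a recorded time stamp
#'
#' Computes the short-time RMS envelope in a window around the stamp,
#' marks samples whose envelope exceeds `mu_rest + onset_k * sigma_rest`,
#' bridges gaps shorter than `merge_span` (so the two coughs of a cycle
#' form one segment), and returns the span from the first to the last
#' active sample.
#'
#' @param emg Band-passed EMG [time_series()].
#' @param stamp Recorded time stamp of the cycle, seconds.
#' @param rest_stats Output of [rest_envelope_stats()].
#' @param cfg A [segment_selection_config()].
#' @param cycle_index Optional index stored in the result.
#' @return A `cough_segment`: list with `start`, `end`, `middle`,
#'   `duration` (s) and `cycle_index`.
#' @export
locate_cough_segment <- function(emg, stamp, rest_stats,
                                 cfg = segment_selection_config(),
                                 cycle_index = NA_integer_) {
  stopifnot(inherits(emg, "time_series"))
  if (stamp < emg$t0 || stamp > ts_end(emg)) {
    stop("stamp ", stamp, " s lies outside the record", call. = FALSE)
  }
  w0 <- max(emg$t0, stamp - cfg$search_halfwidth)
  w1 <- min(ts_end(emg), stamp + cfg$search_halfwidth)
  win <- slice_series(emg, w0, w1)
  env <- rms_envelope(win, cfg$envelope_window)
  thr <- rest_stats$mu + cfg$onset_k * rest_stats$sigma
  active <- env > thr
  if (!any(active)) {
    stop("no EMG activity found around stamp ", stamp, " s", call. = FALSE)
  }
  # bridge gaps shorter than merge_span
  gap_n <- round(cfg$merge_span * win$fs)
  r <- rle(active)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  for (k in which(!r$values)) {
    if (k > 1L && k < length(r$values) && r$lengths[k] < gap_n) {
      active[starts[k]:ends[k]] <- TRUE
    }
  }
  idx <- which(active)
  seg_start <- win$t0 + (idx[1L] - 1L) / win$fs
  seg_end <- win$t0 + (idx[length(idx)] - 1L) / win$fs
  structure(list(start = seg_start, end = seg_end,
                 middle = (seg_start + seg_end) / 2,
                 duration = seg_end - seg_start,
                 cycle_index = cycle_index),
            class = "cough_segment")
}

#' @export
print.cough_segment <- function(x, ...) {
  cat(sprintf("<cough_segment> [%0.3f, %0.3f] s (%.3f s, middle %.3f s)\n",
              x$start, x$end, x$duration, x$middle))
  invisible(x)
}

#' Mean duration of the interior two-cough segments
#'
#' The first and last segments are excluded for stability before
#' averaging (configurable).
#'
#' @param segments List of `cough_segment` objects, in cycle order.
#' @param cfg A [segment_selection_config()].
#' @return Mean duration in seconds.
#' @export
mean_duration <- function(segments, cfg = segment_selection_config()) {
  durs <- vapply(segments, function(s) s$duration, 0)
  if (cfg$exclude_first_last) {
    if (length(durs) < 3L) {
      stop("need >= 3 segments to exclude the first and last",
           call. = FALSE)
    }
    durs <- durs[-c(1L, length(durs))]
  }
  mean(durs)
}

#' Extend interior segments to a common analysis duration
#'
#' Replaces each retained (interior) segment by a window of duration
#' `extension_factor * md` centered on its middle point — the "coughing
#' segments" carried into spectral analysis.
#'
#' @param segments List of `cough_segment` objects in cycle order.
#' @param md Mean duration from [mean_duration()], seconds.
#' @param cfg A [segment_selection_config()].
#' @param record_span Optional `c(start, end)` of the record; an extended
#'   window falling outside it is an error.
#' @return A data.frame with columns `start`, `end`, `middle`,
#'   `cycle_index`; `n_cycles - 2` rows when first/last are excluded.
#' @export
extend_segments <- function(segments, md, cfg = segment_selection_config(),
                            record_span = NULL) {
  keep <- segments
  if (cfg$exclude_first_last) {
    if (length(keep) < 3L) stop("need >= 3 segments", call. = FALSE)
    keep <- keep[-c(1L, length(keep))]
  }
  half <- cfg$extension_factor * md / 2
  out <- do.call(rbind, lapply(keep, function(s) {
    data.frame(start = s$middle - half, end = s$middle + half,
               middle = s$middle, cycle_index = s$cycle_index)
  }))
  if (!is.null(record_span) &&
      (any(out$start < record_span[1]) || any(out$end > record_span[2]))) {
    stop("extended segment clipped at the record edge", call. = FALSE)
  }
  out
}

#' Select stable resting segments
#'
#' Tiles candidate windows of the coughing-segment duration over a rest
#' period and keeps windows whose envelope maximum stays below the
#' activity threshold `mu_rest + onset_k * sigma_rest` — the automated
#' counterpart of visually excluding segments with EMG firings from
#' swallowing or inhalation.
#'
#' @param emg Band-passed EMG [time_series()].
#' @param rest_window `c(start, end)` of the rest period, seconds.
#' @param duration Window duration (the coughing-segment duration), s.
#' @param rest_stats Output of [rest_envelope_stats()].
#' @param cfg A [segment_selection_config()]; `n_rest_segments` windows
#'   are returned.
#' @return Data.frame with columns `start`, `end`.
#' @export
select_resting_segments <- function(emg, rest_window, duration, rest_stats,
                                    cfg = segment_selection_config()) {
  stopifnot(inherits(emg, "time_series"))
  span <- rest_window[2] - rest_window[1]
  if (duration > span) {
    stop("segment duration ", duration, " s exceeds the rest period (",
         span, " s)", call. = FALSE)
  }
  thr <- rest_stats$mu + cfg$onset_k * rest_stats$sigma
  starts <- seq(rest_window[1], rest_window[2] - duration, by = duration)
  stable <- list()
  for (s in starts) {
    win <- slice_series(emg, s, s + duration)
    if (max(rms_envelope(win, cfg$envelope_window)) < thr) {
      stable[[length(stable) + 1L]] <- c(start = s, end = s + duration)
    }
    if (length(stable) == cfg$n_rest_segments) break
  }
  if (length(stable) < cfg$n_rest_segments) {
    stop("only ", length(stable), " stable resting segments found; need ",
         cfg$n_rest_segments, call. = FALSE)
  }
  as.data.frame(do.call(rbind, stable))
}

#' Single-sided DFT amplitude spectrum
#'
#' Unwindowed (rectangular) DFT of a segment: amplitudes are
#' `(2/N)|X_k|` for `0 < k < N/2` and `(1/N)|X_k|` at DC and (for even
#' `N`) Nyquist, so a unit sinusoid at a bin frequency appears with
#' amplitude 1. The spectrum satisfies Parseval's relation:
#' `A_0^2 + A_Nyq^2 + sum(A_k^2)/2 = mean(x^2)`.
#'
#' @param x Numeric vector of segment samples, or a [time_series()].
#' @param fs Sampling rate in Hz (ignored when `x` is a `time_series`).
#' @param window `"rectangular"` (canonical) or `"hann"`.
#' @return List with `frequency` (Hz) and `amplitude` (volts per bin).
#' @export
amplitude_spectrum <- function(x, fs = NULL, window = c("rectangular",
                                                        "hann")) {
  window <- match.arg(window)
  if (inherits(x, "time_series")) {
    fs <- x$fs
    x <- x$samples
  }
  stopifnot(is.numeric(x), length(x) >= 2L, !is.null(fs))
  if (window == "hann") {
    n <- length(x)
    h <- 0.5 - 0.5 * cos(2 * pi * (seq_len(n) - 1) / (n - 1))
    x <- x * h / mean(h)  # amplitude-normalized
  }
  n <- length(x)
  X <- stats::fft(x)
  n_half <- n %/% 2L
  k <- 0:n_half
  amp <- 2 / n * Mod(X[k + 1L])
  amp[1L] <- Mod(X[1L]) / n
  if (n %% 2L == 0L) amp[length(amp)] <- Mod(X[n_half + 1L]) / n
  list(frequency = k * fs / n, amplitude = amp)
}

#' Total spectral amplitude over a frequency band
#'
#' Sum of DFT amplitude bins with `f_lo <= f <= f_hi` (inclusive bounds);
#' the cough-activity statistic over 40-500 Hz.
#'
#' @param spectrum Output of [amplitude_spectrum()].
#' @param f_lo,f_hi Band edges in Hz.
#' @return TSA (volts, summed over bins), >= 0.
#' @export
total_spectral_amplitude <- function(spectrum, f_lo = 40, f_hi = 500) {
  stopifnot(f_lo < f_hi)
  sel <- spectrum$frequency >= f_lo & spectrum$frequency <= f_hi
  sum(spectrum$amplitude[sel])
}

#' Normality-gated paired comparison of TSA values
#'
#' Tests whether coughing-segment TSAs exceed resting-segment TSAs.
#' Normality of the paired differences is assessed by a Shapiro-Wilk test
#' at `alpha`; if not rejected a paired t-test is used, otherwise a
#' Wilcoxon signed-rank test. The alternative is one-sided (coughing >
#' resting) by default.
#'
#' @param rest_tsas,cough_tsas Equal-length numeric vectors (n >= 3) of
#'   per-segment TSA values.
#' @param alpha Significance level of the normality gate.
#' @param alternative `"greater"` (coughing > resting) or `"two.sided"`.
#' @return A `tsa_comparison`: list with `test_name` (`"paired-t"` or
#'   `"wilcoxon-signed-rank"`), `statistic`, `p_value`, `direction`
#'   (`"coughing>resting"`, `"resting>coughing"` or `"none"`),
#'   `normality_p`, and the group means. Degenerate input (all paired
#'   differences zero) yields `p_value = NA`.
#' @export
compare_tsa <- function(rest_tsas, cough_tsas, alpha = 0.05,
                        alternative = c("greater", "two.sided")) {
  alternative <- match.arg(alternative)
  stopifnot(length(rest_tsas) == length(cough_tsas),
            length(rest_tsas) >= 3L)
  d <- cough_tsas - rest_tsas
  direction <- if (mean(d) > 0) "coughing>resting"
               else if (mean(d) < 0) "resting>coughing" else "none"
  base <- list(direction = direction,
               mean_rest = mean(rest_tsas), mean_cough = mean(cough_tsas))
  if (all(d == 0)) {
    return(structure(c(list(test_name = "wilcoxon-signed-rank",
                            statistic = NA_real_, p_value = NA_real_,
                            normality_p = NA_real_), base),
                     class = "tsa_comparison"))
  }
  normality_p <- if (stats::sd(d) > 0) {
    tryCatch(stats::shapiro.test(d)$p.value, error = function(e) NA_real_)
  } else NA_real_
  use_t <- !is.na(normality_p) && normality_p >= alpha
  res <- if (use_t) {
    ht <- stats::t.test(cough_tsas, rest_tsas, paired = TRUE,
                        alternative = alternative)
    list(test_name = "paired-t", statistic = unname(ht$statistic),
         p_value = ht$p.value)
  } else {
    ht <- suppressWarnings(
      stats::wilcox.test(cough_tsas, rest_tsas, paired = TRUE,
                         alternative = alternative))
    list(test_name = "wilcoxon-signed-rank",
         statistic = unname(ht$statistic), p_value = ht$p.value)
  }
  structure(c(res, list(normality_p = normality_p), base),
            class = "tsa_comparison")
}

#' @export
print.tsa_comparison <- function(x, ...) {
  cat(sprintf("<tsa_comparison> %s: statistic %.4g, p = %.4g (%s)\n",
              x$test_name, x$statistic, x$p_value, x$direction))
  invisible(x)
}

#' Full cough TSA analysis of one EMG channel
#'
#' Wires the segment-selection steps together for a session: band-pass,
#' rest-envelope statistics, per-cycle segment location, mean duration of
#' the interior segments, extension to the common coughing-segment
#' duration, resting-segment selection, per-segment TSA, and the
#' normality-gated paired comparison.
#'
#' @param emg Raw EMG [time_series()].
#' @param stamps Numeric vector of two-cough time stamps, seconds.
#' @param rest_window `c(start, end)` of the rest period used both for
#'   envelope statistics and resting segments.
#' @param pre_cfg An [emg_preprocess_config()].
#' @param seg_cfg A [segment_selection_config()].
#' @param band TSA band, Hz.
#' @return List with `segments` (located cycles), `md`, `coughing`
#'   (extended segments), `resting`, `tsa_cough`, `tsa_rest`,
#'   `comparison` and `segment_duration`.
#' @export
analyze_cough_emg <- function(emg, stamps, rest_window,
                              pre_cfg = emg_preprocess_config(),
                              seg_cfg = segment_selection_config(),
                              band = c(40, 500)) {
  bp <- preprocess_emg(emg, pre_cfg)
  rstats <- rest_envelope_stats(bp, rest_window, seg_cfg)
  segs <- lapply(seq_along(stamps), function(k) {
    locate_cough_segment(bp, stamps[k], rstats, seg_cfg, cycle_index = k)
  })
  md <- mean_duration(segs, seg_cfg)
  coughing <- extend_segments(segs, md, seg_cfg,
                              record_span = c(bp$t0, ts_end(bp)))
  seg_dur <- coughing$end[1] - coughing$start[1]
  resting <- select_resting_segments(bp, rest_window, seg_dur, rstats,
                                     seg_cfg)
  tsa_of <- function(s0, s1) {
    total_spectral_amplitude(
      amplitude_spectrum(slice_series(bp, s0, s1)), band[1], band[2])
  }
  tsa_cough <- mapply(tsa_of, coughing$start, coughing$end)
  tsa_rest <- mapply(tsa_of, resting$start, resting$end)
  n <- min(length(tsa_cough), length(tsa_rest))
  list(segments = segs, md = md, coughing = coughing, resting = resting,
       tsa_cough = tsa_cough, tsa_rest = tsa_rest,
       comparison = compare_tsa(tsa_rest[seq_len(n)],
                                tsa_cough[seq_len(n)]),
       segment_duration = seg_dur)
}
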