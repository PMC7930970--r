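#' ECG preprocessing configuration
#'
#' The R-wave emphasis chain: moving average (20-ms window), band-pass
#' filtering (IIR Butterworth, 10-20 Hz), and differential processing over
#' a 10-ms interval. The band-pass is applied forward-backward
#' (zero-phase) so detected extremum times stay alignable with the source.
#'
#' @param ma_window Moving-average window, seconds.
#' @param band Length-2 pass band in Hz.
#' @param diff_interval Differencing interval, seconds.
#' @param filter_order Butterworth order of the band-pass (even; realized
#'   as `butter(filter_order/2)` band-pass sections).
#' @return An object of class `ecg_preprocess_config`.
#' @export
ecg_preprocess_config <- function(ma_window = 0.020, band = c(10, 20),
                                  diff_interval = 0.010, filter_order = 4L) {
  stopifnot(ma_window > 0, diff_interval > 0, length(band) == 2L,
            band[1] > 0, band[1] < band[2], filter_order %% 2 == 0)
  structure(list(ma_window = ma_window, band = band,
                 diff_interval = diff_interval,
                 filter_order = as.integer(filter_order)),
            class = "ecg_preprocess_config")
}

#' Preprocess an ECG channel for R-wave detection
#'
#' Applies, in order: centered moving average (edges truncated to the
#' available samples), zero-phase Butterworth band-pass, and the finite
#' difference `y[n] = x[n] - x[n - D]` with `D = round(diff_interval *
#' fs)`. Length is preserved; the leading `D` samples of the output are 0.
#'
#' @param ts A [time_series()].
#' @param cfg An [ecg_preprocess_config()].
#' @return A `time_series` of the same length.
#' @export
preprocess_ecg <- function(ts, cfg = ecg_preprocess_config()) {
  stopifnot(inherits(ts, "time_series"))
  if (!inherits(cfg, "ecg_preprocess_config")) {
    stop("`cfg` must be an ecg_preprocess_config", call. = FALSE)
  }
  if (cfg$band[2] >= ts$fs / 2) {
    stop("pass band must lie below the Nyquist frequency ", ts$fs / 2,
         " Hz", call. = FALSE)
  }
  if (ts_duration(ts) <= cfg$ma_window + cfg$diff_interval) {
    stop("record too short for the preprocessing chain", call. = FALSE)
  }
  x <- rolling_mean(ts$samples, round(cfg$ma_window * ts$fs))
  x <- x - mean(x)  # DC is in the stop band; removing it first avoids
                    # start-up transients of the zero-phase filter
  bf <- signal::butter(cfg$filter_order / 2L, cfg$band / (ts$fs / 2),
                       type = "pass")
  x <- signal::filtfilt(bf, x)
  d <- round(cfg$diff_interval * ts$fs)
  n <- length(x)
  y <- numeric(n)
  if (d < n) y[(d + 1):n] <- x[(d + 1):n] - x[1:(n - d)]
  out <- ts
  out$samples <- y
  out$label <- paste0(ts$label, "_prep")
  out
}

# Local extrema of the preprocessed trace, refractory-separated by greedy
# magnitude ordering, restricted to one polarity. Returns a data.frame with
# columns time and amp, ordered by time.
candidate_extrema <- function(prep, polarity, refractory, floor_frac) {
  x <- prep$samples * polarity
  n <- length(x)
  is_max <- c(FALSE, x[2:(n - 1)] > x[1:(n - 2)] & x[2:(n - 1)] >= x[3:n],
              FALSE)
  idx <- which(is_max & x > 0)
  if (length(idx) == 0L) return(data.frame(time = numeric(0),
                                           amp = numeric(0)))
  idx <- idx[x[idx] >= floor_frac * max(x[idx])]
  # greedy refractory suppression, largest magnitude first
  ord <- idx[order(-x[idx])]
  keep <- numeric(0)
  ref_n <- refractory * prep$fs
  for (i in ord) {
    if (length(keep) == 0L || all(abs(keep - i) >= ref_n)) keep <- c(keep, i)
  }
  keep <- sort(keep)
  data.frame(time = prep$t0 + (keep - 1) / prep$fs,
             amp = prep$samples[keep])
}

# Dominant polarity: sign whose top-|n_waves| refractory-separated extrema
# have the larger mean magnitude.
detect_polarity <- function(prep, refractory, n_waves, floor_frac) {
  top_mean <- function(pol) {
    ce <- candidate_extrema(prep, pol, refractory, floor_frac)
    if (nrow(ce) == 0L) return(0)
    mean(utils::head(sort(abs(ce$amp), decreasing = TRUE), n_waves))
  }
  if (top_mean(1) >= top_mean(-1)) 1 else -1
}

#' Estimate the R-wave detection threshold
#'
#' Selects `n_waves` assumed R-waves from the preprocessed trace and sets
#' the threshold to `fraction` of their mean amplitude, signed by the
#' dominant polarity. Candidates are local extrema of the dominant
#' polarity, separated by at least the refractory period, with magnitude at
#' least `candidate_floor` of the largest candidate (so that small ripples
#' are not mistaken for assumed R-waves). `mode = "random"` draws the
#' waves without replacement as in the original manual procedure;
#' `mode = "largest"` deterministically takes the largest-magnitude
#' candidates and is the reproducible default.
#'
#' @param prep Preprocessed `time_series` from [preprocess_ecg()].
#' @param n_waves Number of assumed R-waves to average (default 5).
#' @param fraction Fraction of the mean amplitude used as threshold
#'   (default 0.8).
#' @param mode `"largest"` or `"random"`.
#' @param refractory Minimum separation between candidates, seconds.
#' @param polarity `"auto"`, `"positive"` or `"negative"`. R-deflections
#'   may appear as troughs on capacitive channels, in which case the
#'   negative polarity is detected.
#' @param candidate_floor Minimum candidate magnitude as a fraction of the
#'   largest candidate (default 0.4).
#' @param seed Integer seed used by `mode = "random"`.
#' @return Signed threshold in volts (negative for negative polarity).
#' @export
estimate_threshold <- function(prep, n_waves = 5L, fraction = 0.8,
                               mode = c("largest", "random"),
                               refractory = 0.25, polarity = "auto",
                               candidate_floor = 0.4, seed = NULL) {
  stopifnot(inherits(prep, "time_series"))
  mode <- match.arg(mode)
  pol <- switch(polarity,
                auto = detect_polarity(prep, refractory, n_waves,
                                       candidate_floor),
                positive = 1, negative = -1,
                stop("`polarity` must be auto/positive/negative",
                     call. = FALSE))
  ce <- candidate_extrema(prep, pol, refractory, candidate_floor)
  if (nrow(ce) < n_waves && candidate_floor > 0) {
    # the magnitude floor is a robustness heuristic; when it starves the
    # candidate set (e.g. one dominant artifact), fall back to all extrema
    ce <- candidate_extrema(prep, pol, refractory, 0)
  }
  if (nrow(ce) < n_waves) {
    stop("only ", nrow(ce), " candidate waves found; need ", n_waves,
         call. = FALSE)
  }
  amps <- abs(ce$amp)
  picked <- switch(mode,
    largest = utils::head(sort(amps, decreasing = TRUE), n_waves),
    random = with_seed(seed, sample(amps, n_waves)))
  pol * fraction * mean(picked)
}

#' Detect R-waves by threshold crossing
#'
#' Emits one detection at the extremum of each maximal run of samples
#' beyond the threshold (above it for a positive threshold, below it for a
#' negative one). Detections closer than the refractory period to the
#' previous detection are suppressed, keeping the larger-magnitude one.
#'
#' @param prep Preprocessed `time_series`.
#' @param threshold Signed threshold in volts, e.g. from
#'   [estimate_threshold()]; its sign selects the polarity.
#' @param refractory Minimum inter-detection interval, seconds.
#' @return An `rpeak_train`: list with `times` (seconds) and `polarity`.
#' @export
detect_rpeaks <- function(prep, threshold, refractory = 0.25) {
  stopifnot(inherits(prep, "time_series"), is.finite(threshold),
            threshold != 0)
  pol <- sign(threshold)
  x <- prep$samples * pol
  above <- x > abs(threshold)
  times <- numeric(0)
  amps <- numeric(0)
  if (any(above)) {
    r <- rle(above)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    runs <- which(r$values)
    for (k in runs) {
      seg <- starts[k]:ends[k]
      i <- seg[which.max(x[seg])]
      times <- c(times, prep$t0 + (i - 1) / prep$fs)
      amps <- c(amps, x[i])
    }
    # refractory suppression keeping the larger magnitude
    keep_t <- numeric(0)
    keep_a <- numeric(0)
    for (j in seq_along(times)) {
      if (length(keep_t) > 0L &&
          times[j] - keep_t[length(keep_t)] < refractory) {
        if (amps[j] > keep_a[length(keep_a)]) {
          keep_t[length(keep_t)] <- times[j]
          keep_a[length(keep_a)] <- amps[j]
        }
      } else {
        keep_t <- c(keep_t, times[j])
        keep_a <- c(keep_a, amps[j])
      }
    }
    times <- keep_t
  }
  rpeak_train(times, polarity = if (pol > 0) "positive" else "negative")
}

#' Ordered train of R-wave times
#'
#' @param times Strictly increasing event times, seconds.
#' @param polarity `"positive"` or `"negative"` deflection.
#' @return An object of class `rpeak_train`.
#' @export
rpeak_train <- function(times, polarity = "positive") {
  times <- as.numeric(times)
  if (length(times) > 1L && any(diff(times) <= 0)) {
    stop("R-peak times must be strictly increasing", call. = FALSE)
  }
  structure(list(times = times,
                 polarity = match.arg(polarity, c("positive", "negative"))),
            class = "rpeak_train")
}

#' @export
print.rpeak_train <- function(x, ...) {
  cat(sprintf("<rpeak_train> %d beats (%s polarity)\n",
              length(x$times), x$polarity))
  invisible(x)
}

#' RR intervals from a detected beat train
#'
#' Each interval is the time between two consecutively detected R-waves
#' and is attached to the latter beat.
#'
#' @param train An [rpeak_train()].
#' @return A data.frame with columns `time` (latter beat, s) and `rri` (s).
#' @export
compute_rri <- function(train) {
  stopifnot(inherits(train, "rpeak_train"))
  n <- length(train$times)
  if (n < 2L) {
    return(data.frame(time = numeric(0), rri = numeric(0)))
  }
  data.frame(time = train$times[-1L], rri = diff(train$times))
}

#' Match detected beats against a reference train by RR-interval agreement
#'
#' Beats are first paired greedily by nearest time within
#' `pairing_window`. A test beat counts as a true positive when both it
#' and its predecessor are paired and its RR interval agrees with the RR
#' interval between the two paired reference beats to within `tol`
#' (+/-10 ms by default); otherwise it is a false positive and the paired
#' reference beat a false negative. Unpaired test beats are false
#' positives; unpaired reference beats false negatives. The first beat of
#' each train carries no RR interval and is excluded from the counts, and
#' there are no countable true negatives (`n_tn = 0` by convention).
#'
#' @param test,ref [rpeak_train()] objects (e.g. capacitive-channel
#'   detections vs the reference channel).
#' @param tol RR-interval agreement tolerance, seconds.
#' @param pairing_window Maximum time offset for pairing beats, seconds.
#' @return A `detection_counts` object (fields `n_tp`, `n_fp`, `n_fn`,
#'   `n_tn`). Counts conserve: `n_tp + n_fp` equals the number of
#'   RRI-bearing test beats and `n_tp + n_fn` the number of RRI-bearing
#'   reference beats.
#' @export
match_beats <- function(test, ref, tol = 0.010, pairing_window = 0.15) {
  stopifnot(inherits(test, "rpeak_train"), inherits(ref, "rpeak_train"))
  tt <- test$times
  rt <- ref$times
  nt <- length(tt)
  nr <- length(rt)
  partner <- rep(NA_integer_, nt)   # index into ref per test beat
  if (nt > 0L && nr > 0L) {
    d <- abs(outer(tt, rt, "-"))
    cand <- which(d <= pairing_window, arr.ind = TRUE)
    if (nrow(cand) > 0L) {
      cand <- cand[order(d[cand]), , drop = FALSE]
      used_r <- rep(FALSE, nr)
      for (k in seq_len(nrow(cand))) {
        i <- cand[k, 1L]
        j <- cand[k, 2L]
        if (is.na(partner[i]) && !used_r[j]) {
          partner[i] <- j
          used_r[j] <- TRUE
        }
      }
    }
  }
  tp_test <- rep(FALSE, nt)
  tp_ref <- rep(FALSE, nr)
  if (nt >= 2L) {
    for (i in 2:nt) {
      j <- partner[i]
      j_prev <- partner[i - 1L]
      if (!is.na(j) && !is.na(j_prev) && j > j_prev) {
        rri_test <- tt[i] - tt[i - 1L]
        rri_ref <- rt[j] - rt[j_prev]
        if (abs(rri_test - rri_ref) <= tol) {
          tp_test[i] <- TRUE
          tp_ref[j] <- TRUE
        }
      }
    }
  }
  n_tp <- sum(tp_test)
  n_fp <- max(nt - 1L, 0L) - n_tp
  n_fn <- max(nr - 1L, 0L) - sum(tp_ref)  # ref beat 1 can never be a TP
  detection_counts(n_tp, n_fp, n_fn)
}

#' Detection count container
#'
#' @param n_tp,n_fp,n_fn Non-negative integer counts of correctly
#'   detected, falsely detected, and undetected R-waves.
#' @param n_tn True negatives; there are no countable valid events for a
#'   beat detector, so this is fixed at zero.
#' @return An object of class `detection_counts`.
#' @export
detection_counts <- function(n_tp, n_fp, n_fn, n_tn = 0L) {
  vals <- c(n_tp, n_fp, n_fn, n_tn)
  if (any(vals < 0) || any(vals != round(vals))) {
    stop("counts must be non-negative integers", call. = FALSE)
  }
  if (n_tn != 0L) {
    stop("`n_tn` is fixed at zero by convention", call. = FALSE)
  }
  structure(list(n_tp = as.integer(n_tp), n_fp = as.integer(n_fp),
                 n_fn = as.integer(n_fn), n_tn = 0L),
            class = "detection_counts")
}

#' @export
print.detection_counts <- function(x, ...) {
  cat(sprintf("<detection_counts> TP %d, FP %d, FN %d (TN fixed at 0)\n",
              x$n_tp, x$n_fp, x$n_fn))
  invisible(x)
}

#' Sensitivity, accuracy and positive predictive value of beat detection
#'
#' Computes, in percent:
#' \deqn{P_{SNS} = 100 \frac{N_{TP}}{N_{TP} + N_{FN}}, \quad
#'       P_{ACC} = 100 \frac{N_{TP} + N_{TN}}{N_{TP} + N_{TN} + N_{FN} +
#'       N_{FP}}, \quad
#'       P_{PPV} = 100 \frac{N_{TP}}{N_{TP} + N_{FP}}.}
#' With `n_tn = 0`, accuracy never exceeds either of the other two. A
#' metric with zero denominator is reported as `NA` (undefined), never 0.
#'
#' @param counts A [detection_counts()].
#' @param digits Decimal places for the `rounded` element, rounded half
#'   away from zero (display convention; the unrounded values are also
#'   returned).
#' @return A `detection_metrics` object: list with `p_sns`, `p_acc`,
#'   `p_ppv` (unrounded percents), `rounded` (named vector) and `counts`.
#' @examples
#' detection_metrics(detection_counts(39, 154, 79))
#' @export
detection_metrics <- function(counts, digits = 1L) {
  stopifnot(inherits(counts, "detection_counts"))
  frac <- function(num, den) if (den > 0) 100 * num / den else NA_real_
  p_sns <- frac(counts$n_tp, counts$n_tp + counts$n_fn)
  p_acc <- frac(counts$n_tp + counts$n_tn,
                counts$n_tp + counts$n_tn + counts$n_fn + counts$n_fp)
  p_ppv <- frac(counts$n_tp, counts$n_tp + counts$n_fp)
  structure(list(p_sns = p_sns, p_acc = p_acc, p_ppv = p_ppv,
                 rounded = c(p_sns = round_half_up(p_sns, digits),
                             p_acc = round_half_up(p_acc, digits),
                             p_ppv = round_half_up(p_ppv, digits)),
                 counts = counts),
            class = "detection_metrics")
}

#' @export
print.detection_metrics <- function(x, ...) {
  r <- x$rounded
  cat(sprintf("<detection_metrics> P_SNS %s%%, P_ACC %s%%, P_PPV %s%%\n",
              r[["p_sns"]], r[["p_acc"]], r[["p_ppv"]]))
  invisible(x)
}

#' Run the full R-wave detection chain on one channel
#'
#' Convenience wrapper: [preprocess_ecg()], [estimate_threshold()],
#' [detect_rpeaks()].
#'
#' @param ts Raw ECG [time_series()].
#' @param prep_cfg An [ecg_preprocess_config()].
#' @param ... Passed to [estimate_threshold()].
#' @param refractory Refractory period, seconds.
#' @return An [rpeak_train()] with attribute `"threshold"`.
#' @export
detect_ecg <- function(ts, prep_cfg = ecg_preprocess_config(),
                       refractory = 0.25, ...) {
  prep <- preprocess_ecg(ts, prep_cfg)
  thr <- estimate_threshold(prep, refractory = refractory, ...)
  train <- detect_rpeaks(prep, thr, refractory = refractory)
  attr(train, "threshold") <- thr
  train
}
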