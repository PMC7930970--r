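#' Frequency bands for heart-rate-variability analysis
#'
#' VLF (DC-0.04 Hz), LF (0.04-0.15 Hz), HF (0.15-0.40 Hz) and VHF
#' (0.40-3.00 Hz). Bands must be contiguous, non-overlapping and
#' increasing. The VLF lower edge excludes the DC bin.
#'
#' @param vlf,lf,hf,vhf Length-2 numeric vectors `c(lo, hi)` in Hz.
#' @return A named list of class `hrv_bands`.
#' @export
hrv_bands <- function(vlf = c(0, 0.04), lf = c(0.04, 0.15),
                      hf = c(0.15, 0.40), vhf = c(0.40, 3.00)) {
  b <- list(vlf = vlf, lf = lf, hf = hf, vhf = vhf)
  ok_each <- all(vapply(b, function(e) e[1] < e[2], TRUE))
  joins <- vapply(seq_len(3), function(k) b[[k]][2] == b[[k + 1]][1], TRUE)
  if (!ok_each || !all(joins)) {
    stop("bands must be contiguous, non-overlapping and increasing",
         call. = FALSE)
  }
  structure(b, class = "hrv_bands")
}

#' Uniformly resampled RR-interval tachogram
#'
#' Attaches each RR interval to its latter beat time and interpolates the
#' `(time, RRI)` pairs onto a uniform grid by a cubic spline. The mean is
#' retained in the stored series (it is removed only inside the spectral
#' estimator).
#'
#' @param rpeaks An [rpeak_train()] or numeric vector of beat times (>= 3
#'   beats).
#' @param resample_hz Resampling rate of the tachogram, Hz (default 8).
#' @return A [time_series()] of RR intervals (seconds) sampled at
#'   `resample_hz`, starting at the second beat.
#' @export
tachogram <- function(rpeaks, resample_hz = 8) {
  times <- if (inherits(rpeaks, "rpeak_train")) rpeaks$times
           else as.numeric(rpeaks)
  if (length(times) < 3L) {
    stop("need at least 3 beats for a tachogram", call. = FALSE)
  }
  rri_t <- times[-1L]
  rri <- diff(times)
  grid <- seq(rri_t[1L], rri_t[length(rri_t)], by = 1 / resample_hz)
  sf <- stats::splinefun(rri_t, rri, method = "fmm")
  time_series(sf(grid), fs = resample_hz, t0 = grid[1L],
              label = "tachogram")
}

#' Welch power spectral density estimate
#'
#' Mean of modified periodograms over Hann-windowed, overlapping,
#' demeaned segments; one-sided density so that the integral of the PSD
#' over frequency equals the signal variance.
#'
#' @param ts A [time_series()] (e.g. a [tachogram()]).
#' @param nperseg Segment length in samples (default 256, shortened to the
#'   record length if needed).
#' @param overlap Fractional overlap between segments (default 0.5).
#' @return List with `frequency` (Hz) and `psd` (units^2/Hz).
#' @export
welch_psd <- function(ts, nperseg = 256L, overlap = 0.5) {
  stopifnot(inherits(ts, "time_series"))
  x <- ts$samples - mean(ts$samples)
  n <- length(x)
  nperseg <- min(as.integer(nperseg), n)
  if (nperseg < 8L) stop("record too short for a PSD estimate",
                         call. = FALSE)
  step <- max(1L, round(nperseg * (1 - overlap)))
  starts <- seq(1L, n - nperseg + 1L, by = step)
  w <- 0.5 - 0.5 * cos(2 * pi * (seq_len(nperseg) - 1) / (nperseg - 1))
  u <- sum(w^2)
  n_half <- nperseg %/% 2L
  acc <- numeric(n_half + 1L)
  for (s in starts) {
    seg <- x[s:(s + nperseg - 1L)]
    seg <- (seg - mean(seg)) * w
    X <- stats::fft(seg)
    p <- Mod(X[1:(n_half + 1L)])^2 / (u * ts$fs)
    p[2:n_half] <- 2 * p[2:n_half]  # one-sided (DC and Nyquist once)
    acc <- acc + p
  }
  list(frequency = (0:n_half) * ts$fs / nperseg,
       psd = acc / length(starts))
}

#' Band-limited PSD summary of a tachogram
#'
#' Welch PSD of the resampled RR series, summarized per HRV band. The
#' per-band statistic is the mean PSD over the frequency bins inside the
#' band (switchable to the integrated power). The DC bin is excluded, so
#' the VLF band starts at the first nonzero frequency.
#'
#' @param tach A [tachogram()] `time_series`.
#' @param bands An [hrv_bands()].
#' @param statistic `"mean"` (per-bin mean PSD, s^2/Hz) or `"integral"`
#'   (integrated band power, s^2).
#' @param nperseg,overlap Passed to [welch_psd()].
#' @return Named numeric vector with one value per band.
#' @export
band_psd <- function(tach, bands = hrv_bands(), statistic = c("mean",
                                                              "integral"),
                     nperseg = 256L, overlap = 0.5) {
  statistic <- match.arg(statistic)
  est <- welch_psd(tach, nperseg = nperseg, overlap = overlap)
  f <- est$frequency
  df <- f[2L] - f[1L]
  out <- vapply(bands, function(edges) {
    sel <- f > max(edges[1], 0) & f <= edges[2]
    if (!any(sel)) return(0)
    if (statistic == "mean") mean(est$psd[sel]) else sum(est$psd[sel]) * df
  }, 0)
  names(out) <- names(bands)
  out
}

#' Per-band PSD error rate between reference and test recordings
#'
#' For each band, `100 * |ref - test| / ref` percent. A zero reference
#' value yields `NA` (undefined), never 0.
#'
#' @param ref,test Named numeric vectors of per-band PSD values (same
#'   bands, same units).
#' @param digits Optional decimal places for display rounding (half away
#'   from zero); `NULL` returns unrounded values.
#' @return Named numeric vector of error rates in percent.
#' @export
psd_error_rate <- function(ref, test, digits = NULL) {
  stopifnot(length(ref) == length(test))
  if (!is.null(names(ref)) && !is.null(names(test))) {
    test <- test[names(ref)]
  }
  out <- ifelse(ref == 0, NA_real_, 100 * abs(ref - test) / ref)
  names(out) <- names(ref)
  if (!is.null(digits)) out <- round_half_up(out, digits)
  out
}
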