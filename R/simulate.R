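#' Configuration for the synthetic ECG generator
#'
#' Parameters of the Gaussian-bump ECG model used to emulate capacitive
#' recordings. Each beat is a sum of P, Q, R, S, T Gaussian bumps placed
#' relative to the R apex; beat-to-beat timing follows a mean heart rate
#' with optional sinusoidal LF/HF modulation of the RR interval plus white
#' RR jitter. Source-level R amplitudes of the order of 100 uV correspond
#' to what insulator-coupled neck electrodes deliver to the front end.
#'
#' @param mean_hr Mean heart rate, beats per minute (20 < mean_hr < 240).
#' @param rr_sd SD of white RR-interval jitter, seconds.
#' @param lf_mod,hf_mod Length-2 vectors `c(freq_hz, depth_s)`: sinusoidal
#'   RR modulation in the low-frequency (~0.1 Hz) and high-frequency
#'   (~0.25 Hz, respiratory) bands.
#' @param r_amp,t_amp,p_amp Bump amplitudes in volts. A distorted profile
#'   with `t_amp > r_amp` reproduces the failure mode where T-waves are
#'   taller than R-waves.
#' @param q_frac,s_frac Q and S amplitudes as fractions of `r_amp`
#'   (negative bumps).
#' @param widths Named numeric vector of Gaussian SDs in seconds for
#'   `p, q, r, s, t`.
#' @param offsets Named numeric vector of bump centers relative to the R
#'   apex, seconds.
#' @param noise_sd SD of additive white measurement noise, volts.
#' @param wander_amp,wander_corner Baseline-wander RMS (volts) and corner
#'   frequency (Hz) of the first-order shaping filter.
#' @param hf_attenuation Corner frequency (Hz) of a first-order low-pass
#'   emulating the high-frequency attenuation of a distorted capacitive
#'   channel, or `NULL` for none.
#' @param seed Integer seed, or `NULL` to use the current RNG state.
#' @return An object of class `ecg_sim_config`.
#' @export
ecg_sim_config <- function(mean_hr = 70, rr_sd = 0.02,
                           lf_mod = c(0.1, 0), hf_mod = c(0.25, 0),
                           r_amp = 100e-6, t_amp = 30e-6, p_amp = 15e-6,
                           q_frac = 0.2, s_frac = 0.25,
                           widths = c(p = 0.025, q = 0.008, r = 0.010,
                                      s = 0.008, t = 0.050),
                           offsets = c(p = -0.20, q = -0.035, r = 0,
                                       s = 0.035, t = 0.30),
                           noise_sd = 0, wander_amp = 0, wander_corner = 0.3,
                           hf_attenuation = NULL, seed = NULL) {
  if (!(mean_hr > 20 && mean_hr < 240)) {
    stop("`mean_hr` must lie in (20, 240) bpm", call. = FALSE)
  }
  if (any(c(r_amp, t_amp, p_amp, rr_sd, noise_sd, wander_amp) < 0)) {
    stop("amplitudes and noise SDs must be >= 0", call. = FALSE)
  }
  structure(list(mean_hr = mean_hr, rr_sd = rr_sd,
                 lf_mod = lf_mod, hf_mod = hf_mod,
                 r_amp = r_amp, t_amp = t_amp, p_amp = p_amp,
                 q_frac = q_frac, s_frac = s_frac,
                 widths = widths, offsets = offsets,
                 noise_sd = noise_sd, wander_amp = wander_amp,
                 wander_corner = wander_corner,
                 hf_attenuation = hf_attenuation, seed = seed),
            class = "ecg_sim_config")
}

#' Configuration for the synthetic cough-session generator
#'
#' Describes the "cough twice, seven times" protocol: an initial rest
#' period, `n_cycles` two-cough cycles (two band-limited EMG bursts per
#' cycle), and a final rest period. Bursts are white noise band-passed to
#' `burst_band` and scaled to `burst_rms`; the capacitive EMG channel is a
#' scaled, noisier copy of the reference channel.
#'
#' @param n_cycles Number of two-cough cycles (>= 3; the segment-selection
#'   algorithm discards the first and last).
#' @param burst_duration Duration of each cough burst, seconds.
#' @param intra_pair_gap Gap between the two bursts of a cycle, seconds.
#' @param inter_cycle_gap Gap between consecutive cycles, seconds (> 0).
#' @param burst_band Length-2 vector, burst pass band in Hz.
#' @param burst_rms RMS of each burst in the reference EMG, volts.
#' @param rest_rms RMS of the resting noise floor, volts.
#' @param post_cough_wander Amplitude (volts) of the decaying baseline
#'   transient injected into the capacitive ECG after each cycle.
#' @param cemg_scale Attenuation of burst amplitude in the capacitive EMG
#'   relative to the reference (the electrode-output EMG amplitude is a
#'   free parameter of the model).
#' @param seed Integer seed, or `NULL`.
#' @return An object of class `cough_sim_config`.
#' @export
cough_sim_config <- function(n_cycles = 7L, burst_duration = 0.4,
                             intra_pair_gap = 0.3, inter_cycle_gap = 5,
                             burst_band = c(40, 500),
                             burst_rms = 200e-6, rest_rms = 20e-6,
                             post_cough_wander = 100e-6,
                             cemg_scale = 0.5, seed = NULL) {
  n_cycles <- as.integer(n_cycles)
  if (n_cycles < 3L) stop("`n_cycles` must be >= 3", call. = FALSE)
  if (inter_cycle_gap <= 0) {
    stop("`inter_cycle_gap` must be > 0 (cycles may not overlap)",
         call. = FALSE)
  }
  stopifnot(burst_duration > 0, intra_pair_gap > 0,
            length(burst_band) == 2L, burst_band[1] < burst_band[2])
  structure(list(n_cycles = n_cycles, burst_duration = burst_duration,
                 intra_pair_gap = intra_pair_gap,
                 inter_cycle_gap = inter_cycle_gap,
                 burst_band = burst_band, burst_rms = burst_rms,
                 rest_rms = rest_rms, post_cough_wander = post_cough_wander,
                 cemg_scale = cemg_scale, seed = seed),
            class = "cough_sim_config")
}

#' Simulate a beat-time series with modulated RR intervals
#'
#' Generates ordered beat times where each RR interval is
#' `60/mean_hr + lf_depth*sin(2*pi*f_LF*t) + hf_depth*sin(2*pi*f_HF*t) +
#' N(0, rr_sd)`. Gaussian draws producing an RR interval below 0.25 s are
#' redrawn so the train respects a physiological refractory period.
#'
#' @param cfg An [ecg_sim_config()].
#' @param duration Record length in seconds (> 3 mean RR intervals).
#' @param start_offset Time of the first beat, seconds (kept away from the
#'   record edge so filter transients cannot clip the first QRS).
#' @param seed Integer seed; defaults to `cfg$seed`.
#' @return Numeric vector of strictly increasing beat times within
#'   `[0, duration]`.
#' @export
simulate_rr_series <- function(cfg, duration, start_offset = 0.5,
                               seed = cfg$seed) {
  stopifnot(inherits(cfg, "ecg_sim_config"))
  rr_mean <- 60 / cfg$mean_hr
  if (duration <= 3 * rr_mean) {
    stop("`duration` must exceed 3 mean RR intervals", call. = FALSE)
  }
  if (cfg$lf_mod[2] + cfg$hf_mod[2] >= rr_mean) {
    stop("modulation depths exceed the mean RR interval", call. = FALSE)
  }
  with_seed(seed, {
    beats <- numeric(0)
    t <- start_offset
    while (t <= duration) {
      beats <- c(beats, t)
      rr_det <- rr_mean +
        cfg$lf_mod[2] * sin(2 * pi * cfg$lf_mod[1] * t) +
        cfg$hf_mod[2] * sin(2 * pi * cfg$hf_mod[1] * t)
      rr <- rr_det + if (cfg$rr_sd > 0) stats::rnorm(1, 0, cfg$rr_sd) else 0
      tries <- 0L
      while (rr <= 0.25 && tries < 100L) {
        rr <- rr_det + stats::rnorm(1, 0, cfg$rr_sd)
        tries <- tries + 1L
      }
      if (rr <= 0.25) stop("cannot draw RR > 0.25 s; config too extreme",
                           call. = FALSE)
      t <- t + rr
    }
    beats
  })
}

# Smooth baseline wander: first-order-filtered white noise generated on a
# coarse grid and spline-interpolated to the sampling grid, scaled to the
# requested RMS.
gen_wander <- function(n, fs, amp, corner, burn_in = 50L) {
  if (amp <= 0 || n < 2L) return(numeric(n))
  rate <- max(8 * corner, 4)
  m <- ceiling(n / fs * rate) + 2L
  w <- stats::rnorm(m + burn_in)
  a <- exp(-2 * pi * corner / rate)
  y <- stats::filter(w, a, method = "recursive")
  y <- as.numeric(y)[(burn_in + 1L):(burn_in + m)]
  tt_coarse <- (seq_len(m) - 1) / rate
  tt <- (seq_len(n) - 1) / fs
  out <- stats::spline(tt_coarse, y, xout = tt)$y
  s <- stats::sd(out)
  if (s == 0) return(numeric(n))
  out / s * amp
}

#' Render a synthetic ECG trace from beat times
#'
#' Places one sum of P, Q, R, S, T Gaussian bumps per beat, then adds
#' white noise and baseline wander as configured. The ground-truth R time
#' of each beat is the configured R apex (the beat time itself).
#'
#' @param beat_times Strictly increasing beat times, seconds.
#' @param cfg An [ecg_sim_config()].
#' @param fs Sampling rate, Hz.
#' @param duration Record length, seconds.
#' @param label Channel label.
#' @param seed Integer seed for noise/wander; defaults to `cfg$seed`.
#' @return A list with `ts` (the [time_series()]) and `rpeaks` (numeric
#'   vector of ground-truth R times inside the record).
#' @export
synth_ecg <- function(beat_times, cfg, fs = 10000, duration = NULL,
                      label = "ECG", seed = cfg$seed) {
  stopifnot(inherits(cfg, "ecg_sim_config"))
  if (is.null(duration)) duration <- max(beat_times) + 0.5
  n <- round(duration * fs)
  x <- numeric(n)
  amps <- c(p = cfg$p_amp, q = -cfg$q_frac * cfg$r_amp, r = cfg$r_amp,
            s = -cfg$s_frac * cfg$r_amp, t = cfg$t_amp)
  for (w in names(amps)) {
    a <- amps[[w]]
    if (a == 0) next
    sdw <- cfg$widths[[w]]
    off <- cfg$offsets[[w]]
    half <- 5 * sdw
    for (bt in beat_times) {
      ctr <- bt + off
      i0 <- max(1L, floor((ctr - half) * fs) + 1L)
      i1 <- min(n, ceiling((ctr + half) * fs) + 1L)
      if (i1 < i0) next
      tt <- (seq(i0, i1) - 1) / fs
      x[i0:i1] <- x[i0:i1] + a * exp(-(tt - ctr)^2 / (2 * sdw^2))
    }
  }
  x <- with_seed(seed, {
    if (cfg$noise_sd > 0) x <- x + stats::rnorm(n, 0, cfg$noise_sd)
    if (cfg$wander_amp > 0) {
      x <- x + gen_wander(n, fs, cfg$wander_amp, cfg$wander_corner)
    }
    x
  })
  rpeaks <- beat_times[beat_times >= 0 & beat_times <= duration]
  list(ts = time_series(x, fs = fs, t0 = 0, label = label), rpeaks = rpeaks)
}

#' Derive a capacitively distorted copy of an ECG channel
#'
#' Emulates the distortion of a capacitive channel relative to its source:
#' an optional first-order low-pass (applied causally, modelling the
#' high-frequency attenuation introduced by stray capacitance) plus extra
#' noise and baseline wander. Ground-truth R times are unchanged.
#'
#' @param ts Source [time_series()].
#' @param hf_attenuation Low-pass corner frequency in Hz, or `NULL` for
#'   none. A first-order response attenuates a tone at frequency `f` by
#'   `1/sqrt(1 + (f/corner)^2)`.
#' @param noise_sd SD of extra white noise, volts.
#' @param wander_amp,wander_corner Extra baseline-wander RMS (volts) and
#'   corner (Hz).
#' @param label Output channel label.
#' @param seed Integer seed for the stochastic components.
#' @return A `time_series`.
#' @export
synth_cecg <- function(ts, hf_attenuation = NULL, noise_sd = 0,
                       wander_amp = 0, wander_corner = 0.5,
                       label = "cECG", seed = NULL) {
  stopifnot(inherits(ts, "time_series"))
  x <- ts$samples
  if (!is.null(hf_attenuation)) {
    bl <- signal::butter(1, hf_attenuation / (ts$fs / 2), type = "low")
    x <- as.numeric(signal::filter(bl, x))
  }
  x <- with_seed(seed, {
    if (noise_sd > 0) x <- x + stats::rnorm(length(x), 0, noise_sd)
    if (wander_amp > 0) {
      x <- x + gen_wander(length(x), ts$fs, wander_amp, wander_corner)
    }
    x
  })
  time_series(x, fs = ts$fs, t0 = ts$t0, label = label)
}

# One band-limited Gaussian burst of length n samples, scaled to unit RMS.
band_limited_burst <- function(n, fs, band) {
  pad <- round(0.1 * fs)
  w <- stats::rnorm(n + 2 * pad)
  bf <- signal::butter(2, band / (fs / 2), type = "pass")
  y <- signal::filtfilt(bf, w)[(pad + 1):(pad + n)]
  y / sqrt(mean(y^2))
}

#' Generate a full synthetic two-cough session
#'
#' Builds the four-channel session used to exercise the whole pipeline:
#' a pre-cough rest period, `n_cycles` two-cough cycles, and a final rest
#' period. Each cycle carries two band-limited EMG bursts (present in both
#' the reference and capacitive EMG channels), one annotation time stamp at
#' the cycle midpoint, and a decaying baseline transient in the capacitive
#' ECG after the cycle. ECG channels run through the whole record.
#'
#' @param ecg_cfg An [ecg_sim_config()].
#' @param cough_cfg A [cough_sim_config()].
#' @param fs Sampling rate in Hz (default 10 kHz, matching a 16-bit
#'   +/-10 V acquisition chain).
#' @param rest_pre Duration of the initial rest period, seconds (the
#'   protocol's 2-min rest).
#' @param rest_post Duration of the final rest period, seconds.
#' @param seed Integer seed for the whole session; every random draw in
#'   the session flows from this one generator, so equal seeds give
#'   bit-identical sessions.
#' @return An object of class `sim_session`: a list with `channels` (named
#'   list `ECG_ref`, `cECG`, `EMG_ref`, `cEMG` of [time_series()]),
#'   `truth_rpeaks` (numeric), `truth_cough_windows` (data.frame with
#'   `start`, `end`), `annotations` ([event_annotations()]), `fs`,
#'   `duration`, `rest_pre`, `rest_post` and the two configs.
#' @export
synth_cough_session <- function(ecg_cfg = ecg_sim_config(),
                                cough_cfg = cough_sim_config(),
                                fs = 10000, rest_pre = 120, rest_post = 30,
                                seed = cough_cfg$seed) {
  stopifnot(inherits(ecg_cfg, "ecg_sim_config"),
            inherits(cough_cfg, "cough_sim_config"))
  cc <- cough_cfg
  cycle_len <- 2 * cc$burst_duration + cc$intra_pair_gap
  starts <- rest_pre +
    (seq_len(cc$n_cycles) - 1) * (cycle_len + cc$inter_cycle_gap)
  ends <- starts + cycle_len
  duration <- ends[cc$n_cycles] + rest_post
  n <- round(duration * fs)

  with_seed(seed, {
    # --- EMG channels -----------------------------------------------------
    emg_ref <- stats::rnorm(n, 0, cc$rest_rms)
    cemg <- stats::rnorm(n, 0, cc$rest_rms)
    nb <- round(cc$burst_duration * fs)
    burst_starts <- as.vector(rbind(starts,
                                    starts + cc$burst_duration +
                                      cc$intra_pair_gap))
    for (bs in burst_starts) {
      i0 <- round(bs * fs) + 1L
      idx <- i0:(i0 + nb - 1L)
      burst <- band_limited_burst(nb, fs, cc$burst_band) * cc$burst_rms
      emg_ref[idx] <- emg_ref[idx] + burst
      cemg[idx] <- cemg[idx] + cc$cemg_scale * burst
    }

    # --- ECG channels -----------------------------------------------------
    beats <- simulate_rr_series(ecg_cfg, duration, seed = NULL)
    ecg <- synth_ecg(beats, ecg_cfg, fs = fs, duration = duration,
                     label = "ECG_ref", seed = NULL)
    cecg <- synth_cecg(ecg$ts, hf_attenuation = ecg_cfg$hf_attenuation,
                       noise_sd = ecg_cfg$noise_sd,
                       wander_amp = ecg_cfg$wander_amp,
                       wander_corner = ecg_cfg$wander_corner,
                       label = "cECG", seed = NULL)
    if (cc$post_cough_wander > 0) {
      x <- cecg$samples
      for (k in seq_len(cc$n_cycles)) {
        i0 <- round(ends[k] * fs) + 1L
        len <- min(round(4 * fs), n - i0 + 1L)
        if (len <= 0) next
        tt <- (seq_len(len) - 1) / fs
        ph <- stats::runif(1, 0, 2 * pi)
        x[i0:(i0 + len - 1L)] <- x[i0:(i0 + len - 1L)] +
          cc$post_cough_wander * exp(-tt / 1.5) * sin(2 * pi * 0.8 * tt + ph)
      }
      cecg$samples <- x
    }

    ann <- event_annotations((starts + ends) / 2, "two_cough")
    structure(
      list(channels = list(
             ECG_ref = ecg$ts,
             cECG = cecg,
             EMG_ref = time_series(emg_ref, fs = fs, label = "EMG_ref"),
             cEMG = time_series(cemg, fs = fs, label = "cEMG")),
           truth_rpeaks = ecg$rpeaks,
           truth_cough_windows = data.frame(start = starts, end = ends),
           annotations = ann,
           fs = fs, duration = duration,
           rest_pre = rest_pre, rest_post = rest_post,
           ecg_cfg = ecg_cfg, cough_cfg = cough_cfg, seed = seed),
      class = "sim_session")
  })
}

#' @export
print.sim_session <- function(x, ...) {
  cat(sprintf(paste0("<sim_session> %.1f s @ %g Hz, %d two-cough cycles,",
                     " %d truth R-peaks\n"),
              x$duration, x$fs, nrow(x$truth_cough_windows),
              length(x$truth_rpeaks)))
  invisible(x)
}

#' Write a simulated session to disk
#'
#' Writes the four signal channels as one delimited signal table, the
#' annotations as a delimited annotation file, and the ground truth
#' (R-peak times and cough windows) as JSON.
#'
#' @param session A `sim_session` from [synth_cough_session()].
#' @param dir Output directory (created if missing).
#' @return Invisibly, the named vector of written paths.
#' @export
write_session <- function(session, dir) {
  stopifnot(inherits(session, "sim_session"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(signals = file.path(dir, "signals.csv"),
             annotations = file.path(dir, "annotations.csv"),
             truth = file.path(dir, "truth.json"))
  write_signal_table(session$channels, paths[["signals"]])
  write_annotations(session$annotations, paths[["annotations"]])
  jsonlite::write_json(
    list(rpeaks = session$truth_rpeaks,
         cough_windows = session$truth_cough_windows,
         fs = session$fs, rest_pre = session$rest_pre),
    paths[["truth"]], auto_unbox = TRUE, digits = NA)
  invisible(paths)
}
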