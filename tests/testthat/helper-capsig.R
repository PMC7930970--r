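# Shared fixtures, built in code.

# Clean 2-min capacitive ECG at the acquisition rate: no noise, no
# distortion, so detection must be perfect.
make_clean_ecg <- function(seed = 11, fs = 10000, duration = 120,
                           mean_hr = 70, rr_sd = 0.02) {
  cfg <- ecg_sim_config(mean_hr = mean_hr, rr_sd = rr_sd, seed = seed)
  beats <- simulate_rr_series(cfg, duration)
  synth_ecg(beats, cfg, fs = fs, duration = duration, label = "cECG")
}

# Distorted-channel profile: R-wave smaller than T-wave, strong
# high-frequency attenuation, noise and wander of the order of the R
# amplitude — the regime in which a fixed-threshold detector breaks down.
make_distorted_ecg <- function(seed = 12, fs = 10000, duration = 120) {
  cfg <- ecg_sim_config(mean_hr = 70, rr_sd = 0.02,
                        r_amp = 30e-6, t_amp = 60e-6, seed = seed)
  beats <- simulate_rr_series(cfg, duration)
  clean <- synth_ecg(beats, cfg, fs = fs, duration = duration)
  dist <- synth_cecg(clean$ts, hf_attenuation = 15, noise_sd = 50e-6,
                     wander_amp = 50e-6, seed = seed + 1000L)
  list(ts = dist, rpeaks = clean$rpeaks)
}

# Small cough session (reduced sampling rate keeps the EMG band intact
# while the suite stays fast).
make_cough_session <- function(seed = 42, fs = 2000, ...) {
  synth_cough_session(ecg_sim_config(seed = seed),
                      cough_sim_config(...),
                      fs = fs, seed = seed)
}

# A time_series consisting of Gaussian bumps at given times/amplitudes on
# a quiet baseline; used to exercise threshold estimation arithmetic.
bump_series <- function(times, amps, fs = 1000, duration = NULL,
                        width = 0.01) {
  if (is.null(duration)) duration <- max(times) + 0.5
  tt <- seq(0, duration - 1 / fs, by = 1 / fs)
  x <- numeric(length(tt))
  for (k in seq_along(times)) {
    x <- x + amps[k] * exp(-(tt - times[k])^2 / (2 * width^2))
  }
  time_series(x, fs = fs)
}
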