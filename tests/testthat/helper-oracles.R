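# Independent oracles and fixture builders shared across the suite.

# Brute-force O(n^2) one-sided power spectrum: direct DFT sum, independent
# of stats::fft and of the package's frame_power().
brute_dft_power <- function(frame, fft_len) {
  x <- c(frame, rep(0, fft_len - length(frame)))
  n_bins <- fft_len %/% 2 + 1
  p <- numeric(n_bins)
  n <- seq_along(x) - 1
  for (k in seq_len(n_bins) - 1) {
    xk <- sum(x * exp(-2i * pi * k * n / fft_len))
    p[k + 1] <- (Mod(xk) / fft_len)^2
  }
  p
}

# Independent skewness/kurtosis via e1071 (type 1 = biased moment
# estimators; e1071 reports excess kurtosis, hence the +3).
oracle_moments <- function(x) {
  c(skewness = e1071::skewness(x, type = 1),
    kurtosis = e1071::kurtosis(x, type = 1) + 3)
}

# Cohort configuration with contamination switched off: every minute
# should pass the quality screen.
quiet_cohort_config <- function(n_patients_per_class = 2,
                                minutes_per_patient = 1, seed = 1L,
                                noise_sd = 0.005, baseline_wander_amp = 0,
                                powerline_amp = 0, spike_rate = 0, ...) {
  cohort_config(n_patients_per_class = n_patients_per_class,
                minutes_per_patient = minutes_per_patient,
                noise_sd = noise_sd,
                baseline_wander_amp = baseline_wander_amp,
                powerline_amp = powerline_amp, spike_rate = spike_rate,
                seed = seed, ...)
}

# A clean, filtered, un-normalized synthetic ECG minute for screening tests.
clean_minute <- function(seed = 1L) {
  rec <- generate_record(quiet_cohort_config(seed = seed), 1, "healthy")
  segment_minutes(preprocess_record(rec))[[1]]
}

# Inject a 3-sample spike transient (generator's artifact shape) into
# second `sec` (1-based) of a minute segment.
inject_spike_second <- function(seg, sec, amp = 5) {
  k <- round((sec - 1) * seg$fs + seg$fs / 2)
  seg$samples[(k - 1):(k + 1)] <- seg$samples[(k - 1):(k + 1)] +
    amp * c(0.5, 1, 0.5)
  seg
}

# Minimal window stand-in for split/balance tests (samples irrelevant).
fake_windows <- function(counts, labels) {
  out <- list()
  for (i in seq_along(counts)) {
    for (j in seq_len(counts[i])) {
      out[[length(out) + 1]] <- structure(
        list(samples = numeric(4), fs = 250,
             patient_id = names(counts)[i], label = labels[i],
             window_index = j - 1L, segment_index = 0L, offset_s = 0),
        class = "ecg_window")
    }
  }
  out
}

# RMS of the middle half of a signal (clear of filtfilt edge transients).
mid_rms <- function(x) {
  n <- length(x)
  sqrt(mean(x[floor(n / 4):ceiling(3 * n / 4)]^2))
}

sine_record <- function(freq, fs = 250, dur = 10, amp = 1) {
  t <- (seq_len(dur * fs) - 1) / fs
  ecg_record(amp * sin(2 * pi * freq * t), fs, "probe")
}
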