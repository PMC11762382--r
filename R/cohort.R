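#' Synthetic cohort configuration
#'
#' Study conditions for the synthetic single-lead ECG cohort: per-patient
#' record length, heart-rate statistics, class-conditional beat morphologies
#' and contamination levels (baseline wander, 50 Hz powerline pickup,
#' electrode-motion spike transients, broadband noise). Defaults describe a
#' wearable chest-strap acquisition at 250 Hz under everyday activity, with
#' artifact levels chosen so that a quality screen sees both clean and noisy
#' minutes.
#'
#' @param n_patients_per_class Patients per class (healthy / diabetic).
#' @param minutes_per_patient Record length per patient, minutes.
#' @param fs Sampling rate, Hz (> 80 so a 40 Hz analysis band is supported).
#' @param hr_mean,hr_sd Per-beat heart rate distribution, bpm.
#' @param rr_jitter Multiplicative uniform jitter applied to each RR
#'   interval (fraction, e.g. 0.02 for +/-2%).
#' @param noise_sd Broadband (white) noise standard deviation, mV.
#' @param baseline_wander_amp,baseline_wander_freq Respiratory baseline
#'   wander sinusoid amplitude (mV) and frequency (Hz).
#' @param powerline_amp 50 Hz mains pickup amplitude, mV.
#' @param powerline_freq Mains frequency, Hz.
#' @param spike_rate Electrode-motion spike transients per minute (Poisson).
#' @param spike_amp Spike peak amplitude, mV (sign randomised per spike).
#'   5 mV corresponds to an electrode pop near the edge of a typical
#'   analog front-end dynamic range.
#' @param class_morphologies Named list with `healthy` and `diabetic`
#'   [beat_morphology()] entries.
#' @param seed Integer seed; identical configurations (including seed)
#'   regenerate bit-identical cohorts.
#' @return An object of class `cohort_config`.
#' @export
cohort_config <- function(n_patients_per_class = 8,
                          minutes_per_patient = 10,
                          fs = 250,
                          hr_mean = 75, hr_sd = 3,
                          rr_jitter = 0.02,
                          noise_sd = 0.02,
                          baseline_wander_amp = 0.10,
                          baseline_wander_freq = 0.25,
                          powerline_amp = 0.02,
                          powerline_freq = 50,
                          spike_rate = 2,
                          spike_amp = 5,
                          class_morphologies = list(
                            healthy = healthy_morphology(),
                            diabetic = diabetic_morphology()),
                          seed = 1L) {
  stopifnot_scalar(fs, "fs", positive = TRUE)
  if (fs <= 80) stop("fs must exceed 80 Hz", call. = FALSE)
  stopifnot_scalar(hr_mean, "hr_mean", positive = TRUE)
  if (hr_mean < 30 || hr_mean > 220) {
    stop("hr_mean must lie in [30, 220] bpm", call. = FALSE)
  }
  if (n_patients_per_class < 1) {
    stop("n_patients_per_class must be >= 1", call. = FALSE)
  }
  amps <- c(noise_sd, baseline_wander_amp, powerline_amp, spike_amp,
            hr_sd, rr_jitter, spike_rate)
  if (any(amps < 0)) stop("amplitudes and rates must be >= 0", call. = FALSE)
  if (!all(c("healthy", "diabetic") %in% names(class_morphologies))) {
    stop("class_morphologies needs 'healthy' and 'diabetic' entries",
         call. = FALSE)
  }
  structure(list(n_patients_per_class = as.integer(n_patients_per_class),
                 minutes_per_patient = minutes_per_patient,
                 fs = fs, hr_mean = hr_mean, hr_sd = hr_sd,
                 rr_jitter = rr_jitter, noise_sd = noise_sd,
                 baseline_wander_amp = baseline_wander_amp,
                 baseline_wander_freq = baseline_wander_freq,
                 powerline_amp = powerline_amp,
                 powerline_freq = powerline_freq,
                 spike_rate = spike_rate, spike_amp = spike_amp,
                 class_morphologies = class_morphologies,
                 seed = as.integer(seed)),
            class = "cohort_config")
}

#' Construct a single-lead ECG record
#'
#' @param samples Numeric vector, millivolts; must be finite and non-empty.
#' @param fs Sampling rate, Hz.
#' @param patient_id Opaque patient identifier.
#' @param label One of `"healthy"`, `"diabetic"`, `"unknown"`.
#' @param provenance Free-text provenance (synthesis parameters or source
#'   file).
#' @return An object of class `ecg_record`.
#' @export
ecg_record <- function(samples, fs, patient_id, label = "unknown",
                       provenance = "") {
  if (length(samples) < 1L) stop("record must be non-empty", call. = FALSE)
  if (!all(is.finite(samples))) {
    stop("record contains non-finite samples", call. = FALSE)
  }
  stopifnot_scalar(fs, "fs", positive = TRUE)
  label <- match.arg(label, c("healthy", "diabetic", "unknown"))
  structure(list(samples = as.numeric(samples), fs = fs,
                 patient_id = as.character(patient_id), label = label,
                 provenance = provenance),
            class = "ecg_record")
}

#' @export
print.ecg_record <- function(x, ...) {
  cat(sprintf("<ecg_record> patient %s (%s): %d samples @ %g Hz (%.1f s)\n",
              x$patient_id, x$label, length(x$samples), x$fs,
              length(x$samples) / x$fs))
  invisible(x)
}

#' Generate one synthetic patient record
#'
#' Concatenates rendered beats whose RR intervals are drawn from the
#' configured heart-rate distribution (clamped to the morphology's feasible
#' range), then adds baseline wander, mains pickup, Poisson spike transients
#' and white noise. Deterministic given `(cfg$seed, patient_index, label)`.
#'
#' @param cfg A [cohort_config()].
#' @param patient_index Integer index of the patient within its class.
#' @param label `"healthy"` or `"diabetic"`.
#' @return An [ecg_record()].
#' @export
generate_record <- function(cfg, patient_index, label) {
  stopifnot(inherits(cfg, "cohort_config"))
  label <- match.arg(label, c("healthy", "diabetic"))
  m <- cfg$class_morphologies[[label]]
  fs <- cfg$fs
  n_target <- round_half_up(cfg$minutes_per_patient * 60 * fs)
  rr_floor <- max(min_rr(m), 60 / 220)

  seed <- mix_seed(cfg$seed, patient_index,
                   if (label == "healthy") 1L else 2L)
  samples <- with_seed(seed, {
    beats <- vector("list", ceiling(n_target / (fs * 60 / 220)) + 1L)
    i <- 0L
    total <- 0L
    while (total < n_target) {
      hr <- min(max(stats::rnorm(1, cfg$hr_mean, cfg$hr_sd), 30), 220)
      rr <- (60 / hr) * (1 + cfg$rr_jitter * stats::runif(1, -1, 1))
      rr <- max(rr, rr_floor)
      b <- make_beat_template(m, fs, rr)
      i <- i + 1L
      beats[[i]] <- b
      total <- total + length(b)
    }
    x <- unlist(beats[seq_len(i)])[seq_len(n_target)]
    t <- (seq_len(n_target) - 1) / fs
    if (cfg$baseline_wander_amp > 0) {
      x <- x + cfg$baseline_wander_amp *
        sin(2 * pi * cfg$baseline_wander_freq * t + stats::runif(1, 0, 2 * pi))
    }
    if (cfg$powerline_amp > 0) {
      x <- x + cfg$powerline_amp *
        sin(2 * pi * cfg$powerline_freq * t + stats::runif(1, 0, 2 * pi))
    }
    if (cfg$noise_sd > 0) x <- x + stats::rnorm(n_target, 0, cfg$noise_sd)
    if (cfg$spike_rate > 0 && cfg$spike_amp > 0) {
      n_spikes <- stats::rpois(1, cfg$minutes_per_patient * cfg$spike_rate)
      if (n_spikes > 0) {
        pos <- sample.int(n_target - 2L, n_spikes, replace = TRUE) + 1L
        sgn <- sample(c(-1, 1), n_spikes, replace = TRUE)
        for (j in seq_len(n_spikes)) {
          k <- pos[j]
          x[(k - 1L):(k + 1L)] <- x[(k - 1L):(k + 1L)] +
            sgn[j] * cfg$spike_amp * c(0.5, 1, 0.5)
        }
      }
    }
    x
  })

  prefix <- if (label == "healthy") "H" else "D"
  ecg_record(samples, fs,
             patient_id = sprintf("%s%02d", prefix, patient_index),
             label = label,
             provenance = sprintf(
               "synthetic: seed=%d patient_index=%d label=%s fs=%g",
               cfg$seed, patient_index, label, fs))
}

#' Generate a full synthetic cohort
#'
#' @param cfg A [cohort_config()].
#' @return A list of class `ecg_cohort` with elements `records` (list of
#'   [ecg_record()]) and `manifest` (one row per record: patient_id, label,
#'   fs, minutes, n_samples).
#' @export
generate_cohort <- function(cfg) {
  stopifnot(inherits(cfg, "cohort_config"))
  records <- list()
  for (label in c("healthy", "diabetic")) {
    for (i in seq_len(cfg$n_patients_per_class)) {
      records[[length(records) + 1L]] <- generate_record(cfg, i, label)
    }
  }
  manifest <- data.frame(
    patient_id = vapply(records, `[[`, "", "patient_id"),
    label = vapply(records, `[[`, "", "label"),
    fs = vapply(records, `[[`, 0, "fs"),
    minutes = vapply(records, function(r) length(r$samples) / r$fs / 60, 0),
    n_samples = vapply(records, function(r) length(r$samples), 0L),
    stringsAsFactors = FALSE)
  structure(list(records = records, manifest = manifest, config = cfg),
            class = "ecg_cohort")
}

#' @export
print.ecg_cohort <- function(x, ...) {
  cat(sprintf("<ecg_cohort> %d records (%s)\n", nrow(x$manifest),
              paste(sprintf("%s: %d", names(table(x$manifest$label)),
                            as.integer(table(x$manifest$label))),
                    collapse = ", ")))
  cat(sprintf("  %g min/patient @ %g Hz, seed %d\n",
              x$config$minutes_per_patient, x$config$fs, x$config$seed))
  invisible(x)
}
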