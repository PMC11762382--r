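test_that("beat templates honour length arithmetic and the zero case", {
  m0 <- beat_morphology(wave_amplitudes = c(P = 0, Q = 0, R = 0, S = 0, T = 0))
  expect_equal(make_beat_template(m0, fs = 250, rr = 1), rep(0, 250))
  expect_length(make_beat_template(healthy_morphology(), 250, 1.0), 250)
  expect_length(make_beat_template(healthy_morphology(), 360, 0.8), 288)
})

test_that("morphology invariants are enforced", {
  expect_error(beat_morphology(wave_widths = c(P = 0.02, Q = 0, R = 0.01,
                                               S = 0.01, T = 0.05)),
               "widths")
  expect_error(beat_morphology(wave_centers = c(P = -0.1, Q = -0.2, R = 0,
                                                S = 0.04, T = 0.3)),
               "ordered")
  expect_error(beat_morphology(wave_amplitudes = c(P = 0.2, Q = -0.1,
                                                   R = 0.15, S = -0.1,
                                                   T = 0.3)),
               "R amplitude")
  ## a cycle too short for the T wave names the offending wave
  expect_error(make_beat_template(healthy_morphology(), 250, 0.4), "T")
})

test_that("diabetic T waves are measurably more asymmetric than healthy", {
  fs <- 1000
  measure_t_ratio <- function(m) {
    y <- make_beat_template(m, fs, 1.2)
    ## T peak: maximum after the S wave region
    from <- round(0.5 * fs)
    i_peak <- which.max(y[from:length(y)]) + from - 1
    half <- y[i_peak] / 2
    left <- i_peak - max(which(y[1:(i_peak - 1)] <= half))
    right <- min(which(y[(i_peak + 1):length(y)] <= half))
    right / left
  }
  r_healthy <- measure_t_ratio(healthy_morphology())
  r_diabetic <- measure_t_ratio(diabetic_morphology())
  expect_gt(r_diabetic, r_healthy)
  expect_gt(r_diabetic, 1.3)          # clearly asymmetric
  expect_lt(abs(r_healthy - 1), 0.25) # roughly symmetric
})

test_that("generated records have the configured length and rate", {
  cfg <- quiet_cohort_config(minutes_per_patient = 1)
  rec <- generate_record(cfg, 1, "healthy")
  expect_length(rec$samples, 15000)   # 60 s * 250 Hz
  expect_equal(rec$fs, 250)
  expect_true(all(is.finite(rec$samples)))
})

test_that("forced periodicity gives 1 s R-peak spacing", {
  cfg <- quiet_cohort_config(hr_mean = 60, hr_sd = 0, rr_jitter = 0,
                             noise_sd = 0)
  rec <- generate_record(cfg, 1, "healthy")
  x <- rec$samples
  thr <- 0.6 * max(x)
  above <- which(x > thr)
  peaks <- above[c(TRUE, diff(above) > 50)]   # group runs, keep onsets
  spacing <- diff(peaks)
  expect_true(all(abs(spacing - 250) <= 1))
})

test_that("record generation is deterministic in (seed, patient, label)", {
  cfg <- cohort_config(n_patients_per_class = 1, minutes_per_patient = 1)
  a <- generate_record(cfg, 1, "healthy")
  b <- generate_record(cfg, 1, "healthy")
  expect_identical(a$samples, b$samples)
  expect_false(identical(a$samples, generate_record(cfg, 2, "healthy")$samples))
  expect_false(identical(a$samples, generate_record(cfg, 1, "diabetic")$samples))
})

test_that("cohorts have the right shape and reproduce byte-for-byte", {
  cfg <- quiet_cohort_config(n_patients_per_class = 2)
  coh <- generate_cohort(cfg)
  expect_length(coh$records, 4)
  expect_equal(nrow(coh$manifest), 4)
  expect_equal(anyDuplicated(coh$manifest$patient_id), 0L)
  expect_equal(as.vector(table(coh$manifest$label)), c(2, 2))
  coh2 <- generate_cohort(cfg)
  expect_identical(lapply(coh$records, `[[`, "samples"),
                   lapply(coh2$records, `[[`, "samples"))
})

test_that("uncontaminated cohorts pass the quality screen in full", {
  coh <- generate_cohort(quiet_cohort_config(n_patients_per_class = 2))
  segments <- unlist(lapply(coh$records, function(r) {
    segment_minutes(preprocess_record(r))
  }), recursive = FALSE)
  screened <- screen_cohort(segments)
  expect_length(screened$rejected, 0)
  expect_true(all(screened$summary$accept_rate == 1))
})

test_that("the power spectrum shows a 50 Hz line iff powerline pickup is on", {
  peak_ratio <- function(amp) {
    cfg <- quiet_cohort_config(powerline_amp = amp)
    rec <- generate_record(cfg, 1, "healthy")
    p <- Mod(stats::fft(rec$samples))^2
    freqs <- (seq_along(p) - 1) * rec$fs / length(p)
    at50 <- p[which.min(abs(freqs - 50))]
    nearby <- p[freqs > 45 & freqs < 55 & abs(freqs - 50) > 0.5]
    at50 / stats::median(nearby)
  }
  expect_gt(peak_ratio(0.05), 100)
  expect_lt(peak_ratio(0), 100)
})
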