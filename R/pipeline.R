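#' Pipeline configuration
#'
#' Nested per-stage configurations plus a single run seed. The run seed
#' fans out to per-stage seeds through a deterministic integer hash, so
#' each stage remains independently reproducible.
#'
#' @param cohort A [cohort_config()] (its own seed is overridden by the
#'   run seed).
#' @param filter A [filter_spec()].
#' @param quality A [quality_config()].
#' @param spectrogram A [spectrogram_config()].
#' @param model A [cnn_config()] (input geometry is adjusted to the
#'   featurizer output).
#' @param window_s,overlap_s Analysis-window geometry, seconds.
#' @param target_fraction Training share of windows.
#' @param epochs,learning_rate,batch_size,patience Training protocol.
#' @param screen Apply the quality screen (disable to keep every minute).
#' @param quantize Run the int8 quantization stage.
#' @param calibration_windows Calibration sample size for quantization.
#' @param seed Run seed.
#' @param verbose Progress messages.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(cohort = cohort_config(),
                            filter = filter_spec(),
                            quality = quality_config(),
                            spectrogram = spectrogram_config(),
                            model = cnn_config(),
                            window_s = 5, overlap_s = 1,
                            target_fraction = 0.8,
                            epochs = 500, learning_rate = 5e-4,
                            batch_size = 128, patience = 50,
                            screen = TRUE, quantize = TRUE,
                            calibration_windows = 200,
                            seed = 1L, verbose = FALSE) {
  structure(list(cohort = cohort, filter = filter, quality = quality,
                 spectrogram = spectrogram, model = model,
                 window_s = window_s, overlap_s = overlap_s,
                 target_fraction = target_fraction,
                 epochs = epochs, learning_rate = learning_rate,
                 batch_size = batch_size, patience = patience,
                 screen = isTRUE(screen), quantize = isTRUE(quantize),
                 calibration_windows = calibration_windows,
                 seed = as.integer(seed), verbose = isTRUE(verbose)),
            class = "pipeline_config")
}

#' Run the full screening pipeline
#'
#' Generate (or take) a cohort, denoise, segment into minutes, screen
#' signal quality, normalize, window, build the patient-independent
#' balanced split, featurize, train the CNN, evaluate on held-out-patient
#' test windows, quantize with accuracy-delta reporting, estimate memory
#' footprints and rank the bundled MCU profiles.
#'
#' @param cfg A [pipeline_config()].
#' @param cohort Optionally, a pre-built `ecg_cohort` (e.g. from
#'   [read_cohort()]); if omitted one is generated from `cfg$cohort` with
#'   the run seed.
#' @return An object of class `ecg_run_report`.
#' @export
run_ecg_pipeline <- function(cfg = pipeline_config(), cohort = NULL) {
  stopifnot(inherits(cfg, "pipeline_config"))
  say <- function(...) if (cfg$verbose) message(sprintf(...))

  if (is.null(cohort)) {
    ccfg <- cfg$cohort
    ccfg$seed <- mix_seed(cfg$seed, "cohort")
    say("generating cohort (%d + %d patients)...", ccfg$n_patients_per_class,
        ccfg$n_patients_per_class)
    cohort <- generate_cohort(ccfg)
  }

  say("denoising and segmenting...")
  segments <- list()
  for (rec in cohort$records) {
    segs <- segment_minutes(preprocess_record(rec, cfg$filter))
    segments <- c(segments, segs)
  }

  if (cfg$screen) {
    say("quality screening %d minutes...", length(segments))
    screened <- screen_cohort(segments, cfg$quality)
    clean <- screened$clean
    screen_summary <- screened$summary
  } else {
    clean <- segments
    screen_summary <- NULL
  }
  if (length(clean) == 0) stop("pipeline: no clean minutes survived screening",
                               call. = FALSE)
  clean <- lapply(clean, normalize_segment)

  windows <- window_minutes(clean, cfg$window_s, cfg$overlap_s)
  manifest <- split_by_patient(windows, cfg$target_fraction,
                               seed = mix_seed(cfg$seed, "split"))
  assert_patient_disjoint(manifest)
  windows <- balance_classes(windows, manifest,
                             seed = mix_seed(cfg$seed, "balance"))
  splits <- window_split(windows, manifest)

  say("featurizing %d windows...", length(windows))
  feats <- featurize_windows(windows, cfg$spectrogram)
  mcfg <- cfg$model
  mcfg$input_frames <- feats$n_frames
  mcfg$input_bins <- feats$n_bins

  take <- function(s) {
    idx <- which(splits == s)
    list(x = feats$x[idx, , drop = FALSE],
         y = feats$info$label[idx],
         patients = feats$info$patient_id[idx])
  }
  tr <- take("train"); va <- take("validation"); te <- take("test")
  say("training on %d windows (val %d, test %d)...",
      nrow(tr$x), nrow(va$x), nrow(te$x))
  fit <- ecg_cnn(tr$x, tr$y, va$x, va$y, config = mcfg,
                 epochs = cfg$epochs, learning_rate = cfg$learning_rate,
                 batch_size = cfg$batch_size, patience = cfg$patience,
                 seed = mix_seed(cfg$seed, "train"),
                 train_patients = tr$patients, val_patients = va$patients,
                 verbose = cfg$verbose)
  eval_float <- evaluate_model(fit, te$x, te$y)

  eval_int8 <- NULL; qmodel <- NULL
  fp_float <- estimate_footprint(fit)
  fp_int8 <- NULL
  if (cfg$quantize) {
    n_cal <- min(cfg$calibration_windows, nrow(tr$x))
    cal_idx <- with_seed(mix_seed(cfg$seed, "calib"),
                         sample.int(nrow(tr$x), n_cal))
    qmodel <- quantize_int8(fit, tr$x[cal_idx, , drop = FALSE])
    eval_int8 <- evaluate_model(qmodel, te$x, te$y)
    fp_int8 <- estimate_footprint(qmodel)
  }

  counts <- as.data.frame(table(split = splits,
                                label = feats$info$label))
  report <- structure(list(
    config = cfg,
    cohort_manifest = cohort$manifest,
    screen_summary = screen_summary,
    n_windows = counts,
    split_manifest = manifest,
    model = fit,
    eval_float = eval_float,
    eval_int8 = eval_int8,
    accuracy_drop = if (!is.null(eval_int8))
      eval_float$accuracy - eval_int8$accuracy else NA_real_,
    footprint_float = fp_float,
    footprint_int8 = fp_int8,
    quantized_model = qmodel,
    fom = rank_mcus(mcu_profiles()),
    seed = cfg$seed), class = "ecg_run_report")
  report
}

#' @export
print.ecg_run_report <- function(x, ...) {
  cat("=== ECG screening pipeline run (seed", x$seed, ") ===\n")
  cat(sprintf("cohort: %d records\n", nrow(x$cohort_manifest)))
  if (!is.null(x$screen_summary)) {
    cat(sprintf("screening: %d/%d minutes clean\n",
                sum(x$screen_summary$n_clean),
                sum(x$screen_summary$n_segments)))
  }
  tf <- attr(x$split_manifest, "train_fraction")
  cat(sprintf("windows: %d (train share %.3f)\n",
              sum(x$n_windows$Freq), tf))
  cat("\nfloat32 model:\n"); print(x$eval_float)
  print(x$footprint_float)
  if (!is.null(x$eval_int8)) {
    cat("\nint8 model:\n"); print(x$eval_int8)
    print(x$footprint_int8)
    cat(sprintf("accuracy drop after quantization: %.4f\n",
                x$accuracy_drop))
  }
  cat("\nMCU ranking:\n")
  print(x$fom)
  invisible(x)
}
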