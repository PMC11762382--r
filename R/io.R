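#' Write a cohort to per-record CSV files plus a manifest
#'
#' Each record becomes `<patient_id>.csv` with columns `time_s,ecg_mv`;
#' `manifest.csv` lists `patient_id,label,fs,minutes,file`.
#'
#' @param cohort An [generate_cohort()] result (or a bare list of
#'   [ecg_record()]s).
#' @param dir Output directory (created if missing).
#' @return The manifest data frame, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  records <- if (inherits(cohort, "ecg_cohort")) cohort$records else cohort
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rows <- lapply(records, function(r) {
    file <- paste0(r$patient_id, ".csv")
    df <- data.frame(time_s = (seq_along(r$samples) - 1) / r$fs,
                     ecg_mv = r$samples)
    utils::write.csv(df, file.path(dir, file), row.names = FALSE)
    data.frame(patient_id = r$patient_id, label = r$label, fs = r$fs,
               minutes = length(r$samples) / r$fs / 60, file = file,
               stringsAsFactors = FALSE)
  })
  manifest <- do.call(rbind, rows)
  utils::write.csv(manifest, file.path(dir, "manifest.csv"),
                   row.names = FALSE)
  invisible(manifest)
}

#' Read a single ECG record from CSV
#'
#' Accepts the dialect written by [write_cohort()] (`time_s,ecg_mv`); the
#' sampling rate is taken from `fs` if given, otherwise inferred from the
#' median time step.
#'
#' @param file CSV path.
#' @param fs Sampling rate in Hz, or `NULL` to infer.
#' @param patient_id,label Provenance attributes for the record.
#' @return An [ecg_record()].
#' @export
read_ecg_csv <- function(file, fs = NULL, patient_id = basename(file),
                         label = "unknown") {
  df <- utils::read.csv(file)
  if (!"ecg_mv" %in% names(df)) {
    stop("expected an 'ecg_mv' column", call. = FALSE)
  }
  if (is.null(fs)) {
    if (!"time_s" %in% names(df)) {
      stop("need either fs or a time_s column", call. = FALSE)
    }
    fs <- 1 / stats::median(diff(df$time_s))
  }
  ecg_record(df$ecg_mv, fs, patient_id, label,
             provenance = paste("file:", file))
}

#' Read a cohort directory written by [write_cohort()]
#' @param dir Directory containing `manifest.csv` and per-record CSVs.
#' @return An `ecg_cohort`-like list with `records` and `manifest`.
#' @export
read_cohort <- function(dir) {
  manifest <- utils::read.csv(file.path(dir, "manifest.csv"),
                              stringsAsFactors = FALSE)
  records <- lapply(seq_len(nrow(manifest)), function(i) {
    read_ecg_csv(file.path(dir, manifest$file[i]), fs = manifest$fs[i],
                 patient_id = manifest$patient_id[i],
                 label = manifest$label[i])
  })
  structure(list(records = records, manifest = manifest),
            class = "ecg_cohort")
}

#' Read a WFDB-style header plus plain-text sample file
#'
#' A minimal text-format adapter for WFDB-layout records: `<record>.hea`
#' holds `name n_sig fs n_samples` on its first line and
#' `file format gain baseline` on the first signal line (gain in ADC units
#' per mV); samples are read from the named file as one integer per line
#' and converted to millivolts as `(adc - baseline) / gain`. Binary WFDB
#' formats are not supported.
#'
#' @param record Path to the record without the `.hea` extension.
#' @param label Class label to attach.
#' @return An [ecg_record()].
#' @export
read_wfdb_record <- function(record, label = "unknown") {
  hea <- paste0(record, ".hea")
  lines <- readLines(hea)
  lines <- lines[!grepl("^#", lines)]
  head_fields <- strsplit(trimws(lines[1]), "\\s+")[[1]]
  if (length(head_fields) < 3) {
    stop("malformed header line in ", hea, call. = FALSE)
  }
  fs <- as.numeric(head_fields[3])
  sig_fields <- strsplit(trimws(lines[2]), "\\s+")[[1]]
  sample_file <- file.path(dirname(record), sig_fields[1])
  gain <- as.numeric(sub("\\(.*", "", sig_fields[3]))
  if (is.na(gain) || gain == 0) gain <- 200   # WFDB default adu/mV
  baseline <- if (length(sig_fields) >= 4) {
    suppressWarnings(as.numeric(sig_fields[4]))
  } else NA
  if (is.na(baseline)) baseline <- 0
  adc <- scan(sample_file, what = numeric(), quiet = TRUE)
  ecg_record((adc - baseline) / gain, fs,
             patient_id = basename(record), label = label,
             provenance = paste("wfdb:", record))
}
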