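#' Cut clean minutes into fixed-length analysis windows
#'
#' Windows tile each minute independently (a window never spans two
#' minutes, because minutes are screened independently). With the default
#' 5 s windows and 1 s overlap the stride is 4 s, giving
#' `floor((60 - 5) / 4) + 1 = 14` windows per minute.
#'
#' @param segments List of `minute_segment` objects.
#' @param window_s Window length, seconds.
#' @param overlap_s Overlap between consecutive windows, seconds
#'   (`window_s > overlap_s >= 0`).
#' @return List of `ecg_window` objects carrying provenance
#'   (patient, source minute, offset) and a per-patient running
#'   `window_index`.
#' @export
window_minutes <- function(segments, window_s = 5, overlap_s = 1) {
  if (!(window_s > overlap_s && overlap_s >= 0)) {
    stop("need window_s > overlap_s >= 0", call. = FALSE)
  }
  counters <- new.env(parent = emptyenv())
  out <- list()
  for (seg in segments) {
    w_len <- round_half_up(window_s * seg$fs)
    stride <- round_half_up((window_s - overlap_s) * seg$fs)
    n <- length(seg$samples)
    if (n < w_len) next
    starts <- seq(1L, n - w_len + 1L, by = stride)
    for (s in starts) {
      idx <- get0(seg$patient_id, envir = counters, ifnotfound = 0L)
      assign(seg$patient_id, idx + 1L, envir = counters)
      out[[length(out) + 1L]] <- structure(
        list(samples = seg$samples[s:(s + w_len - 1L)],
             fs = seg$fs,
             patient_id = seg$patient_id,
             label = seg$label,
             window_index = idx,
             segment_index = seg$segment_index,
             offset_s = (s - 1L) / seg$fs),
        class = "ecg_window")
    }
  }
  out
}

window_table <- function(windows) {
  data.frame(patient_id = vapply(windows, `[[`, "", "patient_id"),
             label = vapply(windows, `[[`, "", "label"),
             window_index = vapply(windows, `[[`, 0L, "window_index"),
             stringsAsFactors = FALSE)
}

#' Patient-independent train/validation/test assignment
#'
#' Patients (never windows) are assigned to splits so that the training
#' share of windows approaches `target_fraction`. Within each class,
#' patients are taken largest-first into the training pool while doing so
#' moves the class's training share closer to the target (at least one and
#' at most all-but-one patients per class). Remaining patients are
#' alternated test-first (largest to test) between test and validation;
#' a final repair swap restores class representation in test/validation
#' when possible. The procedure is deterministic: ties are broken by
#' patient id.
#'
#' @param windows List of `ecg_window` objects.
#' @param target_fraction Desired training share of windows.
#' @param seed Integer recorded in the manifest (the assignment itself is
#'   deterministic; the seed keys downstream balancing).
#' @return A `split_manifest` data.frame with columns `patient_id`,
#'   `label`, `split`, `n_windows`; attributes `target_fraction`,
#'   `train_fraction` (achieved) and `seed`.
#' @export
split_by_patient <- function(windows, target_fraction = 0.8, seed = 1L) {
  tab <- window_table(windows)
  counts <- stats::aggregate(list(n_windows = tab$window_index),
                             by = list(patient_id = tab$patient_id,
                                       label = tab$label),
                             FUN = length)
  for (cl in unique(counts$label)) {
    if (sum(counts$label == cl) < 2) {
      stop(sprintf(
        "class '%s' has fewer than 2 patients; cannot build a patient-disjoint split",
        cl), call. = FALSE)
    }
  }
  counts <- counts[order(-counts$n_windows, counts$patient_id), ]
  split <- setNames(rep("", nrow(counts)), counts$patient_id)

  for (cl in unique(counts$label)) {
    sub <- counts[counts$label == cl, ]
    total <- sum(sub$n_windows)
    taken <- 0
    n_taken <- 0L
    for (i in seq_len(nrow(sub) - 1L)) {        # keep >= 1 patient out
      after <- taken + sub$n_windows[i]
      if (n_taken == 0L ||
          abs(after / total - target_fraction) <
            abs(taken / total - target_fraction)) {
        split[sub$patient_id[i]] <- "train"
        taken <- after
        n_taken <- n_taken + 1L
      } else {
        break
      }
    }
  }

  residual <- counts[split[counts$patient_id] == "", ]
  dest <- rep(c("test", "validation"), length.out = nrow(residual))
  split[residual$patient_id] <- dest

  ## repair: make sure test and validation each see both classes. First try
  ## swapping between test and validation; if the residual pool is too
  ## lopsided (e.g. a single residual patient of one class), trade the
  ## smallest-count training patient of the missing class instead — class
  ## representation takes priority over hitting the share exactly.
  classes <- unique(counts$label)
  if (length(classes) == 2 && nrow(residual) >= 2) {
    get_ids <- function(s, cl = classes) {
      counts$patient_id[split[counts$patient_id] == s &
                          counts$label %in% cl]
    }
    for (s in c("test", "validation")) {
      for (cl in setdiff(classes, counts$label[split[counts$patient_id] == s])) {
        other <- setdiff(c("test", "validation"), s)
        donors <- get_ids(other, cl)
        takers <- get_ids(s, setdiff(classes, cl))
        if (length(donors) >= 2 && length(takers) >= 1) {
          split[donors[1]] <- s
          split[takers[1]] <- other
        } else if (length(takers) >= 1) {
          train_cl <- get_ids("train", cl)         # sorted largest-first
          if (length(train_cl) >= 2) {
            split[train_cl[length(train_cl)]] <- s
            split[takers[1]] <- "train"
          } else {
            warning(sprintf("split '%s' lacks class '%s' and no swap is possible",
                            s, cl), call. = FALSE)
          }
        }
      }
    }
  }

  manifest <- data.frame(patient_id = counts$patient_id,
                         label = counts$label,
                         split = unname(split[counts$patient_id]),
                         n_windows = counts$n_windows,
                         stringsAsFactors = FALSE)
  manifest <- manifest[order(manifest$patient_id), ]
  rownames(manifest) <- NULL
  structure(manifest,
            class = c("split_manifest", "data.frame"),
            target_fraction = target_fraction,
            train_fraction = sum(manifest$n_windows[manifest$split == "train"]) /
              sum(manifest$n_windows),
            seed = as.integer(seed))
}

#' Check that a split manifest is patient-disjoint
#'
#' @param manifest A [split_by_patient()] manifest.
#' @return `TRUE` invisibly; errors if any patient appears in more than one
#'   split or any split is empty of patients.
#' @export
assert_patient_disjoint <- function(manifest) {
  if (anyDuplicated(manifest$patient_id) > 0) {
    stop("manifest assigns a patient to more than one split", call. = FALSE)
  }
  if (!all(manifest$split %in% c("train", "validation", "test"))) {
    stop("unknown split labels in manifest", call. = FALSE)
  }
  invisible(TRUE)
}

#' Look up the split of each window
#' @param windows List of `ecg_window` objects.
#' @param manifest A [split_by_patient()] manifest.
#' @return Character vector of split names, one per window.
#' @export
window_split <- function(windows, manifest) {
  map <- setNames(manifest$split, manifest$patient_id)
  unname(map[vapply(windows, `[[`, "", "patient_id")])
}

#' Shuffle class labels at the patient level
#'
#' Label-leakage probe: permutes the class labels across patients (every
#' window of a patient receives that patient's permuted label), preserving
#' the overall class counts. A classifier trained on a shuffled cohort
#' should score at chance on held-out patients; materially better
#' performance indicates leakage of patient identity into the features or
#' the split.
#'
#' @param windows List of `ecg_window` objects.
#' @param seed Integer seed for the permutation.
#' @return The window list with permuted labels.
#' @export
shuffle_labels_by_patient <- function(windows, seed = 1L) {
  pid <- vapply(windows, `[[`, "", "patient_id")
  patients <- sort(unique(pid))
  labels <- vapply(patients, function(p) windows[[match(p, pid)]]$label, "")
  perm <- with_seed(mix_seed(seed, "shuffle"), sample(labels))
  names(perm) <- patients
  lapply(windows, function(w) {
    w$label <- perm[[w$patient_id]]
    w
  })
}

#' Balance class counts in the training pool
#'
#' Randomly subsamples majority-class training windows, spreading removals
#' across that class's patients in proportion to their window counts
#' (largest-remainder apportionment; uniform sampling within each patient),
#' until the training class counts differ by at most one. Validation and
#' test windows are untouched. Deterministic under `seed`.
#'
#' @param windows List of `ecg_window` objects.
#' @param manifest A [split_by_patient()] manifest.
#' @param seed Integer seed.
#' @return The window list with excess majority-class training windows
#'   removed.
#' @export
balance_classes <- function(windows, manifest, seed = 1L) {
  splits <- window_split(windows, manifest)
  labels <- vapply(windows, `[[`, "", "label")
  in_train <- splits == "train"
  tab <- table(labels[in_train])
  if (length(tab) < 2 || abs(tab[1] - tab[2]) <= 1) return(windows)
  maj <- names(tab)[which.max(tab)]
  n_target <- min(tab)

  maj_idx <- which(in_train & labels == maj)
  pid <- vapply(windows[maj_idx], `[[`, "", "patient_id")
  per_pat <- table(pid)
  keep_frac <- n_target / length(maj_idx)
  keep_exact <- as.numeric(per_pat) * keep_frac
  keep_n <- floor(keep_exact)
  rem <- keep_exact - keep_n
  short <- n_target - sum(keep_n)
  if (short > 0) {
    order_rem <- order(-rem, names(per_pat))
    keep_n[order_rem[seq_len(short)]] <- keep_n[order_rem[seq_len(short)]] + 1L
  }
  names(keep_n) <- names(per_pat)

  drop <- integer(0)
  for (p in names(per_pat)) {
    idx_p <- maj_idx[pid == p]
    kept <- with_seed(mix_seed(seed, "balance", p),
                      sample(idx_p, keep_n[[p]]))
    drop <- c(drop, setdiff(idx_p, kept))
  }
  if (length(drop)) windows[-drop] else windows
}
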