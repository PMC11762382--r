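#' Signal-quality screening configuration
#'
#' Threshold-based screening of one-minute ECG segments: skewness and
#' (non-excess, Pearson) kurtosis are computed on non-overlapping
#' one-second subsegments, a subsegment violates if either statistic falls
#' outside its acceptance range, and the minute is kept as clean when the
#' number of violating subsegments does not exceed `max_violations`.
#'
#' The signed skewness lower bound of 0 implicitly assumes upright R waves;
#' an inverted lead is rejected wholesale. Set `abs_skew = TRUE` to screen
#' on `|skewness|` instead.
#'
#' @param skew_range Closed acceptance interval for skewness.
#' @param kurt_range Closed acceptance interval for kurtosis (non-excess:
#'   a Gaussian scores 3).
#' @param subsegment_s Subsegment length in seconds (non-overlapping).
#' @param max_violations Largest number of violating subsegments a clean
#'   minute may contain.
#' @param abs_skew Screen on absolute skewness instead of signed skewness.
#' @return An object of class `quality_config`.
#' @export
quality_config <- function(skew_range = c(0, 5), kurt_range = c(3, 30),
                           subsegment_s = 1, max_violations = 3,
                           abs_skew = FALSE) {
  if (skew_range[1] >= skew_range[2] || kurt_range[1] >= kurt_range[2]) {
    stop("acceptance intervals must have lower < upper", call. = FALSE)
  }
  stopifnot_scalar(subsegment_s, "subsegment_s", positive = TRUE)
  if (max_violations < 0) stop("max_violations must be >= 0", call. = FALSE)
  structure(list(skew_range = skew_range, kurt_range = kurt_range,
                 subsegment_s = subsegment_s,
                 max_violations = as.integer(max_violations),
                 abs_skew = isTRUE(abs_skew)),
            class = "quality_config")
}

#' Skewness and kurtosis of a sample
#'
#' Biased (population) central moments: skewness `m3 / m2^1.5` and Pearson
#' non-excess kurtosis `m4 / m2^2` (a Gaussian scores 3). At the 250-sample
#' subsegments the screen operates on, estimator bias is negligible.
#'
#' @param x Numeric vector, length >= 4, non-zero variance.
#' @return Named vector `c(skewness, kurtosis)`.
#' @export
moment_stats <- function(x) {
  if (length(x) < 4) stop("need at least 4 samples", call. = FALSE)
  m <- mean(x)
  d <- x - m
  m2 <- mean(d^2)
  if (m2 == 0) stop("zero-variance input", call. = FALSE)
  c(skewness = mean(d^3) / m2^1.5, kurtosis = mean(d^4) / m2^2)
}

#' Screen a one-minute segment for signal quality
#'
#' @param seg A `minute_segment` (see [segment_minutes()]), un-normalized or
#'   normalized; the statistics are location/scale-invariant.
#' @param cfg A [quality_config()].
#' @return An object of class `quality_report` with `per_subsegment`
#'   (data.frame of skewness, kurtosis, violated), `n_violations` and
#'   `clean`. Zero-variance subsegments count as violations (with `NA`
#'   statistics) rather than raising an error: screening must survive
#'   flat-lined wearable data.
#' @export
screen_segment <- function(seg, cfg = quality_config()) {
  sub_len <- round_half_up(cfg$subsegment_s * seg$fs)
  n <- length(seg$samples)
  if (n %% sub_len != 0) {
    stop("segment length must divide into whole subsegments", call. = FALSE)
  }
  n_sub <- n %/% sub_len
  skew <- kurt <- rep(NA_real_, n_sub)
  violated <- logical(n_sub)
  for (i in seq_len(n_sub)) {
    x <- seg$samples[((i - 1) * sub_len + 1):(i * sub_len)]
    if (length(x) < 4 || stats::var(x) == 0) {
      violated[i] <- TRUE
      next
    }
    st <- moment_stats(x)
    skew[i] <- st[["skewness"]]
    kurt[i] <- st[["kurtosis"]]
    s <- if (cfg$abs_skew) abs(skew[i]) else skew[i]
    violated[i] <- s < cfg$skew_range[1] || s > cfg$skew_range[2] ||
      kurt[i] < cfg$kurt_range[1] || kurt[i] > cfg$kurt_range[2]
  }
  n_violations <- sum(violated)
  structure(list(per_subsegment = data.frame(skewness = skew, kurtosis = kurt,
                                             violated = violated),
                 n_violations = n_violations,
                 clean = n_violations <= cfg$max_violations,
                 max_violations = cfg$max_violations,
                 patient_id = seg$patient_id,
                 segment_index = seg$segment_index),
            class = "quality_report")
}

#' @export
print.quality_report <- function(x, ...) {
  cat(sprintf("<quality_report> %s minute %d: %d/%d subsegments violate -> %s\n",
              x$patient_id, x$segment_index, x$n_violations,
              nrow(x$per_subsegment), if (x$clean) "clean" else "noisy"))
  invisible(x)
}

#' Screen a list of minute segments
#'
#' @param segments List of `minute_segment` objects.
#' @param cfg A [quality_config()].
#' @return List with `clean` and `rejected` segment lists (order and
#'   provenance preserved), `reports` (one [screen_segment()] report per
#'   input) and `summary` (per-patient segment counts and accept rates).
#' @export
screen_cohort <- function(segments, cfg = quality_config()) {
  reports <- lapply(segments, screen_segment, cfg = cfg)
  keep <- vapply(reports, `[[`, TRUE, "clean")
  ids <- vapply(segments, `[[`, "", "patient_id")
  summary <- do.call(rbind, lapply(unique(ids), function(p) {
    sel <- ids == p
    data.frame(patient_id = p, n_segments = sum(sel),
               n_clean = sum(keep[sel]),
               accept_rate = mean(keep[sel]),
               stringsAsFactors = FALSE)
  }))
  if (is.null(summary)) {
    summary <- data.frame(patient_id = character(), n_segments = integer(),
                          n_clean = integer(), accept_rate = numeric())
  }
  list(clean = segments[keep], rejected = segments[!keep],
       reports = reports, summary = summary)
}
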