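#' Spectrogram configuration
#'
#' Short-time spectrogram geometry for 5 s analysis windows: 0.7 s frames,
#' a stride of 10% of the frame (0.07 s), a 256-point FFT and a -50 dB
#' noise floor. Frame and stride lengths are converted to samples with
#' round-half-up; at 250 Hz this gives a 175-sample frame and an 18-sample
#' stride, i.e. 60 frames per 5 s window and 60 x 129 = 7740 features.
#' (Floor-rounding the 17.5-sample stride would give 64 frames and break
#' that geometry.)
#'
#' @param frame_s Frame length, seconds.
#' @param stride_fraction Stride as a fraction of the frame length.
#' @param fft_len FFT length (power of two, >= frame samples; frames are
#'   zero-padded).
#' @param noise_floor_db Clip level in dB; spectra are affinely mapped so
#'   that `noise_floor_db` becomes 0 and 0 dB becomes 1, then clipped to
#'   \[0, 1\].
#' @param taper `"rect"` (none, default) or `"hann"` applied before the
#'   FFT.
#' @return An object of class `spectrogram_config`.
#' @export
spectrogram_config <- function(frame_s = 0.7, stride_fraction = 0.10,
                               fft_len = 256, noise_floor_db = -50,
                               taper = c("rect", "hann")) {
  if (!(stride_fraction > 0 && stride_fraction <= 1)) {
    stop("stride_fraction must lie in (0, 1]", call. = FALSE)
  }
  if (fft_len < 2 || bitwAnd(fft_len, fft_len - 1L) != 0) {
    stop("fft_len must be a power of two", call. = FALSE)
  }
  if (noise_floor_db >= 0) stop("noise_floor_db must be < 0", call. = FALSE)
  structure(list(frame_s = frame_s, stride_fraction = stride_fraction,
                 fft_len = as.integer(fft_len),
                 noise_floor_db = noise_floor_db,
                 taper = match.arg(taper)),
            class = "spectrogram_config")
}

#' Frame geometry for a window length
#' @param n_samples Window length in samples.
#' @param fs Sampling rate, Hz.
#' @param cfg A [spectrogram_config()].
#' @return List with `frame_len`, `stride` (samples, round-half-up) and
#'   `n_frames = floor((n_samples - frame_len) / stride) + 1`.
#' @export
frame_geometry <- function(n_samples, fs, cfg = spectrogram_config()) {
  frame_len <- as.integer(round_half_up(cfg$frame_s * fs))
  stride <- as.integer(round_half_up(cfg$frame_s * cfg$stride_fraction * fs))
  if (frame_len > n_samples) {
    stop("frame is longer than the analysis window", call. = FALSE)
  }
  list(frame_len = frame_len, stride = stride,
       n_frames = as.integer((n_samples - frame_len) %/% stride) + 1L)
}

#' Slice a window into overlapping frames
#'
#' @param window An `ecg_window` or numeric vector.
#' @param cfg A [spectrogram_config()].
#' @param fs Sampling rate (taken from the window if omitted).
#' @return Matrix of `n_frames` rows by `frame_len` columns; any trailing
#'   partial frame is dropped.
#' @export
frame_signal <- function(window, cfg = spectrogram_config(), fs = NULL) {
  if (inherits(window, "ecg_window")) {
    fs <- window$fs
    x <- window$samples
  } else {
    x <- as.numeric(window)
    if (is.null(fs)) stop("fs is required for a bare numeric window",
                          call. = FALSE)
  }
  g <- frame_geometry(length(x), fs, cfg)
  starts <- (seq_len(g$n_frames) - 1L) * g$stride
  out <- matrix(0, g$n_frames, g$frame_len)
  for (i in seq_len(g$n_frames)) {
    out[i, ] <- x[(starts[i] + 1L):(starts[i] + g$frame_len)]
  }
  out
}

taper_vector <- function(cfg, frame_len) {
  if (cfg$taper == "hann") {
    0.5 - 0.5 * cos(2 * pi * (seq_len(frame_len) - 1) / (frame_len - 1))
  } else {
    rep(1, frame_len)
  }
}

#' One-sided power spectrum of a frame (pre-dB)
#'
#' Power is `(|X_k| / fft_len)^2` for the zero-padded, optionally tapered
#' frame, at bins `k = 0 .. fft_len/2` (so a unit-amplitude sinusoid lands
#' near -6 dB after [frame_spectrum()]'s dB conversion).
#'
#' @param frame Numeric vector, length <= `fft_len`.
#' @param cfg A [spectrogram_config()].
#' @return Numeric vector of `fft_len / 2 + 1` power values.
#' @export
frame_power <- function(frame, cfg = spectrogram_config()) {
  if (!all(is.finite(frame))) stop("non-finite frame input", call. = FALSE)
  n <- length(frame)
  if (n > cfg$fft_len) {
    stop("frame longer than fft_len; cannot zero-pad", call. = FALSE)
  }
  padded <- c(frame * taper_vector(cfg, n), rep(0, cfg$fft_len - n))
  x <- stats::fft(padded)
  n_bins <- cfg$fft_len %/% 2L + 1L
  (Mod(x[seq_len(n_bins)]) / cfg$fft_len)^2
}

#' Normalized dB spectrum of a frame
#'
#' Converts [frame_power()] to dB (`10 log10(power + 1e-12)`), clips at the
#' noise floor and rescales affinely so the floor maps to 0 and 0 dB maps
#' to 1, clipping to \[0, 1\].
#'
#' @inheritParams frame_power
#' @return Numeric vector of `fft_len / 2 + 1` values in \[0, 1\].
#' @export
frame_spectrum <- function(frame, cfg = spectrogram_config()) {
  p <- frame_power(frame, cfg)
  db <- 10 * log10(p + 1e-12)
  v <- (db - cfg$noise_floor_db) / (-cfg$noise_floor_db)
  pmin(pmax(v, 0), 1)
}

#' Spectrogram feature tensor of one analysis window
#'
#' @param window An `ecg_window` (or numeric vector with `fs` given).
#' @param cfg A [spectrogram_config()].
#' @param fs Sampling rate if `window` is a bare vector.
#' @return A `feature_tensor`: an `n_frames x n_bins` matrix of values in
#'   \[0, 1\] with attributes `frame_times` (frame start times, s) and
#'   `bin_freqs` (Hz). Flatten with [as_feature_vector()] (time-major:
#'   frame 0 bins first).
#' @export
featurize_window <- function(window, cfg = spectrogram_config(), fs = NULL) {
  frames <- frame_signal(window, cfg, fs)
  if (is.null(fs)) fs <- window$fs
  g <- frame_geometry(if (inherits(window, "ecg_window"))
    length(window$samples) else length(window), fs, cfg)
  n_bins <- cfg$fft_len %/% 2L + 1L
  values <- t(apply(frames, 1, frame_spectrum, cfg = cfg))
  structure(values,
            class = c("feature_tensor", "matrix", "array"),
            frame_times = (seq_len(g$n_frames) - 1L) * g$stride / fs,
            bin_freqs = (seq_len(n_bins) - 1L) * fs / cfg$fft_len)
}

#' Flatten a feature tensor time-major
#' @param ft A [featurize_window()] tensor.
#' @return Numeric vector of length `n_frames * n_bins` (frame 0 bins,
#'   frame 1 bins, ...).
#' @export
as_feature_vector <- function(ft) {
  as.vector(t(unclass(ft)))
}

#' Featurize a list of windows into a design matrix
#'
#' Vectorized over frames with a single multi-column FFT per window.
#'
#' @param windows List of `ecg_window` objects (equal length and rate).
#' @param cfg A [spectrogram_config()].
#' @return List with `x` (matrix, one flattened time-major spectrogram per
#'   row), `info` (window provenance data.frame), `n_frames`, `n_bins`.
#' @export
featurize_windows <- function(windows, cfg = spectrogram_config()) {
  if (length(windows) == 0) stop("no windows to featurize", call. = FALSE)
  fs <- windows[[1]]$fs
  n_samp <- length(windows[[1]]$samples)
  g <- frame_geometry(n_samp, fs, cfg)
  n_bins <- cfg$fft_len %/% 2L + 1L
  taper <- taper_vector(cfg, g$frame_len)
  starts <- (seq_len(g$n_frames) - 1L) * g$stride
  idx <- outer(seq_len(g$frame_len), starts, `+`)   # frame_len x n_frames
  x <- matrix(0, length(windows), g$n_frames * n_bins)
  padded <- matrix(0, cfg$fft_len, g$n_frames)
  for (i in seq_along(windows)) {
    w <- windows[[i]]
    padded[seq_len(g$frame_len), ] <- w$samples[idx] * taper
    p <- (Mod(stats::mvfft(padded)[seq_len(n_bins), , drop = FALSE]) /
            cfg$fft_len)^2
    db <- 10 * log10(p + 1e-12)
    v <- pmin(pmax((db - cfg$noise_floor_db) / (-cfg$noise_floor_db), 0), 1)
    x[i, ] <- as.vector(v)                          # bins fastest => time-major
  }
  list(x = x, info = window_table(windows),
       n_frames = g$n_frames, n_bins = n_bins)
}
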