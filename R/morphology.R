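#' Beat morphology description
#'
#' Parametric description of one cardiac cycle as a sum of Gaussian bumps,
#' one per wave (P, Q, R, S, T). The T wave is rendered from two
#' half-Gaussians whose right/left width ratio is `t_asymmetry`, and a flat
#' `st_offset` plateau (with short cosine ramps) is inserted between the end
#' of the S wave and the T-wave onset. This is the simplest construction that
#' exposes the ST-segment deviation and T-wave flattening/asymmetry reported
#' for type 1 diabetic ECG, and is not intended as a physiologically
#' validated simulator.
#'
#' @param wave_amplitudes Named numeric vector (P, Q, R, S, T), millivolts.
#' @param wave_centers Named numeric vector of wave centres in seconds
#'   relative to the R peak; must be strictly ordered P < Q < R < S < T.
#' @param wave_widths Named numeric vector of Gaussian widths (standard
#'   deviations) in seconds; all positive.
#' @param t_asymmetry Ratio of the right to the left T-wave width
#'   (dimensionless, >= 0); 1 gives a symmetric T.
#' @param st_offset Millivolts added on the ST interval.
#' @param qt_scale Multiplier (>= 1) applied to the T-wave latency,
#'   emulating QT prolongation.
#' @return An object of class `beat_morphology`.
#' @examples
#' m <- healthy_morphology()
#' beat <- make_beat_template(m, fs = 250, rr = 1)
#' @export
beat_morphology <- function(wave_amplitudes = c(P = 0.12, Q = -0.10, R = 1.00,
                                                S = -0.18, T = 0.30),
                            wave_centers = c(P = -0.170, Q = -0.035, R = 0,
                                             S = 0.035, T = 0.280),
                            wave_widths = c(P = 0.022, Q = 0.010, R = 0.011,
                                            S = 0.010, T = 0.045),
                            t_asymmetry = 1,
                            st_offset = 0,
                            qt_scale = 1) {
  waves <- c("P", "Q", "R", "S", "T")
  for (v in list(wave_amplitudes, wave_centers, wave_widths)) {
    if (!all(waves %in% names(v))) {
      stop("wave parameter vectors must be named P, Q, R, S, T", call. = FALSE)
    }
  }
  wave_amplitudes <- wave_amplitudes[waves]
  wave_centers <- wave_centers[waves]
  wave_widths <- wave_widths[waves]
  if (any(wave_widths <= 0)) stop("all wave widths must be > 0", call. = FALSE)
  if (any(diff(wave_centers) <= 0)) {
    stop("wave centers must be strictly ordered P < Q < R < S < T",
         call. = FALSE)
  }
  amp_r <- wave_amplitudes[["R"]]
  others <- abs(wave_amplitudes[setdiff(waves, "R")])
  ## an all-zero morphology is allowed (degenerate case); otherwise the R
  ## wave must dominate every other wave in magnitude
  all_zero <- amp_r == 0 && all(others == 0)
  if (!all_zero && amp_r <= max(others)) {
    stop("R amplitude must exceed the magnitude of every other wave",
         call. = FALSE)
  }
  if (t_asymmetry < 0) stop("t_asymmetry must be >= 0", call. = FALSE)
  if (qt_scale < 1) stop("qt_scale must be >= 1", call. = FALSE)
  structure(list(wave_amplitudes = wave_amplitudes,
                 wave_centers = wave_centers,
                 wave_widths = wave_widths,
                 t_asymmetry = t_asymmetry,
                 st_offset = st_offset,
                 qt_scale = qt_scale),
            class = "beat_morphology")
}

#' Default healthy beat morphology
#' @return A `beat_morphology` with a symmetric T wave and no ST deviation.
#' @export
healthy_morphology <- function() beat_morphology()

#' Default diabetic beat morphology
#'
#' Relative to [healthy_morphology()]: ST segment depressed by 0.05 mV, T
#' amplitude reduced to 70%, right/left T width ratio 1.8 and T latency
#' scaled by 1.08. The magnitudes are tunable emulation parameters, not
#' clinically calibrated effect sizes.
#' @return A `beat_morphology`.
#' @export
diabetic_morphology <- function() {
  amps <- c(P = 0.12, Q = -0.10, R = 1.00, S = -0.18, T = 0.30 * 0.7)
  beat_morphology(wave_amplitudes = amps, t_asymmetry = 1.8,
                  st_offset = -0.05, qt_scale = 1.08)
}

## R-peak position (seconds from beat onset) implied by a morphology: leaves
## room for the earliest wave plus a 10 ms guard.
r_peak_position <- function(m) {
  i <- which.min(m$wave_centers)
  -m$wave_centers[[i]] + 3 * m$wave_widths[[i]] + 0.01
}

#' Minimum RR interval a morphology can be rendered in
#'
#' The smallest cycle length (seconds) for which no wave (evaluated at three
#' Gaussian widths) overflows the beat.
#' @param m A `beat_morphology`.
#' @return Seconds.
#' @export
min_rr <- function(m) {
  r_pos <- r_peak_position(m)
  cen <- m$wave_centers
  cen[["T"]] <- cen[["T"]] * m$qt_scale
  wid_r <- m$wave_widths
  wid_r[["T"]] <- wid_r[["T"]] * max(m$t_asymmetry, 1)
  max(r_pos + cen + 3 * wid_r) + 0.01
}

half_gauss <- function(t, centre, w_left, w_right, amp) {
  w <- ifelse(t < centre, w_left, w_right)
  amp * exp(-0.5 * ((t - centre) / w)^2)
}

#' Render one cardiac cycle from a beat morphology
#'
#' @param m A [beat_morphology()].
#' @param fs Sampling rate in Hz.
#' @param rr Cycle length in seconds; must be at least [min_rr()] for `m`.
#' @return Numeric vector of `round(rr * fs)` samples in millivolts.
#' @export
make_beat_template <- function(m, fs, rr) {
  stopifnot(inherits(m, "beat_morphology"))
  stopifnot_scalar(fs, "fs", positive = TRUE)
  stopifnot_scalar(rr, "rr", positive = TRUE)
  n <- round_half_up(rr * fs)
  t <- (seq_len(n) - 1) / fs
  r_pos <- r_peak_position(m)

  cen <- m$wave_centers
  cen[["T"]] <- cen[["T"]] * m$qt_scale
  for (w in c("P", "Q", "R", "S", "T")) {
    w_right <- m$wave_widths[[w]] * if (w == "T") max(m$t_asymmetry, 1) else 1
    edge <- r_pos + cen[[w]] + 3 * w_right
    lo <- r_pos + cen[[w]] - 3 * m$wave_widths[[w]]
    if (edge > rr || lo < 0) {
      stop(sprintf("wave %s overflows the %0.3f s cycle", w, rr),
           call. = FALSE)
    }
  }

  y <- numeric(n)
  for (w in c("P", "Q", "R", "S")) {
    y <- y + half_gauss(t, r_pos + cen[[w]], m$wave_widths[[w]],
                        m$wave_widths[[w]], m$wave_amplitudes[[w]])
  }
  t_centre <- r_pos + cen[["T"]]
  w_left <- m$wave_widths[["T"]]
  y <- y + half_gauss(t, t_centre, w_left, w_left * m$t_asymmetry,
                      m$wave_amplitudes[["T"]])

  if (m$st_offset != 0) {
    s_end <- r_pos + cen[["S"]] + 3 * m$wave_widths[["S"]]
    t_onset <- t_centre - 2 * w_left
    if (t_onset > s_end) {
      ramp <- 0.02
      env <- as.numeric(t >= s_end & t <= t_onset)
      i_l <- which(t >= s_end - ramp & t < s_end)
      env[i_l] <- 0.5 * (1 - cos(pi * (t[i_l] - (s_end - ramp)) / ramp))
      i_r <- which(t > t_onset & t <= t_onset + ramp)
      env[i_r] <- 0.5 * (1 + cos(pi * (t[i_r] - t_onset) / ramp))
      y <- y + m$st_offset * env
    }
  }
  y
}
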