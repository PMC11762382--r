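#' Figure of merit for MCU selection
#'
#' `FOM = 1 / (t_i * f_clk^2)` in (ms * MHz^2)^-1: inference latency trades
#' against dynamic power, which grows with the square of the clock
#' frequency. Higher is better.
#'
#' @param t_i_ms Inference time, milliseconds (> 0).
#' @param f_clk_mhz Clock frequency, MHz (> 0).
#' @return Numeric FOM values (vectorized).
#' @export
fom <- function(t_i_ms, f_clk_mhz) {
  if (any(t_i_ms <= 0) || any(f_clk_mhz <= 0)) {
    stop("inference time and clock frequency must be positive", call. = FALSE)
  }
  1 / (t_i_ms * f_clk_mhz^2)
}

#' Rank MCU profiles by figure of merit
#'
#' @param profiles Data frame with columns `name`, `f_clk_mhz`, `t_i_ms`
#'   (see [mcu_profiles()] for the bundled benchmark set).
#' @return A `fom_table` data frame sorted by decreasing FOM with `fom`
#'   and `rank` columns; ties are broken by name for determinism.
#' @export
rank_mcus <- function(profiles) {
  req <- c("name", "f_clk_mhz", "t_i_ms")
  if (!all(req %in% names(profiles))) {
    stop("profiles need columns name, f_clk_mhz, t_i_ms", call. = FALSE)
  }
  if (nrow(profiles) < 1) stop("need at least one profile", call. = FALSE)
  if (anyDuplicated(profiles$name) > 0) {
    stop("duplicate MCU names", call. = FALSE)
  }
  profiles$fom <- fom(profiles$t_i_ms, profiles$f_clk_mhz)
  profiles <- profiles[order(-profiles$fom, profiles$name), ]
  profiles$rank <- seq_len(nrow(profiles))
  rownames(profiles) <- NULL
  structure(profiles, class = c("fom_table", "data.frame"))
}

#' @export
print.fom_table <- function(x, ...) {
  y <- as.data.frame(x)
  y$fom <- signif(y$fom, 4)
  print(y, row.names = FALSE)
  invisible(x)
}

#' Bundled MCU benchmark profiles
#'
#' Clock frequencies and measured classifier inference times for six 32-bit
#' ARM microcontrollers, as published in the benchmark this package
#' emulates. Profiles are opaque inputs: the latencies are
#' toolchain-reported and are not recomputed here.
#'
#' @return Data frame with columns `name`, `f_clk_mhz`, `t_i_ms`.
#' @export
mcu_profiles <- function() {
  path <- system.file("extdata", "mcu_profiles.csv", package = "ecgedge",
                      mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}
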