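#' @keywords internal
"_PACKAGE"

## Round half up. base::round() uses banker's rounding; sample-domain frame
## geometry (e.g. a 17.5-sample stride at 250 Hz) must round up
## deterministically. The 1e-9 guard absorbs floating-point dust in products
## like 0.7 * 0.1 * 250, which lands a hair below 17.5.
round_half_up <- function(x) floor(x + 0.5 + 1e-9)

## Derive a 31-bit child seed from a parent seed and an arbitrary key chain
## (integers or strings). Linear-congruential mixing; all arithmetic stays
## below 2^53 so it is exact in doubles.
mix_seed <- function(seed, ...) {
  keys <- list(...)
  h <- abs(as.double(seed)) %% 2147483647
  for (k in keys) {
    if (is.character(k)) {
      ints <- utf8ToInt(k)
      k <- sum(ints * seq_along(ints))
    }
    h <- (h * 48271 + as.double(k) + 1) %% 2147483647
  }
  as.integer(h)
}

## Evaluate `code` under a temporary RNG seed, restoring the caller's RNG
## state afterwards so package functions do not clobber user randomness.
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

stopifnot_scalar <- function(x, name, positive = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop(sprintf("'%s' must be a single finite number", name), call. = FALSE)
  }
  if (positive && x <= 0) {
    stop(sprintf("'%s' must be positive", name), call. = FALSE)
  }
  invisible(x)
}
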