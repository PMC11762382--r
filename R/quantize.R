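#' Post-training int8 quantization
#'
#' Symmetric per-tensor weight quantization (scale = max|w| / 127, zero
#' point 0) with activation calibration: min/max ranges of every
#' intermediate activation are recorded over a representative calibration
#' set and inference emulates int8 arithmetic by fake-quantizing (round,
#' clamp, dequantize) both weights and activations. An all-zero tensor gets
#' scale 1 and round-trips to zeros.
#'
#' @param object A fitted [ecg_cnn()].
#' @param calib_x Non-empty calibration feature matrix (typically a sample
#'   of training windows).
#' @return An object of class `ecg_cnn_q` holding integer weight tensors,
#'   per-tensor scales, activation calibration ranges and the source
#'   architecture.
#' @export
quantize_int8 <- function(object, calib_x) {
  stopifnot(inherits(object, "ecg_cnn"))
  if (is.null(calib_x) || nrow(calib_x) == 0) {
    stop("calibration set must be non-empty", call. = FALSE)
  }
  q <- lapply(object$params, function(w) {
    scale <- max(abs(w)) / 127
    if (scale == 0) scale <- 1
    qw <- pmin(pmax(round(w / scale), -127), 127)
    list(q = qw, scale = scale)
  })

  ## calibration: capture activation ranges at the emulation checkpoints
  cache <- cnn_forward(object$params, calib_x, object$config,
                       keep_cache = TRUE)
  rng <- function(a) range(a)
  act_ranges <- list(input = rng(calib_x),
                     pool1 = rng(cache$p1),
                     pool2 = rng(cache$p2),
                     dense1 = rng(cache$ad),
                     logits = rng(cache$logits))

  structure(list(q_params = lapply(q, `[[`, "q"),
                 scales = lapply(q, `[[`, "scale"),
                 act_ranges = act_ranges,
                 config = object$config,
                 classes = object$classes,
                 n_parameters = object$n_parameters),
            class = "ecg_cnn_q")
}

#' Dequantized weight tensors of a quantized model
#' @param qmodel An [quantize_int8()] model.
#' @return List of float tensors (`q * scale`).
#' @export
dequantize_params <- function(qmodel) {
  stopifnot(inherits(qmodel, "ecg_cnn_q"))
  mapply(function(q, s) q * s, qmodel$q_params, qmodel$scales,
         SIMPLIFY = FALSE)
}

#' @export
predict.ecg_cnn_q <- function(object, newx, type = c("prob", "class"), ...) {
  type <- match.arg(type)
  if (inherits(newx, "feature_tensor")) {
    newx <- matrix(as_feature_vector(newx), nrow = 1)
  }
  probs <- cnn_forward(dequantize_params(object), newx, object$config,
                       act_ranges = object$act_ranges)$probs
  colnames(probs) <- object$classes
  if (type == "prob") probs else object$classes[max.col(probs)]
}

#' @export
print.ecg_cnn_q <- function(x, ...) {
  cat(sprintf("Quantized (int8) 1D-CNN: %d parameters, %d weight tensors\n",
              x$n_parameters, length(x$q_params)))
  invisible(x)
}

## Per-layer activation buffer sizes (elements) along the forward pass.
activation_elements <- function(cfg) {
  d <- cnn_dims(cfg)
  c(input = d$t0 * d$c0,
    conv1 = d$t0 * cfg$conv_filters[1],
    pool1 = d$t1 * cfg$conv_filters[1],
    conv2 = d$t1 * cfg$conv_filters[2],
    pool2 = d$t2 * cfg$conv_filters[2],
    dense1 = cfg$dense_units,
    logits = cfg$n_classes)
}

#' Flash and RAM footprint estimate against an MCU budget
#'
#' An analytic byte-count model, not a toolchain measurement: flash is the
#' parameter payload (4 bytes per float32 weight, 1 byte per int8 weight)
#' plus a fixed code/metadata overhead, and RAM is the largest concurrent
#' pair of activation buffers (a layer's input and output must coexist)
#' plus a fixed arena overhead. Toolchain-reported footprints additionally
#' include runtime structures this model deliberately ignores; only
#' ordering and budget-fit are asserted, never kB equality.
#'
#' @param model A fitted [ecg_cnn()] (float32) or [quantize_int8()] model.
#' @param budget Named vector with `flash` and `ram` byte budgets; the
#'   default is the STM32F401 (512 kB flash, 96 kB RAM).
#' @param flash_overhead,ram_overhead Fixed overhead constants, bytes.
#' @return An object of class `footprint_estimate` with `flash_bytes`,
#'   `ram_bytes`, `bytes_per_weight`, `budget`, `fits_flash`, `fits_ram`.
#' @export
estimate_footprint <- function(model,
                               budget = c(flash = 512 * 1024,
                                          ram = 96 * 1024),
                               flash_overhead = 1024,
                               ram_overhead = 2048) {
  bytes <- if (inherits(model, "ecg_cnn_q")) 1L else 4L
  cfg <- model$config
  n_par <- if (!is.null(model$n_parameters)) model$n_parameters else
    unname(cnn_parameter_count(cfg)[["total"]])
  act <- activation_elements(cfg)
  peak <- max(act[-length(act)] + act[-1])
  flash <- n_par * bytes + flash_overhead
  ram <- peak * bytes + ram_overhead
  structure(list(flash_bytes = flash, ram_bytes = ram,
                 bytes_per_weight = bytes, n_parameters = n_par,
                 budget = budget,
                 fits_flash = flash <= budget[["flash"]],
                 fits_ram = ram <= budget[["ram"]]),
            class = "footprint_estimate")
}

#' @export
print.footprint_estimate <- function(x, ...) {
  cat(sprintf("flash %.1f kB / %.0f kB (%s)   ram %.1f kB / %.0f kB (%s)\n",
              x$flash_bytes / 1024, x$budget[["flash"]] / 1024,
              if (x$fits_flash) "fits" else "OVER",
              x$ram_bytes / 1024, x$budget[["ram"]] / 1024,
              if (x$fits_ram) "fits" else "OVER"))
  invisible(x)
}
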