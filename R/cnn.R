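#' Compact 1D-CNN architecture configuration
#'
#' Two 1D convolutional layers (Swish activation, each followed by average
#' pooling), a flatten + dropout stage, one hidden dense layer (Swish) and
#' a 2-way softmax output. Convolution runs along the frame (time) axis of
#' the spectrogram with the frequency bins as input channels; set
#' `time_axis = "bins"` to convolve along frequency instead (ablation).
#'
#' @param conv_filters Filter counts of the two convolutional layers.
#' @param kernel_size Convolution kernel length (odd; same-padding).
#' @param pool_size Average-pooling width (2: halves the time axis).
#' @param dropout_rate Dropout probability after flattening, in \[0, 1).
#' @param dense_units Hidden dense layer width.
#' @param n_classes Output classes (2: healthy vs diabetic).
#' @param input_frames,input_bins Input spectrogram geometry.
#' @param time_axis `"frames"` (default) or `"bins"`.
#' @return An object of class `cnn_config`.
#' @export
cnn_config <- function(conv_filters = c(8, 16), kernel_size = 3,
                       pool_size = 2, dropout_rate = 0.25,
                       dense_units = 20, n_classes = 2,
                       input_frames = 60, input_bins = 129,
                       time_axis = c("frames", "bins")) {
  if (length(conv_filters) != 2) {
    stop("exactly two convolutional layers are supported", call. = FALSE)
  }
  if (kernel_size %% 2 != 1) stop("kernel_size must be odd", call. = FALSE)
  if (!(dropout_rate >= 0 && dropout_rate < 1)) {
    stop("dropout_rate must lie in [0, 1)", call. = FALSE)
  }
  time_axis <- match.arg(time_axis)
  cfg <- structure(list(conv_filters = as.integer(conv_filters),
                        kernel_size = as.integer(kernel_size),
                        pool_size = as.integer(pool_size),
                        dropout_rate = dropout_rate,
                        dense_units = as.integer(dense_units),
                        n_classes = as.integer(n_classes),
                        input_frames = as.integer(input_frames),
                        input_bins = as.integer(input_bins),
                        time_axis = time_axis),
                   class = "cnn_config")
  cfg
}

## Layer geometry: lengths along the convolution axis and channel counts.
cnn_dims <- function(cfg) {
  if (cfg$time_axis == "frames") {
    t0 <- cfg$input_frames; c0 <- cfg$input_bins
  } else {
    t0 <- cfg$input_bins; c0 <- cfg$input_frames
  }
  t1 <- t0 %/% cfg$pool_size
  t2 <- t1 %/% cfg$pool_size
  list(t0 = t0, c0 = c0, t1 = t1, t2 = t2,
       flat = t2 * cfg$conv_filters[2])
}

## He-style initialization of all parameter tensors.
cnn_init <- function(cfg, seed = 1L) {
  d <- cnn_dims(cfg)
  k <- cfg$kernel_size
  f1 <- cfg$conv_filters[1]; f2 <- cfg$conv_filters[2]
  with_seed(mix_seed(seed, "init"), list(
    W1 = array(stats::rnorm(k * d$c0 * f1, 0, sqrt(2 / (k * d$c0))),
               dim = c(k, d$c0, f1)),
    b1 = numeric(f1),
    W2 = array(stats::rnorm(k * f1 * f2, 0, sqrt(2 / (k * f1))),
               dim = c(k, f1, f2)),
    b2 = numeric(f2),
    W3 = matrix(stats::rnorm(d$flat * cfg$dense_units, 0,
                             sqrt(2 / d$flat)),
                d$flat, cfg$dense_units),
    b3 = numeric(cfg$dense_units),
    W4 = matrix(stats::rnorm(cfg$dense_units * cfg$n_classes, 0,
                             sqrt(2 / cfg$dense_units)),
                cfg$dense_units, cfg$n_classes),
    b4 = numeric(cfg$n_classes)))
}

#' Number of trainable parameters of an architecture
#' @param cfg A [cnn_config()].
#' @return Named vector of per-tensor parameter counts plus a `total`.
#' @export
cnn_parameter_count <- function(cfg) {
  d <- cnn_dims(cfg)
  k <- cfg$kernel_size
  counts <- c(conv1 = k * d$c0 * cfg$conv_filters[1] + cfg$conv_filters[1],
              conv2 = k * cfg$conv_filters[1] * cfg$conv_filters[2] +
                cfg$conv_filters[2],
              dense1 = d$flat * cfg$dense_units + cfg$dense_units,
              dense2 = cfg$dense_units * cfg$n_classes + cfg$n_classes)
  c(counts, total = sum(counts))
}

#' Swish activation
#'
#' `swish(x) = x * sigmoid(x)`; smooth, non-monotone near zero, and free of
#' the dying-ReLU failure mode.
#' @param x Numeric.
#' @return `x * sigmoid(x)`.
#' @export
swish <- function(x) x * stats::plogis(x)

swish_grad <- function(x) {
  s <- stats::plogis(x)
  s * (1 + x * (1 - s))
}

softmax_rows <- function(z) {
  z <- z - apply(z, 1, max)
  e <- exp(z)
  e / rowSums(e)
}

## ---- internal tensor plumbing -------------------------------------------
## A batch lives in two layouts:
##   flat:  N x (T*C) matrix, time-major (frame 0 channels first)
##   rows:  (N*T) x C matrix, row (n-1)*T + t = channels of frame t
flat_to_rows <- function(x, n_ch) {
  matrix(as.vector(t(x)), ncol = n_ch, byrow = TRUE)
}
rows_to_flat <- function(m, n_obs) {
  matrix(as.vector(t(m)), nrow = n_obs, byrow = TRUE)
}

## Shift the per-window time axis of a rows-layout matrix by d steps,
## zero-filling across window boundaries.
shift_rows <- function(m, d, t_len) {
  if (d == 0) return(m)
  nr <- nrow(m)
  out <- matrix(0, nr, ncol(m))
  if (d > 0) {
    out[seq_len(nr - d), ] <- m[(d + 1):nr, ]
  } else {
    out[(-d + 1):nr, ] <- m[seq_len(nr + d), ]
  }
  t_idx <- ((seq_len(nr) - 1L) %% t_len) + 1L
  bad <- t_idx + d < 1L | t_idx + d > t_len
  if (any(bad)) out[bad, ] <- 0
  out
}

## Same-padded 1D convolution (cross-correlation) in rows layout. With
## keep_shifts the shifted input copies are returned for reuse by the
## backward pass (they dominate the R-level cost of a training step).
conv_rows <- function(m, w, b, t_len, keep_shifts = FALSE) {
  k <- dim(w)[1]
  half <- (k - 1L) %/% 2L
  shifts <- lapply(seq_len(k), function(j) shift_rows(m, j - 1L - half, t_len))
  out <- matrix(rep(b, each = nrow(m)), nrow(m), length(b))
  for (j in seq_len(k)) {
    out <- out + shifts[[j]] %*% w[j, , ]
  }
  if (keep_shifts) list(out = out, shifts = shifts) else out
}

## Backward pass helpers for conv_rows.
conv_rows_grad_w <- function(shifts, d_out) {
  k <- length(shifts)
  g <- array(0, dim = c(k, ncol(shifts[[1]]), ncol(d_out)))
  for (j in seq_len(k)) {
    g[j, , ] <- crossprod(shifts[[j]], d_out)
  }
  g
}
conv_rows_grad_in <- function(d_out, w, t_len) {
  k <- dim(w)[1]
  half <- (k - 1L) %/% 2L
  g <- matrix(0, nrow(d_out), dim(w)[2])
  for (j in seq_len(k)) {
    g <- g + shift_rows(d_out %*% t(w[j, , ]), -(j - 1L - half), t_len)
  }
  g
}

## Average-pool pairs of time steps (drops a trailing odd step).
pool_rows <- function(m, t_len, pool) {
  t_out <- t_len %/% pool
  nr <- nrow(m)
  keep <- ((seq_len(nr) - 1L) %% t_len) < t_out * pool
  mk <- m[keep, , drop = FALSE]
  idx <- seq(1L, nrow(mk), by = pool)
  out <- mk[idx, , drop = FALSE]
  for (j in seq_len(pool - 1L)) out <- out + mk[idx + j, , drop = FALSE]
  out / pool
}
unpool_rows <- function(d_out, t_len, pool) {
  t_out <- t_len %/% pool
  n_obs <- nrow(d_out) %/% t_out
  full <- matrix(0, n_obs * t_len, ncol(d_out))
  src <- rep(seq_len(nrow(d_out)), each = pool)
  dest <- as.vector(vapply(seq_len(n_obs) - 1L,
                           function(n) n * t_len + seq_len(t_out * pool),
                           integer(t_out * pool)))
  full[dest, ] <- d_out[src, , drop = FALSE] / pool
  full
}

## Fake int8 quantization of an activation tensor given a calibration
## range; identity when rng is NULL.
fake_quant <- function(a, rng) {
  if (is.null(rng)) return(a)
  lo <- rng[1]; hi <- rng[2]
  if (hi <= lo) hi <- lo + 1e-6
  scale <- (hi - lo) / 255
  q <- round((pmin(pmax(a, lo), hi) - lo) / scale)
  q * scale + lo
}

## Full forward pass. `x` is N x (T*C) flat (time-major). Returns
## probabilities plus (optionally) every intermediate needed for backprop.
## `dropout_mask` (N x flat) enables training-mode dropout; `act_ranges`
## enables emulated-int8 activation quantization.
cnn_forward <- function(params, x, cfg, dropout_mask = NULL,
                        act_ranges = NULL, keep_cache = FALSE) {
  d <- cnn_dims(cfg)
  n <- nrow(x)
  if (ncol(x) != d$t0 * d$c0) {
    stop(sprintf("input has %d features; the architecture expects %d",
                 ncol(x), d$t0 * d$c0), call. = FALSE)
  }
  if (cfg$time_axis == "bins") {
    ## transpose each window from (frames x bins, bins-fastest) to
    ## (bins x frames, frames-fastest)
    x <- t(apply(x, 1, function(v) {
      as.vector(t(matrix(v, cfg$input_bins, cfg$input_frames)))
    }))
  }
  x <- fake_quant(x, act_ranges$input)
  m0 <- flat_to_rows(x, d$c0)
  c1 <- conv_rows(m0, params$W1, params$b1, d$t0, keep_shifts = keep_cache)
  z1 <- if (keep_cache) c1$out else c1
  a1 <- swish(z1)
  p1 <- pool_rows(a1, d$t0, cfg$pool_size)
  p1 <- fake_quant(p1, act_ranges$pool1)
  c2 <- conv_rows(p1, params$W2, params$b2, d$t1, keep_shifts = keep_cache)
  z2 <- if (keep_cache) c2$out else c2
  a2 <- swish(z2)
  p2 <- pool_rows(a2, d$t1, cfg$pool_size)
  p2 <- fake_quant(p2, act_ranges$pool2)
  fl <- rows_to_flat(p2, n)
  if (!is.null(dropout_mask)) fl <- fl * dropout_mask
  zd <- sweep(fl %*% params$W3, 2, params$b3, `+`)
  ad <- swish(zd)
  ad <- fake_quant(ad, act_ranges$dense1)
  logits <- sweep(ad %*% params$W4, 2, params$b4, `+`)
  logits <- fake_quant(logits, act_ranges$logits)
  probs <- softmax_rows(logits)
  if (!keep_cache) return(list(probs = probs, logits = logits))
  list(probs = probs, logits = logits,
       s1 = c1$shifts, z1 = z1, p1 = p1, s2 = c2$shifts, z2 = z2, p2 = p2,
       fl = fl, zd = zd, ad = ad)
}

## Cross-entropy loss and full gradient for one batch.
cnn_loss_grad <- function(params, x, y_onehot, cfg, dropout_mask = NULL) {
  d <- cnn_dims(cfg)
  n <- nrow(x)
  fw <- cnn_forward(params, x, cfg, dropout_mask = dropout_mask,
                    keep_cache = TRUE)
  loss <- -mean(rowSums(y_onehot * log(fw$probs + 1e-12)))

  dlogits <- (fw$probs - y_onehot) / n
  gW4 <- crossprod(fw$ad, dlogits)
  gb4 <- colSums(dlogits)
  dad <- dlogits %*% t(params$W4)
  dzd <- dad * swish_grad(fw$zd)
  gW3 <- crossprod(fw$fl, dzd)
  gb3 <- colSums(dzd)
  dfl <- dzd %*% t(params$W3)
  if (!is.null(dropout_mask)) dfl <- dfl * dropout_mask
  dp2 <- flat_to_rows(dfl, cfg$conv_filters[2])
  da2 <- unpool_rows(dp2, d$t1, cfg$pool_size)
  dz2 <- da2 * swish_grad(fw$z2)
  gW2 <- conv_rows_grad_w(fw$s2, dz2)
  gb2 <- colSums(dz2)
  dp1 <- conv_rows_grad_in(dz2, params$W2, d$t1)
  da1 <- unpool_rows(dp1, d$t0, cfg$pool_size)
  dz1 <- da1 * swish_grad(fw$z1)
  gW1 <- conv_rows_grad_w(fw$s1, dz1)
  gb1 <- colSums(dz1)

  list(loss = loss,
       grads = list(W1 = gW1, b1 = gb1, W2 = gW2, b2 = gb2,
                    W3 = gW3, b3 = gb3, W4 = gW4, b4 = gb4))
}

## Parameter vector round-trips (used by the finite-difference gradient
## check and by quantization).
params_to_vector <- function(p) {
  unlist(lapply(p, as.vector), use.names = FALSE)
}
vector_to_params <- function(v, template) {
  out <- template
  pos <- 0L
  for (nm in names(template)) {
    n <- length(template[[nm]])
    slice <- v[(pos + 1L):(pos + n)]
    out[[nm]] <- if (is.array(template[[nm]]) || is.matrix(template[[nm]])) {
      array(slice, dim = dim(template[[nm]]))
    } else {
      slice
    }
    pos <- pos + n
  }
  out
}

onehot <- function(y, classes) {
  m <- matrix(0, length(y), length(classes))
  m[cbind(seq_along(y), match(y, classes))] <- 1
  m
}

#' Fit the compact 1D-CNN ECG classifier
#'
#' Trains the two-conv / two-dense Swish network on flattened spectrogram
#' features with the Adam optimizer (cross-entropy objective), mini-batches
#' and early stopping on the validation loss with best-weight restoration.
#' Train and validation data must come from disjoint patients; pass the
#' split manifest (or the patient ids) so the fit can verify this.
#'
#' @param x Numeric matrix, one flattened time-major spectrogram per row
#'   (see [featurize_windows()]).
#' @param y Class labels (factor or character: `"healthy"`/`"diabetic"`).
#' @param val_x,val_y Validation features and labels, used for early
#'   stopping; if omitted the training loss is monitored instead.
#' @param config A [cnn_config()].
#' @param epochs Maximum training epochs.
#' @param learning_rate Adam step size.
#' @param batch_size Mini-batch size.
#' @param patience Early-stopping patience (epochs without monitored-loss
#'   improvement).
#' @param seed Integer seed controlling initialization, batch shuffling and
#'   dropout.
#' @param train_patients,val_patients Optional patient-id vectors aligned
#'   with `x` / `val_x`; if both given, any overlap is an error.
#' @param verbose Print per-epoch progress.
#' @return An object of class `ecg_cnn` with components `params`, `config`,
#'   `classes`, `history` (per-epoch losses/accuracies), `best_epoch` and
#'   `n_parameters`.
#' @seealso [predict.ecg_cnn()], [evaluate_model()], [quantize_int8()]
#' @export
ecg_cnn <- function(x, y, val_x = NULL, val_y = NULL,
                    config = cnn_config(), epochs = 500,
                    learning_rate = 5e-4, batch_size = 128,
                    patience = 50, seed = 1L,
                    train_patients = NULL, val_patients = NULL,
                    verbose = FALSE) {
  stopifnot(is.matrix(x))
  if (nrow(x) == 0) stop("empty training set", call. = FALSE)
  stopifnot_scalar(learning_rate, "learning_rate", positive = TRUE)
  if (batch_size < 1) stop("batch_size must be >= 1", call. = FALSE)
  classes <- if (is.factor(y)) levels(y) else sort(unique(as.character(y)))
  y <- as.character(y)
  if (length(unique(y)) < 2) {
    stop("training set contains a single class", call. = FALSE)
  }
  if (!is.null(train_patients) && !is.null(val_patients)) {
    overlap <- intersect(unique(train_patients), unique(val_patients))
    if (length(overlap)) {
      stop(sprintf("train/validation splits share patients: %s",
                   paste(overlap, collapse = ", ")), call. = FALSE)
    }
  }
  has_val <- !is.null(val_x) && !is.null(val_y) && nrow(val_x) > 0
  y_mat <- onehot(y, classes)
  if (has_val) val_mat <- onehot(as.character(val_y), classes)

  params <- cnn_init(config, seed)
  d <- cnn_dims(config)
  adam_m <- lapply(params, function(p) p * 0)
  adam_v <- lapply(params, function(p) p * 0)
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
  step <- 0L
  n <- nrow(x)
  keep_prob <- 1 - config$dropout_rate

  history <- vector("list", epochs)
  best_loss <- Inf
  best_params <- params
  best_epoch <- 0L
  wait <- 0L

  with_seed(mix_seed(seed, "train"), {
    for (epoch in seq_len(epochs)) {
      ord <- sample.int(n)
      ep_loss <- 0
      n_batches <- 0L
      for (start in seq(1L, n, by = batch_size)) {
        idx <- ord[start:min(start + batch_size - 1L, n)]
        xb <- x[idx, , drop = FALSE]
        yb <- y_mat[idx, , drop = FALSE]
        mask <- if (config$dropout_rate > 0) {
          matrix(stats::rbinom(length(idx) * d$flat, 1, keep_prob) /
                   keep_prob, length(idx), d$flat)
        } else NULL
        lg <- cnn_loss_grad(params, xb, yb, config, dropout_mask = mask)
        ep_loss <- ep_loss + lg$loss
        n_batches <- n_batches + 1L
        step <- step + 1L
        corr <- sqrt(1 - b2^step) / (1 - b1^step)
        for (nm in names(params)) {
          g <- lg$grads[[nm]]
          adam_m[[nm]] <- b1 * adam_m[[nm]] + (1 - b1) * g
          adam_v[[nm]] <- b2 * adam_v[[nm]] + (1 - b2) * g^2
          params[[nm]] <- params[[nm]] - learning_rate * corr *
            adam_m[[nm]] / (sqrt(adam_v[[nm]]) + eps)
        }
      }
      train_loss <- ep_loss / n_batches
      if (has_val) {
        vp <- cnn_forward(params, val_x, config)$probs
        val_loss <- -mean(rowSums(val_mat * log(vp + 1e-12)))
        val_acc <- mean(classes[max.col(vp)] == as.character(val_y))
      } else {
        val_loss <- NA_real_
        val_acc <- NA_real_
      }
      history[[epoch]] <- data.frame(epoch = epoch, train_loss = train_loss,
                                     val_loss = val_loss, val_acc = val_acc)
      if (verbose) {
        message(sprintf("epoch %3d  train loss %.4f  val loss %s", epoch,
                        train_loss,
                        if (has_val) sprintf("%.4f", val_loss) else "-"))
      }
      monitored <- if (has_val) val_loss else train_loss
      if (monitored < best_loss - 1e-6) {
        best_loss <- monitored
        best_params <- params
        best_epoch <- epoch
        wait <- 0L
      } else {
        wait <- wait + 1L
        if (wait >= patience) break
      }
    }
  })

  history <- do.call(rbind, history[!vapply(history, is.null, TRUE)])
  structure(list(params = best_params, config = config, classes = classes,
                 history = history, best_epoch = best_epoch,
                 monitored = if (has_val) "val_loss" else "train_loss",
                 n_parameters = unname(
                   cnn_parameter_count(config)[["total"]]),
                 learning_rate = learning_rate, batch_size = batch_size,
                 patience = patience, seed = as.integer(seed),
                 call = match.call()),
            class = "ecg_cnn")
}

#' Predict from a fitted ECG CNN
#'
#' @param object An [ecg_cnn()] fit.
#' @param newx Feature matrix (rows as in training) or a single
#'   `feature_tensor`.
#' @param type `"prob"` for class probabilities, `"class"` for hard labels.
#' @param ... Unused.
#' @return Matrix of probabilities (columns named by class) or a character
#'   vector of labels.
#' @export
predict.ecg_cnn <- function(object, newx, type = c("prob", "class"), ...) {
  type <- match.arg(type)
  if (inherits(newx, "feature_tensor")) {
    newx <- matrix(as_feature_vector(newx), nrow = 1)
  }
  probs <- cnn_forward(object$params, newx, object$config)$probs
  colnames(probs) <- object$classes
  if (type == "prob") probs else object$classes[max.col(probs)]
}

#' @export
print.ecg_cnn <- function(x, ...) {
  cat("Compact 1D-CNN ECG classifier\n")
  cat(sprintf("  input: %d frames x %d bins (conv along %s)\n",
              x$config$input_frames, x$config$input_bins,
              x$config$time_axis))
  cat(sprintf("  parameters: %d  classes: %s\n", x$n_parameters,
              paste(x$classes, collapse = ", ")))
  cat(sprintf("  trained %d epochs (best %d, monitoring %s)\n",
              nrow(x$history), x$best_epoch, x$monitored))
  invisible(x)
}

#' @export
summary.ecg_cnn <- function(object, ...) {
  counts <- cnn_parameter_count(object$config)
  d <- cnn_dims(object$config)
  layers <- data.frame(
    layer = c("conv1 (swish)", "avgpool1", "conv2 (swish)", "avgpool2",
              "flatten+dropout", "dense1 (swish)", "dense2 (softmax)"),
    output = c(sprintf("%d x %d", d$t0, object$config$conv_filters[1]),
               sprintf("%d x %d", d$t1, object$config$conv_filters[1]),
               sprintf("%d x %d", d$t1, object$config$conv_filters[2]),
               sprintf("%d x %d", d$t2, object$config$conv_filters[2]),
               sprintf("%d", d$flat),
               sprintf("%d", object$config$dense_units),
               sprintf("%d", object$config$n_classes)),
    parameters = c(counts[["conv1"]], 0, counts[["conv2"]], 0, 0,
                   counts[["dense1"]], counts[["dense2"]]))
  out <- list(layers = layers, total = counts[["total"]],
              history = object$history, best_epoch = object$best_epoch)
  class(out) <- "summary.ecg_cnn"
  out
}

#' @export
print.summary.ecg_cnn <- function(x, ...) {
  print(x$layers, row.names = FALSE)
  cat(sprintf("total parameters: %d; best epoch %d of %d\n",
              x$total, x$best_epoch, nrow(x$history)))
  invisible(x)
}

#' @export
coef.ecg_cnn <- function(object, ...) object$params

#' Plot training history
#' @param x An [ecg_cnn()] fit.
#' @param ... Passed to [graphics::matplot()].
#' @export
plot.ecg_cnn <- function(x, ...) {
  h <- x$history
  graphics::matplot(h$epoch, cbind(h$train_loss, h$val_loss), type = "l",
                    lty = 1, col = c("black", "red3"),
                    xlab = "epoch", ylab = "cross-entropy loss", ...)
  graphics::abline(v = x$best_epoch, lty = 3)
  graphics::legend("topright", c("train", "validation"), lty = 1,
                   col = c("black", "red3"), bty = "n")
  invisible(x)
}
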