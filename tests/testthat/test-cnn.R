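tiny_cfg <- cnn_config(conv_filters = c(2, 3), dense_units = 4,
                       input_frames = 10, input_bins = 8)

test_that("parameter counts follow the architecture arithmetic", {
  counts <- cnn_parameter_count(cnn_config())
  expect_equal(counts[["conv1"]], 129 * 3 * 8 + 8)   # 3104
  expect_equal(counts[["conv2"]], 8 * 3 * 16 + 16)
  expect_equal(counts[["dense1"]], 15 * 16 * 20 + 20)
  expect_equal(counts[["dense2"]], 20 * 2 + 2)
  p <- ecgedge:::cnn_init(cnn_config(), 1)
  expect_length(ecgedge:::params_to_vector(p), counts[["total"]])
})

test_that("swish has the right fixed point and asymptote", {
  expect_equal(swish(0), 0)
  expect_lt(abs(swish(20) / 20 - 1), 1e-6)
  expect_lt(abs(swish(-20)), 1e-6)
})

test_that("an untrained model emits valid probabilities", {
  set.seed(20)
  p <- ecgedge:::cnn_init(tiny_cfg, 3)
  x <- matrix(stats::rnorm(5 * 80), 5, 80)
  probs <- ecgedge:::cnn_forward(p, x, tiny_cfg)$probs
  expect_equal(rowSums(probs), rep(1, 5), tolerance = 1e-6)
  expect_true(all(probs > 0))
  expect_error(ecgedge:::cnn_forward(p, matrix(0, 2, 81), tiny_cfg),
               "expects")
})

test_that("analytic gradients match finite differences", {
  set.seed(22)
  p <- ecgedge:::cnn_init(tiny_cfg, 5)
  x <- matrix(stats::rnorm(6 * 80), 6, 80)
  y <- ecgedge:::onehot(sample(c("healthy", "diabetic"), 6, TRUE),
                        c("healthy", "diabetic"))
  analytic <- ecgedge:::params_to_vector(
    ecgedge:::cnn_loss_grad(p, x, y, tiny_cfg)$grads)
  v <- ecgedge:::params_to_vector(p)
  eps <- 1e-5
  loss_at <- function(vv) {
    ecgedge:::cnn_loss_grad(ecgedge:::vector_to_params(vv, p), x, y,
                            tiny_cfg)$loss
  }
  idx <- round(seq(1, length(v), length.out = 5))
  for (i in idx) {
    vp <- v; vp[i] <- vp[i] + eps
    vm <- v; vm[i] <- vm[i] - eps
    numeric_grad <- (loss_at(vp) - loss_at(vm)) / (2 * eps)
    expect_lt(abs(analytic[i] - numeric_grad) /
                max(abs(numeric_grad), 1e-8), 1e-3)
  }
})

test_that("the network saturates a linearly separable toy problem", {
  set.seed(24)
  n <- 512
  mu <- rep(c(0.8, -0.8), each = n / 2)
  x <- matrix(stats::rnorm(n * 80, mean = mu), n, 80)
  y <- rep(c("diabetic", "healthy"), each = n / 2)
  fit <- ecg_cnn(x, y, config = tiny_cfg, epochs = 100, batch_size = 64,
                 patience = 100, seed = 7)
  expect_gte(mean(predict(fit, x, type = "class") == y), 0.99)
  expect_lte(nrow(fit$history), 100)
})

test_that("training degeneracies and leakage guards raise errors", {
  x <- matrix(stats::rnorm(10 * 80), 10, 80)
  expect_error(ecg_cnn(x[0, , drop = FALSE], character(0), config = tiny_cfg),
               "empty")
  expect_error(ecg_cnn(x, rep("healthy", 10), config = tiny_cfg),
               "single class")
  expect_error(
    ecg_cnn(x, rep(c("healthy", "diabetic"), 5), x, rep("healthy", 10),
            config = tiny_cfg, epochs = 1,
            train_patients = rep(c("A", "B"), 5),
            val_patients = rep("B", 10)),
    "share patients")
})

test_that("early stopping halts a stalled fit and keeps the best epoch", {
  set.seed(26)
  ## labels independent of features: validation loss cannot keep improving
  x <- matrix(stats::rnorm(64 * 80), 64, 80)
  y <- rep(c("healthy", "diabetic"), 32)
  xv <- matrix(stats::rnorm(32 * 80), 32, 80)
  yv <- rep(c("healthy", "diabetic"), 16)
  fit <- ecg_cnn(x, y, xv, yv, config = tiny_cfg, epochs = 400,
                 batch_size = 32, patience = 5, seed = 9)
  expect_lt(nrow(fit$history), 400)
  expect_lte(fit$best_epoch, nrow(fit$history))
  expect_equal(fit$monitored, "val_loss")
})

test_that("confusion-matrix metrics match hand arithmetic", {
  perfect <- metrics_from_confusion(matrix(c(50, 0, 0, 50), 2, byrow = TRUE))
  expect_equal(perfect$accuracy, 1)
  expect_equal(perfect$weighted_f1, 1)

  m <- metrics_from_confusion(matrix(c(45, 5, 10, 40), 2, byrow = TRUE))
  expect_equal(m$accuracy, 0.85)

  sym <- metrics_from_confusion(matrix(c(45, 5, 5, 45), 2, byrow = TRUE))
  expect_equal(sym$accuracy, 0.9)
  expect_equal(sym$weighted_precision, 0.9)
  expect_equal(sym$weighted_recall, 0.9)

  expect_warning(
    z <- metrics_from_confusion(matrix(c(0, 0, 0, 100), 2, byrow = TRUE)),
    "zero-support")
  expect_true(z$zero_division)
  expect_equal(z$per_class$recall[1], 0)
  expect_equal(z$accuracy, 1)

  expect_error(metrics_from_confusion(matrix(0, 2, 2)), "total > 0")
})

test_that("evaluation reports a coherent confusion matrix and AUC", {
  set.seed(28)
  n <- 128
  mu <- rep(c(1, -1), each = n / 2)
  x <- matrix(stats::rnorm(n * 80, mean = mu), n, 80)
  y <- rep(c("diabetic", "healthy"), each = n / 2)
  fit <- ecg_cnn(x, y, config = tiny_cfg, epochs = 60, batch_size = 64,
                 patience = 60, seed = 11)
  ev <- evaluate_model(fit, x, y)
  expect_equal(sum(ev$confusion), n)
  expect_gte(ev$accuracy, 0.95)
  expect_gte(ev$auc, 0.99)
  ## single-class evaluation: AUC undefined
  suppressWarnings(ev1 <- evaluate_model(fit, x[1:10, ], rep("diabetic", 10)))
  expect_true(is.na(ev1$auc))
})

test_that("both convolution orientations run and differ", {
  set.seed(30)
  x <- matrix(stats::rnorm(4 * 80), 4, 80)
  p <- ecgedge:::cnn_init(tiny_cfg, 2)
  cfg_t <- tiny_cfg
  cfg_t$time_axis <- "bins"
  p_t <- ecgedge:::cnn_init(cfg_t, 2)
  a <- ecgedge:::cnn_forward(p, x, tiny_cfg)$probs
  b <- ecgedge:::cnn_forward(p_t, x, cfg_t)$probs
  expect_equal(dim(a), dim(b))
  expect_false(isTRUE(all.equal(a, b)))
})
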