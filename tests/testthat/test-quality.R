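test_that("moment statistics match closed forms", {
  alternating <- rep(c(-1, 1), 125)
  st <- moment_stats(alternating)
  expect_equal(st[["skewness"]], 0)
  expect_equal(st[["kurtosis"]], 1)

  set.seed(5)
  g <- stats::rnorm(1e5)
  st_g <- moment_stats(g)
  expect_lt(abs(st_g[["skewness"]]), 0.1)
  expect_lt(abs(st_g[["kurtosis"]] - 3), 0.2)

  ## one large spike among low-level samples drives kurtosis far above 30
  spiky <- c(rep(c(-0.01, 0.01), 124), 0.01, 5)
  expect_gt(moment_stats(spiky)[["kurtosis"]], 30)

  expect_error(moment_stats(c(1, 2, 3)), "4 samples")
  expect_error(moment_stats(rep(2, 100)), "variance")
})

test_that("moment statistics agree with an independent implementation", {
  skip_if_not_installed("e1071")
  set.seed(31)
  for (i in 1:20) {
    x <- stats::rnorm(250, sd = stats::runif(1, 0.1, 5))^(sample(1:3, 1))
    expect_equal(moment_stats(x), oracle_moments(x), tolerance = 1e-10)
  }
})

test_that("the violation budget boundary is exact: 3 clean, 4 noisy", {
  base <- clean_minute()
  flatten_seconds <- function(seg, secs) {
    for (s in secs) {
      seg$samples[((s - 1) * seg$fs + 1):(s * seg$fs)] <- 0  # zero variance
    }
    seg
  }
  expect_true(screen_segment(flatten_seconds(base, 1:3))$clean)
  expect_equal(screen_segment(flatten_seconds(base, 1:3))$n_violations, 3)
  expect_false(screen_segment(flatten_seconds(base, 1:4))$clean)
  expect_equal(screen_segment(flatten_seconds(base, c(2, 17, 33, 58)))$n_violations, 4)
})

test_that("clean synthetic minutes pass; spike-ridden minutes fail", {
  minute <- clean_minute()
  expect_true(screen_segment(minute)$clean)
  spiked <- minute
  for (s in c(5, 15, 25, 35, 45)) spiked <- inject_spike_second(spiked, s)
  expect_false(screen_segment(spiked)$clean)
})

test_that("screening is invariant under positive affine rescaling", {
  minute <- clean_minute(seed = 3)
  spiked <- inject_spike_second(minute, 10)
  for (seg in list(minute, spiked)) {
    ref <- screen_segment(seg)
    scaled <- seg
    scaled$samples <- 3.7 * seg$samples - 2.2
    got <- screen_segment(scaled)
    expect_equal(got$per_subsegment$violated, ref$per_subsegment$violated)
    expect_equal(got$n_violations, ref$n_violations)
    expect_equal(got$clean, ref$clean)
  }
})

test_that("adding a spike never un-violates a subsegment", {
  minute <- clean_minute(seed = 7)
  before <- screen_segment(minute)$per_subsegment$violated
  for (amp in c(5, 8, 12)) {
    spiked <- inject_spike_second(minute, 20, amp = amp)
    after <- screen_segment(spiked)$per_subsegment$violated
    expect_true(all(after[before]))   # violated stays violated
  }
})

test_that("violation counts match a brute-force recount", {
  skip_if_not_installed("e1071")
  minute <- inject_spike_second(clean_minute(seed = 9), 30)
  cfg <- quality_config()
  rep <- screen_segment(minute, cfg)
  fs <- minute$fs
  recount <- 0
  for (i in 1:60) {
    x <- minute$samples[((i - 1) * fs + 1):(i * fs)]
    st <- oracle_moments(x)
    if (st[["skewness"]] < 0 || st[["skewness"]] > 5 ||
        st[["kurtosis"]] < 3 || st[["kurtosis"]] > 30) recount <- recount + 1
  }
  expect_equal(rep$n_violations, recount)
})

test_that("an inverted lead is rejected by the signed skewness bound", {
  minute <- clean_minute(seed = 13)
  expect_true(screen_segment(minute)$clean)
  flipped <- minute
  flipped$samples <- -minute$samples
  expect_false(screen_segment(flipped)$clean)
  ## the documented escape hatch: screen on |skewness|
  expect_true(screen_segment(flipped, quality_config(abs_skew = TRUE))$clean)
})

test_that("cohort screening partitions and summarizes per patient", {
  expect_length(screen_cohort(list())$clean, 0)
  good <- clean_minute(seed = 21)
  bad <- good
  for (s in seq(2, 50, by = 4)) bad <- inject_spike_second(bad, s)
  bad$patient_id <- "noisy01"
  res <- screen_cohort(list(good, bad, good))
  expect_length(res$clean, 2)
  expect_length(res$rejected, 1)
  summ <- res$summary
  expect_equal(summ$accept_rate[summ$patient_id == "noisy01"], 0)
  expect_true(all(summ$accept_rate[summ$patient_id != "noisy01"] > 0))
})
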