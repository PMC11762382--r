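make_minutes <- function(n, patient = "P01", label = "healthy", fs = 250) {
  lapply(seq_len(n) - 1L, function(i) {
    structure(list(samples = stats::rnorm(60 * fs), fs = fs,
                   patient_id = patient, label = label,
                   segment_index = i),
              class = "minute_segment")
  })
}

test_that("windowing geometry follows the 5 s / 1 s overlap rule", {
  set.seed(1)
  w1 <- window_minutes(make_minutes(1))
  expect_length(w1, 14)                       # floor((60-5)/4)+1
  expect_true(all(vapply(w1, function(w) length(w$samples), 0L) == 1250))
  w2 <- window_minutes(make_minutes(2))
  expect_length(w2, 28)
  expect_equal(sort(vapply(w2, `[[`, 0L, "window_index")), 0:27)
  expect_length(window_minutes(make_minutes(1), window_s = 5, overlap_s = 0),
                12)
  expect_error(window_minutes(make_minutes(1), window_s = 1, overlap_s = 2),
               "overlap")
})

test_that("windows never extend past their source minute", {
  set.seed(2)
  wins <- window_minutes(make_minutes(2))
  ends <- vapply(wins, function(w) w$offset_s + length(w$samples) / w$fs, 0)
  expect_true(all(ends <= 60 + 1e-9))
})

test_that("the greedy split puts the largest patients in training", {
  wins <- c(fake_windows(c(h1 = 40), "healthy"),
            fake_windows(c(d1 = 40), "diabetic"),
            fake_windows(c(h2 = 10), "healthy"),
            fake_windows(c(d2 = 10), "diabetic"))
  ## with one residual patient per class, test/validation cannot both cover
  ## both classes; the split warns about the best-effort assignment
  suppressWarnings(man <- split_by_patient(wins, target_fraction = 0.8,
                                           seed = 1))
  sp <- setNames(man$split, man$patient_id)
  expect_equal(unname(sp[c("h1", "d1")]), c("train", "train"))
  expect_setequal(unname(sp[c("h2", "d2")]), c("test", "validation"))
  expect_equal(attr(man, "train_fraction"), 0.8)
})

test_that("splits are patient-disjoint with all splits populated", {
  set.seed(3)
  for (rep in 1:10) {
    n_h <- sample(3:8, 1)
    n_d <- sample(3:8, 1)
    counts_h <- setNames(sample(5:40, n_h), sprintf("H%02d", seq_len(n_h)))
    counts_d <- setNames(sample(5:40, n_d), sprintf("D%02d", seq_len(n_d)))
    wins <- c(fake_windows(counts_h, rep("healthy", n_h)),
              fake_windows(counts_d, rep("diabetic", n_d)))
    man <- split_by_patient(wins, 0.8, seed = rep)
    expect_true(assert_patient_disjoint(man))
    expect_setequal(unique(man$split), c("train", "validation", "test"))
    ## both classes in train, and in test whenever >= 2 residual per class
    expect_setequal(unique(man$label[man$split == "train"]),
                    c("healthy", "diabetic"))
  }
})

test_that("split assignment is deterministic and guards small classes", {
  wins <- c(fake_windows(c(h1 = 10, h2 = 12, h3 = 9), rep("healthy", 3)),
            fake_windows(c(d1 = 11, d2 = 8, d3 = 10), rep("diabetic", 3)))
  m1 <- split_by_patient(wins, 0.8, seed = 5)
  m2 <- split_by_patient(wins, 0.8, seed = 5)
  expect_identical(as.data.frame(m1), as.data.frame(m2))
  solo <- c(fake_windows(c(h1 = 10, h2 = 10), rep("healthy", 2)),
            fake_windows(c(d1 = 10), "diabetic"))
  expect_error(split_by_patient(solo), "fewer than 2 patients")
})

test_that("class balancing subsamples the majority to within one window", {
  wins <- c(fake_windows(c(h1 = 60, h2 = 40), rep("healthy", 2)),
            fake_windows(c(d1 = 30, d2 = 30), rep("diabetic", 2)))
  man <- structure(data.frame(patient_id = c("h1", "h2", "d1", "d2"),
                              label = c("healthy", "healthy",
                                        "diabetic", "diabetic"),
                              split = "train",
                              n_windows = c(60, 40, 30, 30)),
                   class = c("split_manifest", "data.frame"))
  out <- balance_classes(wins, man, seed = 2)
  tab <- table(vapply(out, `[[`, "", "label"))
  expect_lte(abs(tab[["healthy"]] - tab[["diabetic"]]), 1)
  expect_equal(tab[["diabetic"]], 60)          # minority untouched
  out2 <- balance_classes(wins, man, seed = 2)
  expect_identical(vapply(out, function(w) paste(w$patient_id, w$window_index),
                          ""),
                   vapply(out2, function(w) paste(w$patient_id, w$window_index),
                          ""))
  balanced <- c(fake_windows(c(h1 = 30, d1 = 30), c("healthy", "diabetic")))
  man_b <- man[c(1, 3), ]
  man_b$patient_id <- c("h1", "d1")
  man_b$n_windows <- c(30, 30)
  expect_length(balance_classes(balanced, man_b, seed = 1), 60)
})

test_that("patient-level label shuffling preserves counts and coherence", {
  wins <- c(fake_windows(c(h1 = 5, h2 = 7), rep("healthy", 2)),
            fake_windows(c(d1 = 6, d2 = 4), rep("diabetic", 2)))
  sh <- shuffle_labels_by_patient(wins, seed = 4)
  pid <- vapply(sh, `[[`, "", "patient_id")
  lab <- vapply(sh, `[[`, "", "label")
  for (p in unique(pid)) expect_length(unique(lab[pid == p]), 1)
  ## patient-level class counts preserved (2 healthy, 2 diabetic patients)
  per_patient <- vapply(unique(pid), function(p) lab[pid == p][1], "")
  expect_equal(as.vector(table(per_patient)), c(2, 2))
})
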