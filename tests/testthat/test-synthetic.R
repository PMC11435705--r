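test_that("cohort configuration validates its knobs", {
  expect_error(cohort_config(n_subjects = 1), "2 subjects")
  expect_error(cohort_config(gain_sigma = -1), ">= 0")
  expect_error(cohort_config(class_sequence = c(0, 5)), "class id")
  expect_error(cohort_config(segment_ms = 220, segment_jitter = 0.2),
               "200 ms")
})

test_that("subject generation is deterministic and labeled sample-by-sample", {
  cc <- cohort_config(n_subjects = 2, trial_seconds = 3, seed = 9)
  p <- subject_profile(cc, 1)
  r1 <- generate_subject(p, cc)
  r2 <- generate_subject(p, cc)
  expect_identical(r1$data, r2$data)
  expect_identical(r1$labels, r2$labels)
  expect_equal(ncol(r1$data), 3000)
  expect_true(all(r1$labels %in% 0:3))
  expect_true(all(rowSums(abs(p$mixing)) - 1 < 1e-12))  # row-stochastic
  expect_true(all(p$channel_gains > 0))

  # every label segment spans at least one 200 ms window
  runs <- rle(r1$labels)
  expect_true(all(runs$lengths[-length(runs$lengths)] >= 200))
})

test_that("a silenced class produces zero signal during its segments", {
  cc <- cohort_config(n_subjects = 2, trial_seconds = 3, noise_floor = 0,
                      seed = 5)
  p <- subject_profile(cc, 1)
  p$noise_floor <- 0
  p$envelope_scale[1] <- 0       # class 0 never activates
  rec <- generate_subject(p, cc)
  in_class0 <- rec$labels == 0L
  expect_true(any(in_class0))
  expect_equal(max(abs(rec$data[, in_class0])), 0)
  expect_gt(max(abs(rec$data[, !in_class0])), 0)
})

test_that("carriers concentrate their power in the 20-450 Hz band", {
  cc <- cohort_config(n_subjects = 2, trial_seconds = 4, noise_floor = 0,
                      seed = 3)
  rec <- generate_subject(subject_profile(cc, 1), cc)
  x <- rec$data[1, ]
  sp <- stats::spec.pgram(x, plot = FALSE, taper = 0, detrend = FALSE)
  f <- sp$freq * cc$fs
  in_band <- sum(sp$spec[f >= 20 & f <= 450])
  expect_gt(in_band / sum(sp$spec), 0.90)
})

test_that("zero variability collapses subjects to the same profile", {
  cc <- cohort_config(n_subjects = 3, trial_seconds = 2, gain_sigma = 0,
                      channel_weight_sigma = 0, shift_sigma_ms = 0,
                      mixing_strength = 0, envelope_scale_sigma = 0,
                      seed = 8)
  coh <- generate_cohort(cc)
  p <- coh$manifest$profiles
  for (i in 2:3) {
    expect_equal(p[[i]]$channel_gains, p[[1]]$channel_gains)
    expect_equal(p[[i]]$mixing, p[[1]]$mixing)
    expect_equal(p[[i]]$envelope_shift_ms, 0)
    expect_equal(p[[i]]$envelope_scale, rep(1, 4))
  }
  # signals still differ: independent carrier noise realizations
  expect_false(identical(coh$recordings[[1]]$data, coh$recordings[[2]]$data))
})

test_that("cohorts round-trip through the dataset writer", {
  coh <- generate_cohort(cohort_config(n_subjects = 2, trial_seconds = 2,
                                       seed = 12))
  path <- withr::local_tempdir()
  write_cohort(coh$recordings, path)
  back <- read_cohort(path)
  expect_identical(back[[1]]$data, coh$recordings[[1]]$data)
  expect_identical(back[[2]]$labels, coh$recordings[[2]]$labels)
  # the manifest itself serializes to JSON
  js <- jsonlite::toJSON(coh$manifest, auto_unbox = TRUE, digits = NA,
                         force = TRUE)
  expect_gt(nchar(js), 100)
})

test_that("raising the gain spread widens the raw cross-subject gap", {
  # proxy classifier on raw (unnormalized) window RMS features: linear
  # discriminant trained on subject 1, tested on subject 2
  skip_if_not_installed("MASS")
  xsub_acc <- function(gain_sigma, seed) {
    cc <- cohort_config(n_subjects = 2, trial_seconds = 6,
                        gain_sigma = gain_sigma, channel_weight_sigma = 0.1,
                        mixing_strength = 0, shift_sigma_ms = 0,
                        envelope_scale_sigma = 0, seed = seed)
    coh <- generate_cohort(cc)
    feats <- lapply(coh$recordings, function(r) {
      ws <- segment_windows(bandlimit_filter(r))
      list(x = t(apply(ws$windows, 3, function(w) sqrt(rowMeans(w^2)))),
           y = ws$labels)
    })
    fit <- MASS::lda(feats[[1]]$x, grouping = feats[[1]]$y)
    mean(predict(fit, feats[[2]]$x)$class == feats[[2]]$y)
  }
  lo <- mean(vapply(1:3, function(s) xsub_acc(0.05, 20 + s), 0))
  hi <- mean(vapply(1:3, function(s) xsub_acc(0.8, 20 + s), 0))
  expect_gt(lo, hi)
})

test_that("the default cohort opens a positive cross-subject gap", {
  # proxy linear classifier on window RMS features: accuracy on a held-in
  # split of the training subject minus accuracy on a held-out subject
  skip_if_not_installed("MASS")
  gap <- vapply(1:3, function(s) {
    coh <- generate_cohort(cohort_config(n_subjects = 2, trial_seconds = 8,
                                         seed = 400 + s))
    feats <- lapply(coh$recordings, function(r) {
      ws <- prepare_windows(r)
      list(x = t(apply(ws$windows, 3, function(w) sqrt(rowMeans(w^2)))),
           y = ws$labels)
    })
    n <- nrow(feats[[1]]$x)
    tr <- seq_len(n) <= n / 2
    fit <- MASS::lda(feats[[1]]$x[tr, ], grouping = feats[[1]]$y[tr])
    held_in <- mean(predict(fit, feats[[1]]$x[!tr, ])$class ==
                      feats[[1]]$y[!tr])
    held_out <- mean(predict(fit, feats[[2]]$x)$class == feats[[2]]$y)
    held_in - held_out
  }, 0)
  expect_gt(mean(gap), 0)
})
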