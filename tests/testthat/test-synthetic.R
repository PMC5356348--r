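test_that("zero-dispersion draws equal the configured medians exactly", {
  cfg <- stroke_cohort_config(n_subjects = 5, sdlog_A = 0, sdlog_tau = 0,
                              sd_C = 0, sd_D = 0)
  p <- draw_subject_params(cfg, seed = 1)
  expect_equal(p$A, rep(279, 5))
  expect_equal(p$tau, rep(64, 5))
  expect_equal(p$C, rep(1.11, 5))
  expect_equal(p$D5, rep(432, 5))
})

test_that("draw medians and IQR converge to the configured operating point", {
  cfg <- stroke_cohort_config(n_subjects = 10000)
  p <- draw_subject_params(cfg, seed = 3)
  expect_equal(median(p$A), 279, tolerance = 0.02)
  expect_equal(median(p$tau), 64, tolerance = 0.02)
  expect_equal(median(p$C), 1.11, tolerance = 0.05)
  # the log-normal quartile ratio matches the IQR ratio the dispersion
  # was calibrated to (a median-anchored log-normal cannot reproduce the
  # reported quartiles themselves, which are asymmetric about the median
  # on the log scale: closed form gives [189.6, 410.6])
  q <- quantile(p$A, c(0.25, 0.75), names = FALSE)
  expect_equal(q[2] / q[1], 455 / 210, tolerance = 0.05)
  expect_equal(q[1], 279 * exp(-qnorm(0.75) * iqr_dispersion(210, 455, log = TRUE)),
               tolerance = 0.03)
})

test_that("non-positive log-normal medians are a configuration error", {
  expect_error(stroke_cohort_config(median_A = -5), "positive")
  expect_error(stroke_cohort_config(sd_C = -1), ">= 0")
})

test_that("training sessions have exact per-target counts and optional no-repeat", {
  cfg <- stroke_cohort_config(n_subjects = 2)
  ch <- simulate_cohort(cfg, seed = 4)
  counts <- table(ch$trials$subject, ch$trials$target)
  expect_true(all(counts == 120))
  expect_equal(max(ch$trials$t), 120)
  # default: never the same target twice in a row within a subject
  for (id in unique(ch$trials$subject)) {
    seqk <- ch$trials$target[ch$trials$subject == id]
    expect_true(all(diff(seqk) != 0))
  }
})

test_that("noise-free, dispersion-free sessions reproduce the model exactly", {
  cfg <- stroke_cohort_config(n_subjects = 1, sdlog_A = 0, sdlog_tau = 0,
                              sd_C = 0, sd_D = 0, residual_sd = 0,
                              retention_noise_sd = 0)
  ch <- simulate_cohort(cfg, seed = 9)
  p <- as.list(ch$params[1, ])
  pred <- predict_mt(p, ch$trials$t, ch$trials$target)
  expect_equal(ch$trials$mt_ms, pred)
})

test_that("generated residual SD matches the configured value", {
  cfg <- stroke_cohort_config(n_subjects = 4)
  ch <- simulate_cohort(cfg, seed = 12)
  res <- unlist(lapply(seq_len(4), function(i) {
    tr <- ch$trials[ch$trials$subject == ch$params$subject[i], ]
    tr$mt_ms - predict_mt(ch$params[i, ], tr$t, tr$target)
  }))
  expect_equal(sd(res), 76, tolerance = 0.05)
})

test_that("test phases follow the retention construct in closed form", {
  cfg <- stroke_cohort_config(n_subjects = 3, retention_fraction = 1,
                              retention_noise_sd = 0)
  ch <- simulate_cohort(cfg, seed = 6)
  Dbar <- rowMeans(ch$params[, paste0("D", 1:5)])
  expect_equal(ch$test_phases$long_term_change,
               ch$params$A / (ch$params$A + Dbar))
  cfg0 <- stroke_cohort_config(n_subjects = 3, retention_fraction = 0,
                               retention_noise_sd = 0)
  ch0 <- simulate_cohort(cfg0, seed = 6)
  expect_equal(ch0$test_phases$mt_1month, ch0$test_phases$mt_pre1)
  expect_equal(ch0$test_phases$long_term_change, rep(0, 3))
})

test_that("same seed reproduces a cohort, different seeds differ", {
  cfg <- control_cohort_config(n_subjects = 3)
  a <- simulate_cohort(cfg, seed = 21)
  b <- simulate_cohort(cfg, seed = 21)
  c <- simulate_cohort(cfg, seed = 22)
  expect_identical(a$trials, b$trials)
  expect_identical(a$test_phases, b$test_phases)
  expect_false(identical(a$trials$mt_ms, c$trials$mt_ms))
})

test_that("minimum-jerk trajectories carry exact threshold-crossing truth", {
  span_frac <- min_jerk_span_oracle()
  tr <- generate_trajectory(1000, 25, sample_rate = 120)
  expect_equal(tr$truth$span_ms, span_frac * 1000, tolerance = 1e-9)
  expect_equal(tr$truth$peak_speed, 1.875 * 25, tolerance = 1e-12)
  # scale invariance of the normalised profile
  tr3 <- generate_trajectory(3000, 25)
  expect_equal(tr3$truth$span_ms / 3000, tr$truth$span_ms / 1000,
               tolerance = 1e-12)
  expect_error(generate_trajectory(1000, 0), "degenerate")
  expect_error(generate_trajectory(50, 25, sample_rate = 100), "20 samples")
})

test_that("cohort tables round-trip losslessly through the CSV writers", {
  ch <- simulate_cohort(stroke_cohort_config(n_subjects = 2), seed = 31)
  td <- withr::local_tempdir()
  f1 <- file.path(td, "trials.csv")
  write_trials(ch$trials, f1)
  back <- read_trials(f1)
  expect_equal(back$mt_ms, ch$trials$mt_ms, tolerance = 1e-12)
  expect_equal(back$subject, ch$trials$subject)
  expect_equal(back$t, ch$trials$t)
  f2 <- file.path(td, "tests.csv")
  write_test_phases(ch$test_phases, f2)
  expect_equal(read_test_phases(f2)$mt_pre1, ch$test_phases$mt_pre1,
               tolerance = 1e-12)
})
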