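make_sine_traj <- function(freq, fs = 120, dur = 10) {
  t <- seq(0, dur, by = 1 / fs)
  data.frame(t_s = t, x_cm = sin(2 * pi * freq * t), y_cm = 0)
}

test_that("lowpass filter has unit DC gain and halves power at the cutoff", {
  t <- seq(0, 2, by = 1 / 120)
  const <- data.frame(t_s = t, x_cm = rep(3.2, length(t)), y_cm = rep(-1, length(t)))
  out <- lowpass_filter(const, 5)
  expect_equal(out$x_cm, const$x_cm, tolerance = 1e-5)
  expect_equal(out$y_cm, const$y_cm, tolerance = 1e-5)
  # two passes of -3 dB at the cutoff: amplitude ratio 0.5
  sine <- make_sine_traj(5)
  f <- lowpass_filter(sine, 5)
  mid <- f$x_cm[sine$t_s > 2 & sine$t_s < 8]
  expect_equal(max(abs(mid)), 0.5, tolerance = 0.01)
  # low-pass contracts the energy of white noise
  set.seed(1)
  noise <- data.frame(t_s = t, x_cm = rnorm(length(t)), y_cm = 0)
  expect_lt(var(lowpass_filter(noise, 5)$x_cm), var(noise$x_cm))
  expect_error(lowpass_filter(sine, 60), "Nyquist")
})

test_that("speed computation recovers known profiles", {
  t <- seq(0, 1, by = 1 / 120)
  lin <- data.frame(t_s = t, x_cm = 10 * t, y_cm = 0)
  sp <- compute_speed(lin)
  expect_equal(sp[5:100], rep(10, 96), tolerance = 1e-10)
  still <- data.frame(t_s = t, x_cm = rep(2, length(t)), y_cm = rep(2, length(t)))
  expect_equal(compute_speed(still), rep(0, length(t)))
  # closed-form minimum-jerk peak speed 1.875 d / T
  tr <- generate_trajectory(1000, 25, sample_rate = 240)
  expect_equal(max(compute_speed(tr$trajectory)), 46.875, tolerance = 0.001)
})

test_that("movement time matches the continuous threshold-crossing oracle", {
  span_frac <- min_jerk_span_oracle()
  for (T_s in c(0.3, 1.0, 3.0)) {
    tr <- generate_trajectory(T_s * 1000, 25, sample_rate = 120)
    seg <- extract_movement_time(tr$trajectory,
                                 target_spec(tr$truth$target_x, tr$truth$target_y))
    expect_lt(abs(seg$mt_ms - span_frac * T_s * 1000), 1000 / 120)
    expect_false(seg$timeout)
  }
})

test_that("movement time scales linearly with duration", {
  Ts <- seq(0.3, 3, by = 0.15)
  mt <- vapply(Ts, function(T_s) {
    tr <- generate_trajectory(T_s * 1000, 25, sample_rate = 120)
    extract_movement_time(tr$trajectory, target_spec(25, 0))$mt_ms
  }, numeric(1))
  fit <- lm(mt ~ I(Ts * 1000))
  expect_equal(unname(coef(fit)[2]), min_jerk_span_oracle(), tolerance = 0.005)
  expect_gt(summary(fit)$r.squared, 0.999)
})

test_that("extraction errors are informative", {
  t <- seq(0, 1, by = 1 / 120)
  still <- data.frame(t_s = t, x_cm = rep(0, length(t)), y_cm = rep(0, length(t)))
  expect_error(extract_movement_time(still, target_spec(10, 0)), "no movement")
  # movement that stops far from the target never acquires it
  tr <- generate_trajectory(1000, 25)
  expect_error(extract_movement_time(tr$trajectory, target_spec(0, 20)),
               "never acquired")
})

test_that("a sub-threshold dip outside the target does not end the movement", {
  # two back-to-back reaches: speed dips below threshold between them at
  # x = 12.5 cm, outside the target at 25 cm; the valid offset is after
  # the second sub-movement. Oracle: exhaustive scan over samples.
  t1 <- generate_trajectory(600, 12.5, pad_s = 0.05)$trajectory
  t2 <- generate_trajectory(600, 12.5, pad_s = 0.05)$trajectory
  t2$x_cm <- t2$x_cm + 12.5
  t2$t_s <- t2$t_s + max(t1$t_s) + 1 / 120
  traj <- rbind(t1, t2)
  traj$t_s <- seq(0, by = 1 / 120, length.out = nrow(traj))
  tg <- target_spec(25, 0)
  seg <- extract_movement_time(traj, tg)
  sp <- compute_speed(traj)
  thr <- 0.05 * max(sp)
  dist <- abs(traj$x_cm - 25)
  oracle_offset <- traj$t_s[which(seq_along(sp) >= which.max(sp) &
                                    sp < thr & dist <= tg$radius)[1]]
  expect_equal(seg$offset_s, oracle_offset)
  expect_gt(seg$offset_s, max(t1$t_s))
})

test_that("extraction is invariant to time shift and rotation about home", {
  tr <- generate_trajectory(1000, 25, sample_rate = 120)
  base <- extract_movement_time(tr$trajectory, target_spec(25, 0))
  shifted <- tr$trajectory
  shifted$t_s <- shifted$t_s + 13.7
  expect_equal(extract_movement_time(shifted, target_spec(25, 0))$mt_ms,
               base$mt_ms)
  th <- 70 * pi / 180
  rot <- tr$trajectory
  rot$x_cm <- tr$trajectory$x_cm * cos(th)
  rot$y_cm <- tr$trajectory$x_cm * sin(th)
  expect_equal(extract_movement_time(rot, target_spec(25 * cos(th),
                                                      25 * sin(th)))$mt_ms,
               base$mt_ms, tolerance = 1e-9)
})

test_that("left-hemiparesis flip is an involution preserving MT", {
  rec <- data.frame(subject = "s", side = c("left", "left", "right", "left"),
                    target = c(1L, 3L, 2L, 5L), mt_ms = c(500, 600, 700, 800))
  once <- flip_left_hemiparesis(rec)
  expect_equal(once$target, c(5L, 3L, 2L, 1L))
  expect_equal(once$mt_ms, rec$mt_ms)
  twice <- flip_left_hemiparesis(once)
  expect_identical(twice, rec)
  # right side alone is the identity
  right <- rec[rec$side == "right", ]
  expect_identical(flip_left_hemiparesis(right), right)
  expect_error(flip_left_hemiparesis(rec, side = "dominant"), "left")
  # trajectory x mirrors about the home axis
  tr <- data.frame(side = "left", x_cm = c(1, -2, 3), target = c(1L, 1L, 1L))
  expect_equal(flip_left_hemiparesis(tr)$x_cm, c(-1, 2, -3))
})
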