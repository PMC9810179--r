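test_that("flip correction is a no-op on unflipped streams and idempotent", {
  set.seed(3)
  prof <- noiseless_profile()
  prof$jerk_scale <- 1
  s <- simulate_trial_response(prof, 120, 200)
  out <- correct_flip(s)
  expect_false(attr(out, "flip_corrected"))
  expect_equal(as.data.frame(out), as.data.frame(s), ignore_attr = TRUE)
  twice <- correct_flip(correct_flip(s))
  expect_equal(as.data.frame(twice), as.data.frame(correct_flip(s)), ignore_attr = TRUE)
})

test_that("flip correction recovers the unflipped emission exactly", {
  prof <- noiseless_profile()
  prof$jerk_scale <- 1
  set.seed(8)
  plain <- simulate_trial_response(prof, 120, 200)
  set.seed(8)
  flipped <- simulate_trial_response(prof, 120, 200, flip = TRUE)
  fixed <- correct_flip(flipped)
  expect_true(attr(fixed, "flip_corrected"))
  for (ch in c("ax", "ay", "az", "gx", "gy", "gz")) {
    expect_equal(fixed[[ch]], plain[[ch]], tolerance = 1e-12)
  }
  expect_lt(max(abs(wrap_signed(fixed$heading - plain$heading))), 1e-9)
  # and a corrected stream is never flipped again
  again <- correct_flip(fixed)
  expect_false(attr(again, "flip_corrected"))
  expect_equal(as.data.frame(again), as.data.frame(fixed), ignore_attr = TRUE)
})

test_that("heading unwrapping handles wraparound and is exact inverse of wrapping", {
  expect_equal(
    as.numeric(unwrap_heading(c(10, 5, 0, 355, 350))),
    c(10, 5, 0, -5, -10)
  )
  mono <- seq(200, 100, by = -0.5)
  expect_equal(as.numeric(unwrap_heading(mono)), mono)
  # random continuous trajectories with per-step |delta| < 80 are recovered
  # up to a global multiple of 360
  set.seed(21)
  for (rep in 1:20) {
    steps <- stats::runif(300, -75, 75)
    traj <- cumsum(c(stats::runif(1, 0, 360), steps))
    wrapped <- wrap_heading(traj)
    rec <- as.numeric(unwrap_heading(wrapped))
    offs <- (rec - traj) / 360
    expect_equal(offs, rep(round(offs[1]), length(offs)), tolerance = 1e-9)
    expect_lt(max(abs(wrap_heading(rec) - wrapped)), 1e-9)
    expect_equal(attr(unwrap_heading(wrapped), "n_rejected"), 0)
  }
})

test_that("glitch samples beyond the gate are rejected, interpolated and counted", {
  traj <- seq(10, 60, by = 0.5)
  spiked <- traj
  spiked[50] <- wrap_heading(traj[50] + 170) # not a wrap: a glitch
  out <- unwrap_heading(spiked)
  expect_equal(attr(out, "n_rejected"), 1)
  expect_equal(as.numeric(out), traj, tolerance = 0.5)
  expect_true(all(abs(diff(as.numeric(out))) < 80))
})

test_that("moving-window smoothing is length-preserving, bounded and linear", {
  expect_equal(moving_window_smooth(rep(3.5, 200)), rep(3.5, 200))
  x <- stats::rnorm(500)
  expect_equal(moving_window_smooth(x, window = 1), x)
  sm <- moving_window_smooth(x, window = 100)
  expect_length(sm, 500)
  expect_true(all(sm >= min(x) - 1e-12 & sm <= max(x) + 1e-12))
  y <- stats::rnorm(500)
  expect_equal(
    moving_window_smooth(2 * x + 3 * y, 100),
    2 * moving_window_smooth(x, 100) + 3 * moving_window_smooth(y, 100),
    tolerance = 1e-10
  )
  expect_error(moving_window_smooth(x, 0), "positive")
})

test_that("smoothing white noise by 100 points shrinks its sd about tenfold", {
  set.seed(17)
  x <- stats::rnorm(20000, sd = 2)
  sm <- moving_window_smooth(x, 100)
  interior <- sm[1000:19000]
  # mean of 100 iid draws has sd sigma/10; wide Monte-Carlo tolerance
  # because neighbouring window means are correlated
  expect_equal(stats::sd(interior), 2 / 10, tolerance = 0.15)
})

test_that("peak detection finds constructed extrema and ignores monotone or flat input", {
  expect_equal(nrow(detect_peaks(seq(0, 10, by = 0.1))), 0)
  expect_equal(nrow(detect_peaks(rep(1, 50))), 0)
  # bimodal speed profile with one inserted stop: peak, trough, peak
  t <- seq(0, 1, by = 0.002)
  x <- exp(-((t - 0.25) / 0.08)^2) + exp(-((t - 0.75) / 0.08)^2)
  ev <- detect_peaks(x)
  expect_equal(ev$type, c("peak", "trough", "peak"))
  expect_equal(t[ev$index], c(0.25, 0.5, 0.75), tolerance = 0.01)
  # events alternate and are ordered for a noisy multi-extremum series
  set.seed(4)
  noisy <- moving_window_smooth(stats::rnorm(2000), 150)
  ev2 <- detect_peaks(noisy)
  if (nrow(ev2) > 1) {
    expect_true(all(diff(ev2$index) > 0))
    expect_true(all(ev2$type[-1] != ev2$type[-nrow(ev2)]))
  }
})

test_that("preprocessing yields a gap-free unwrapped heading and flags", {
  co <- generate_cohort(small_config(flip_prob = 0.5, seed = 13))
  n_flip <- 0
  for (i in seq_len(nrow(co$trials))) {
    cl <- preprocess_stream(co$trials$stream[[i]])
    expect_true(all(abs(diff(cl$heading_unwrapped)) < 80))
    expect_equal(attr(cl, "n_compass_rejections"), 0)
    n_flip <- n_flip + attr(cl, "flip_corrected")
  }
  expect_equal(n_flip, sum(co$trials$flipped))
})
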