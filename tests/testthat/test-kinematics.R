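test_that("median-then-mean smoothing removes single-frame spikes", {
  expect_equal(smooth_series(rep(4, 10)), rep(4, 10))
  expect_equal(smooth_series(c(0, 0, 9, 0, 0)), rep(0, 5))
  ramp <- as.numeric(1:20)
  expect_equal(smooth_series(ramp)[2:19], ramp[2:19])
  # NA frames stay NA and do not leak into neighbours
  x <- c(1, 2, NA, 4, 5)
  s <- smooth_series(x)
  expect_true(is.na(s[3]))
  expect_false(anyNA(s[-3]))
})

test_that("kinematics derivation handles wrap-around and stationarity", {
  fs <- 60
  n <- 30
  pose <- data.frame(x = (0:(n - 1)) * 10 / fs, y = 0,
                     heading = rep(0, n))
  k <- derive_kinematics(pose, fs)
  expect_equal(k$speed[5:(n - 4)], rep(10, n - 8), tolerance = 1e-9)
  expect_equal(k$ang_vel[5:(n - 4)], rep(0, n - 8))
  # heading crossing 359 -> 1 must give ~ +120 deg/s, not a huge spike
  pose2 <- data.frame(x = 0, y = 0,
                      heading = (359 + 2 * (0:(n - 1))) %% 360)
  k2 <- derive_kinematics(pose2, fs)
  expect_equal(k2$ang_vel[5], 120, tolerance = 1e-9)
  expect_true(all(abs(k2$ang_vel[-1]) < 200))
  # stationary pose
  pose3 <- data.frame(x = rep(1, n), y = rep(2, n), heading = rep(45, n))
  expect_true(all(derive_kinematics(pose3, fs)$speed == 0))
})

test_that("jump frames are flagged by either threshold", {
  expect_true(flag_jumps(150, 0))
  expect_true(flag_jumps(5, 1200))
  expect_false(flag_jumps(99, 900))
  expect_identical(flag_jumps(c(NA, 150), c(0, 0)), c(FALSE, TRUE))
})

test_that("trial exclusion applies the jump, wall and inactivity rules", {
  fs <- 60
  n <- 120
  mk <- function(id, x, y, speed, ang_vel)
    data.frame(trial_id = id, x = x, y = y, speed = speed,
               ang_vel = ang_vel)
  good <- mk(1, 0, 0, rep(10, n), rep(20, n))
  jumpy <- mk(2, 0, 0, c(rep(10, 60), 150, rep(10, n - 61)), rep(0, n))
  wally <- mk(3, 25, 0, rep(10, n), rep(0, n))
  lazy <- mk(4, 0, 0, rep(0.5, n), rep(0, n))
  traj <- rbind(good, jumpy, wally, lazy)
  log <- data.frame(trial_id = 1:4, kind = "full_field",
                    rotation_dir = "CW", t_motion_onset = 1,
                    n_frames = n)
  tr <- segment_trials(traj, log, arena_radius = 27.5)
  expect_equal(tr$exclusion_reason, c("none", "jump", "wall", "inactive"))
  expect_equal(tr$excluded, c(FALSE, TRUE, TRUE, TRUE))
  # exclusion is monotone: adding a jump frame can only exclude
  good_jump <- good
  good_jump$speed[50] <- 200
  tr2 <- segment_trials(rbind(good_jump, jumpy, wally, lazy), log, 27.5)
  expect_true(tr2$excluded[1])
  # malformed span
  expect_error(segment_trials(traj[-(1:5), ], log, 27.5), "tile")
})

test_that("stimulus alignment flips exactly the negative-sign trials", {
  n <- 10
  traj <- data.frame(trial_id = rep(1:2, each = n),
                     ang_vel = rep(c(-40, 25), each = n))
  trials <- data.frame(trial_id = 1:2, rotation_dir = c("CW", "CCW"),
                       mirrored = FALSE)
  al <- align_to_stimulus(traj, trials)
  expect_equal(unique(al$traj$ang_vel_aligned[al$traj$trial_id == 1]), 40)
  expect_equal(unique(al$traj$ang_vel_aligned[al$traj$trial_id == 2]), 25)
  expect_equal(al$trials$mirrored, c(TRUE, FALSE))
  # involution on the raw negation and pointwise |ang_vel| preservation
  expect_identical(abs(al$traj$ang_vel_aligned), abs(traj$ang_vel))
  al2 <- align_to_stimulus(al$traj, al$trials)
  expect_identical(al2$traj$ang_vel_aligned, al$traj$ang_vel_aligned)
})

test_that("mirroring preserves the downstream saccade count", {
  fs <- 60
  x <- planted_trace(600, 201, 0.12, 500, fs) +
    planted_trace(600, 401, 0.1, -400, fs)
  expect_equal(nrow(detect_saccades(x, fs)), nrow(detect_saccades(-x, fs)))
})
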