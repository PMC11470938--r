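test_that("walker ground-truth decomposition is conserved exactly", {
  p <- walker_params(seed = 3, spont_saccade_rate = 0.3)
  cond <- stimulus_condition("full_field", "CW")
  sim <- simulate_walker(p, cond, n_trials = 4)
  tj <- sim$trajectory
  expect_identical(tj$smooth_true + tj$sacc_true, tj$ang_vel_true)
  # events non-overlapping within trials
  for (id in unique(sim$events$trial_id)) {
    ev <- sim$events[sim$events$trial_id == id, ]
    ev <- ev[order(ev$onset_frame), ]
    if (nrow(ev) > 1)
      expect_true(all(ev$onset_frame[-1] > ev$offset_frame[-nrow(ev)]))
  }
  # spontaneous saccades before motion onset are labelled
  expect_true(any(sim$events$pre_motion))
})

test_that("walker runs are bit-identical under a fixed seed", {
  p <- walker_params(seed = 11)
  cond <- stimulus_condition("full_field", "CCW")
  s1 <- simulate_walker(p, cond, n_trials = 2)
  s2 <- simulate_walker(p, cond, n_trials = 2)
  expect_identical(s1$trajectory, s2$trajectory)
  expect_identical(s1$events, s2$events)
})

test_that("without any turning source the walker goes straight", {
  p <- walker_params(smooth_turn_noise_sd = 0, smooth_turn_gain = 0,
                     syn_saccade_rate = c(full_field = 0, unilateral_FtB = 0,
                                          unilateral_BtF = 0, static = 0),
                     anti_saccade_rate = c(full_field = 0, unilateral_FtB = 0,
                                           unilateral_BtF = 0, static = 0),
                     speed_sd = 0, start_radius = 0, wall_buffer = 5,
                     seed = 5)
  sim <- simulate_walker(p, stimulus_condition("full_field", "CW"), 1)
  tj <- sim$trajectory
  # the only turning left comes from wall reflections (booked on the
  # smooth channel); at most a few frames over a 10 s trial
  turns <- which(tj$ang_vel_true != 0)
  expect_lte(length(turns), 4)
  expect_identical(tj$ang_vel_true, tj$smooth_true)
  # before the first wall contact the path is a straight line
  upto <- if (length(turns)) turns[1] - 1 else nrow(tj)
  expect_equal(diff(tj$body_angle[2:upto]),
               rep(0, length(diff(tj$body_angle[2:upto]))))
  dx <- diff(tj$x[2:upto]); dy <- diff(tj$y[2:upto])
  expect_lt(sd(atan2(dy, dx)), 1e-10)
})

test_that("linear mode makes the full-field drive the sum of unilateral drives", {
  p <- walker_params(linearity_mode = "linear")
  expect_equal(p$drive[["full_field"]],
               p$drive[["unilateral_FtB"]] + p$drive[["unilateral_BtF"]])
  expect_equal(p$syn_saccade_rate[["full_field"]],
               p$syn_saccade_rate[["unilateral_FtB"]] +
                 p$syn_saccade_rate[["unilateral_BtF"]])
  expect_equal(p$anti_saccade_rate[["full_field"]],
               p$anti_saccade_rate[["unilateral_FtB"]] +
                 p$anti_saccade_rate[["unilateral_BtF"]])
})

test_that("planted walker saccades satisfy the detector's nominal criteria", {
  # independent FFT band-pass oracle on each generated pulse
  p <- walker_params(seed = 21)
  cond <- stimulus_condition("full_field", "CW")
  sim <- simulate_walker(p, cond, n_trials = 6)
  ev <- sim$events
  ev <- ev[!ev$pre_motion, ]
  expect_gt(nrow(ev), 3)
  expect_true(all(abs(ev$peak_deg_s) >= 300))
  widths <- (ev$offset_frame - ev$onset_frame + 1) / p$fs * 1000
  expect_true(all(widths >= 70 & widths <= 220))
  det <- do.call(rbind, lapply(unique(ev$trial_id), function(id) {
    tj <- sim$trajectory[sim$trajectory$trial_id == id, ]
    d <- detect_saccades(tj$ang_vel_true, p$fs, method = "fft")
    if (nrow(d)) cbind(trial = id, d) else NULL
  }))
  # every planted motion-period event is found by the oracle route
  truth <- data.frame(trial = ev$trial_id, onset_frame = ev$onset_frame,
                      offset_frame = ev$offset_frame,
                      half_peak_onset_frame = ev$onset_frame)
  hits <- 0
  for (k in seq_len(nrow(truth))) {
    hits <- hits + any(det$trial == truth$trial[k] &
                       det$peak_frame >= truth$onset_frame[k] - 3 &
                       det$peak_frame <= truth$offset_frame[k] + 3)
  }
  expect_gte(hits / nrow(truth), 0.9)
})

test_that("silhouette rendering is deterministic with wings trailing", {
  ip <- image_params(width = 256L, height = 256L)
  f1 <- render_silhouette(128, 128, 0, ip)
  f2 <- render_silhouette(128, 128, 0, ip)
  expect_identical(f1, f2)
  # wing pixels (intermediate intensity) lie at negative x of the body centre
  wing_px <- which(f1 == ip$wing, arr.ind = TRUE)
  body_px <- which(f1 == ip$body, arr.ind = TRUE)
  expect_lt(mean(wing_px[, 2]), mean(body_px[, 2]))
  expect_error(render_silhouette(4, 128, 0, ip), "outside")
})

test_that("rendered major axis tracks the pose heading mod 180", {
  ip <- image_params(width = 256L, height = 256L)
  for (h in seq(0, 350, by = 35)) {
    fr <- render_silhouette(128, 128, h, ip)
    p <- fit_pose(fr, 0.3)
    expect_lt(ang_dist(p$body_axis_angle, h, 180), 2)
  }
})

test_that("scan responses reflect the planted field through dot products", {
  pr <- scan_protocol(azimuths = seq(-20, 20, 10),
                      elevations = seq(-10, 10, 10))
  # uniform field pointing +azimuth
  rf <- planted_rf(azimuths = seq(-20, 20, 10),
                   elevations = seq(-10, 10, 10))
  rf$vx <- 3; rf$vy <- 0
  sim <- simulate_scan_responses(rf, pr, noise_sd = 0, seed = 1)
  expect_equal(unique(sim$frame_response[pr$direction == "+az"]), 3)
  expect_equal(unique(sim$frame_response[pr$direction == "-az"]), -3)
  expect_equal(unique(abs(sim$frame_response[pr$direction %in%
                                             c("+el", "-el")])), 0)
  # zero field -> pure noise with mean ~ 0
  rf0 <- rf; rf0$vx <- 0
  simn <- simulate_scan_responses(rf0, pr, noise_sd = 1, seed = 2)
  expect_lt(abs(mean(simn$frame_response)), 3 / sqrt(nrow(pr)) * 3)
  # seeded reproducibility
  s1 <- simulate_scan_responses(rf, pr, noise_sd = 0.5, seed = 9)
  s2 <- simulate_scan_responses(rf, pr, noise_sd = 0.5, seed = 9)
  expect_identical(s1$v, s2$v)
})

test_that("baseline simulator respects spectral contracts", {
  fs <- 500
  v <- simulate_baseline(4, fs, data.frame(freq_hz = 20, amp_mv = 1))
  pb <- power_bands(v, fs)
  expect_gt(pb$mid_fraction, 0.99)
  expect_equal(simulate_baseline(2, fs), rep(0, 1000))
  # doubling the amplitude quadruples total power
  v2 <- simulate_baseline(4, fs, data.frame(freq_hz = 20, amp_mv = 2))
  expect_equal(sum(v2^2) / sum(v^2), 4, tolerance = 1e-9)
  expect_error(simulate_baseline(1, 100, data.frame(freq_hz = 60,
                                                    amp_mv = 1)),
               "Nyquist|alias")
})
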