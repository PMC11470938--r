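test_that("single planted pulses are detected with accurate geometry", {
  fs <- 60
  x <- planted_trace(600, 201, 0.12, 500, fs)
  ev <- detect_saccades(x, fs)
  expect_equal(nrow(ev), 1)
  true_peak <- 201 + which.max(hann_pulse(0.12, 500, fs)) - 1
  expect_lte(abs(ev$peak_frame - true_peak), 2)
  expect_equal(ev$peak_speed, max(x), tolerance = 1e-9)
  expect_gt(ev$width_ms, 50)
  expect_lt(ev$width_ms, 250)
  # 400 ms pulse: too slow for the band, rejected
  expect_equal(nrow(detect_saccades(planted_trace(600, 201, 0.4, 500, fs),
                                    fs)), 0)
  # constant angular velocity carries no band energy
  expect_equal(nrow(detect_saccades(rep(150, 600), fs)), 0)
  # sub-threshold peak
  expect_equal(nrow(detect_saccades(planted_trace(600, 201, 0.12, 150, fs),
                                    fs)), 0)
})

test_that("detection is sign-equivariant", {
  fs <- 60
  x <- planted_trace(600, 101, 0.1, 450, fs) +
    planted_trace(600, 301, 0.15, -350, fs)
  a <- detect_saccades(x, fs)
  b <- detect_saccades(-x, fs)
  expect_equal(nrow(a), 2)
  expect_equal(a$onset, b$onset)
  expect_equal(a$displacement, -b$displacement)
  expect_equal(a$sign, -b$sign)
})

test_that("close pulses separated by at least 300 ms stay distinct", {
  fs <- 60
  x <- planted_trace(600, 200, 0.1, 400, fs) +
    planted_trace(600, 200 + round(0.1 * fs) + round(0.3 * fs), 0.1, 400, fs)
  ev <- detect_saccades(x, fs)
  expect_equal(nrow(ev), 2)
  expect_true(all(ev$onset[-1] > ev$offset[-nrow(ev)]))
})

test_that("classification is by aligned displacement sign with pre-motion flag", {
  ev <- data.frame(onset = c(10, 100, 200), offset = c(15, 106, 206),
                   peak_frame = c(12, 103, 203),
                   displacement = c(35, -20, 0))
  cl <- classify_saccades(ev, motion_onset_frame = 50)
  expect_equal(cl$klass, c("syn", "anti", "syn"))
  expect_equal(cl$pre_motion, c(TRUE, FALSE, FALSE))
})

test_that("turning decomposition is exact and integrates by hand", {
  fs <- 60
  x <- rnorm(300, sd = 30)
  ev <- detect_saccades(planted_trace(300, 100, 0.12, 500, fs) + x, fs)
  v <- planted_trace(300, 100, 0.12, 500, fs) + x
  dec <- decompose_turning(v, ev, fs)
  expect_identical(dec$smooth + dec$saccadic, v)
  # no events: saccadic channel is zero
  dec0 <- decompose_turning(v, detect_saccades(rep(0, 300), fs), fs)
  expect_identical(dec0$saccadic, rep(0, 300))
  expect_identical(dec0$smooth, v)
  # hand integration: event over frames 100..107 at constant 300 deg/s
  v2 <- numeric(300); v2[100:107] <- 300
  ev2 <- data.frame(onset = 100L, offset = 107L, peak_frame = 103L,
                    displacement = 300 * 7 / fs)
  dec2 <- decompose_turning(v2, ev2, fs)
  # channel trapezoids sum exactly to the total cumulative displacement
  expect_equal(dec2$disp_smooth + dec2$disp_syn + dec2$disp_anti,
               .trapz_ref(v2) / fs)
  # interior of the event: 7 intervals x 300 / fs, plus the two edge ramps
  expect_equal(dec2$disp_syn, (300 * 7 + 300) / fs)
  # overlapping events refuse
  bad <- data.frame(onset = c(10, 12), offset = c(14, 20),
                    peak_frame = c(11, 15), displacement = c(1, 1))
  expect_error(decompose_turning(v2, bad, fs), "overlap")
})


test_that("per-fly summaries aggregate displacement by class", {
  events <- data.frame(fly_id = 1, trial_id = c(1, 1, 2),
                       klass = c("syn", "syn", "anti"),
                       displacement = c(30, 10, -25),
                       peak_speed = c(400, 350, 380),
                       pre_motion = FALSE)
  trials <- data.frame(fly_id = 1, trial_id = 1:2, kind = "full_field",
                       excluded = FALSE, motion_s = 5)
  s <- saccade_summary(events, trials)
  expect_equal(s$n_syn, 2)
  expect_equal(s$n_anti, 1)
  expect_equal(s$cum_syn, mean(c(40, 0)))
  expect_equal(s$cum_anti, mean(c(0, -25)))
  expect_equal(s$rate_syn, 2 / 10)
  # empty events
  s0 <- saccade_summary(events[0, ], trials)
  expect_equal(s0$n_syn + s0$n_anti, 0)
  expect_equal(s0$cum_syn, 0)
})

test_that("detector recovers planted event rates on simulated walkers", {
  p <- walker_params(seed = 31)
  cond <- stimulus_condition("full_field", "CW")
  sim <- simulate_walker(p, cond, n_trials = 40)
  an <- analyse_walker_trials(sim, p, cond, detect = TRUE)
  truth_n <- sum(!sim$events$pre_motion &
                 sim$events$trial_id %in%
                   an$trials$trial_id[!an$trials$excluded])
  det_n <- sum(!an$events$pre_motion)
  expect_lt(abs(det_n - truth_n) / truth_n, 0.15)
})

test_that("SWT detection agrees with the FFT oracle on benchmark traces", {
  bm <- simulate_saccade_benchmark(n_trials = 12, seed = 5)
  cs <- vapply(bm$traces,
               function(x) nrow(detect_saccades(x, 60, method = "swt")),
               numeric(1))
  cf <- vapply(bm$traces,
               function(x) nrow(detect_saccades(x, 60, method = "fft")),
               numeric(1))
  expect_gte(mean(cs == cf), 0.95)
})
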