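test_that("rolling-baseline subtraction removes slow structure only", {
  fs <- 100
  expect_equal(rolling_baseline_subtract(rep(-50, 100 * fs), fs),
               rep(0, 100 * fs), ignore_attr = TRUE)
  # slow linear drift: interior residual near zero
  v <- seq(0, 2, length.out = 100 * fs)   # 1.2 mV/min
  r <- rolling_baseline_subtract(v, fs)
  core <- (40 * fs):(60 * fs)
  expect_lt(max(abs(r[core])), 1e-9)
  # a 20 Hz tone is untouched (window >> period)
  t <- (seq_len(90 * fs) - 1) / fs
  tone <- sin(2 * pi * 20 * t)
  rt <- rolling_baseline_subtract(tone, fs)
  expect_lt(max(abs(rt - tone)[(35 * fs):(55 * fs)]), 1e-3)
  # short record: global mean, flagged
  s <- rolling_baseline_subtract(c(1, 2, 3), fs)
  expect_true(attr(s, "global_mean_used"))
  expect_equal(as.numeric(s), c(-1, 0, 1))
})

test_that("binned responses average within stimulus frames", {
  fs <- 10000
  v <- rep(2, 5000)
  b <- bin_responses(v, fs, seq(0, 0.4, by = 1 / 60))
  expect_true(all(abs(b[!is.na(b)] - 2) < 1e-12))
  # each 16.6 ms bin holds ~166 samples of a 10 kHz record
  expect_equal(round(1 / 60 * fs), 167)
  expect_error(bin_responses(v, fs, c(0.2, 0.1)), "increasing")
  # step at a bin boundary: bins take pre/post values exactly
  ft <- c(0, 0.1)
  v2 <- c(rep(1, 1000), rep(5, 1000))
  b2 <- bin_responses(v2, fs, ft, bin_s = 0.1)
  expect_equal(as.numeric(b2), c(1, 5))
})

test_that("noiseless reconstruction equals twice the planted field", {
  pr <- scan_protocol(azimuths = seq(-30, 30, 10),
                      elevations = seq(-20, 20, 10))
  rf <- planted_rf(azimuths = seq(-30, 30, 10),
                   elevations = seq(-20, 20, 10), centre = c(10, 0),
                   contra_share = 0.25)
  sim <- simulate_scan_responses(rf, pr, noise_sd = 0, seed = 1)
  rec <- reconstruct_rf(bin_responses(sim$v, sim$fs, sim$frame_times), pr)
  m <- match(paste(rec$azimuth, rec$elevation),
             paste(rf$azimuth, rf$elevation))
  scale <- max(sqrt(rf$vx^2 + rf$vy^2))
  expect_lt(max(abs(rec$vx - 2 * rf$vx[m])) / scale, 1e-9)
  expect_lt(max(abs(rec$vy - 2 * rf$vy[m])) / scale, 1e-9)
  # zero responses give a zero field
  rec0 <- reconstruct_rf(rep(0, nrow(pr)), pr)
  expect_true(all(rec0$length == 0))
  # reconstruction is linear in the responses
  b1 <- bin_responses(sim$v, sim$fs, sim$frame_times)
  rec3 <- reconstruct_rf(3 * b1, pr)
  expect_equal(rec3$vx, 3 * rec$vx, tolerance = 1e-12)
  # a missing direction is an error
  bad <- pr[pr$direction != "-el", ]
  expect_error(reconstruct_rf(rep(0, nrow(bad)), bad), "direction")
})

test_that("field metrics report areas and hemifield shares", {
  g <- expand.grid(azimuth = seq(-20, 20, 10), elevation = seq(-10, 10, 10))
  uni <- data.frame(g, vx = 1, vy = 0)
  m <- rf_metrics(uni)
  total_area <- sum(cos(uni$elevation * pi / 180) * 100)
  expect_equal(unname(m$areas["area_30pct"]), total_area)
  # field confined to the ipsilateral side: contralateral share 0
  ipsi_only <- uni
  ipsi_only$vx[ipsi_only$azimuth <= 0] <- 0
  mi <- rf_metrics(ipsi_only)
  expect_equal(mi$share_sum_abs, 0)
  expect_equal(mi$contra_ipsi_ratio, 0)
  expect_error(rf_metrics(data.frame(g, vx = 0, vy = 0)), "zero")
})

test_that("planted contralateral mass is recovered within two points", {
  pr <- scan_protocol()
  rf <- planted_rf(contra_share = 0.25)
  sim <- simulate_scan_responses(rf, pr, noise_sd = 0, seed = 3)
  rec <- reconstruct_rf(bin_responses(sim$v, sim$fs, sim$frame_times), pr)
  expect_lt(abs(rf_metrics(rec)$share_sum_abs - 25), 2)
})

test_that("power bands separate slow and fast oscillations", {
  fs <- 1000
  t <- (seq_len(10 * fs) - 1) / fs
  p20 <- power_bands(sin(2 * pi * 20 * t), fs)
  expect_gte(p20$mid_fraction, 0.99)
  p5 <- power_bands(sin(2 * pi * 5 * t), fs)
  expect_gte(p5$low_fraction, 0.99)
  expect_equal(sum(p20$power), 1, tolerance = 1e-9)
  pmix <- power_bands(sin(2 * pi * 5 * t) + sin(2 * pi * 20 * t), fs)
  expect_equal(pmix$low_fraction, 0.5, tolerance = 1e-6)
  expect_equal(pmix$mid_fraction, 0.5, tolerance = 1e-6)
  expect_error(power_bands(rnorm(100), fs), "1 s")
  # repetition averaging keeps unit normalisation
  reps <- list(sin(2 * pi * 20 * t), sin(2 * pi * 20 * t) + rnorm(10 * fs))
  expect_equal(sum(power_bands(reps, fs)$power), 1, tolerance = 1e-9)
})

test_that("flash transients measure peak deviation from baseline", {
  fs <- 1000
  v <- numeric(3 * fs)
  v[(1 * fs + 1):(3 * fs)] <- 5          # +5 mV step at t = 1 s
  ev <- data.frame(time = 1, class = "ON")
  r <- flash_response(v, fs, ev)
  expect_equal(r$mean_amplitude_mv, 5)
  expect_equal(flash_response(numeric(2 * fs), fs,
                              data.frame(time = 1, class = "OFF"))
               $mean_amplitude_mv, 0)
  # decaying exponential peaking 8 mV shortly after onset
  t <- (seq_len(fs) - 1) / fs
  v2 <- c(numeric(fs), 8 * exp(-(t) / 0.08) * (t >= 0))
  r2 <- flash_response(v2, fs, data.frame(time = 1, class = "ON"))
  expect_equal(r2$mean_amplitude_mv, 8, tolerance = 1e-6)
})

test_that("grating tuning subtracts the static baseline and normalises", {
  fs <- 1000
  # 2 s static at -2 mV then 2 s motion at +6 mV
  v <- c(rep(-2, 2 * fs), rep(6, 2 * fs), rep(0, fs))
  tr <- data.frame(t_static_on = 0, t_motion_on = 2, t_motion_off = 4,
                   direction = 0)
  tc <- tuning_curves(v, fs, tr)
  expect_equal(tc$response_mv, 8)
  # equal responses in all directions -> normalised curve of ones
  dirs <- seq(0, 315, by = 45)
  n_per <- 2 * fs
  v8 <- rep(c(rep(0, fs), rep(4, fs)), times = 8)
  tr8 <- data.frame(t_static_on = (0:7) * 2, t_motion_on = (0:7) * 2 + 1,
                    t_motion_off = (0:7) * 2 + 2, direction = dirs)
  tc8 <- tuning_curves(v8, fs, tr8)
  expect_equal(tc8$normalised, rep(1, 8))
  # cosine-tuned synthetic cell: preferred direction recovered
  amp <- 3 + 3 * cos((dirs - 90) * pi / 180)
  vc <- unlist(lapply(amp, function(a) c(rep(0, fs), rep(a, fs))))
  tcc <- tuning_curves(vc, fs, tr8)
  expect_equal(tcc$direction[which.max(tcc$response_mv)], 90)
  expect_error(tuning_curves(v, fs, data.frame(t_static_on = 2,
                                               t_motion_on = 1,
                                               t_motion_off = 4,
                                               direction = 0)),
               "static")
})
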