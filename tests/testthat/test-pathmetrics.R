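test_that("bout segmentation applies the duration and speed rules", {
  fs <- 60
  n <- 240
  traj <- data.frame(x = cumsum(rep(10 / fs, n)), y = 0,
                     speed = rep(10, n))
  # two saccades one second apart -> one qualifying bout between them
  ev <- data.frame(onset = c(60L, 121L), offset = c(66L, 127L))
  b <- segment_bouts(traj, ev, fs)
  mid <- b[b$start > 66 & b$end < 121, ]
  expect_equal(nrow(mid), 1)
  expect_gt(mid$duration_s, 1 / 3)
  # a 200 ms inter-saccade gap is rejected
  ev2 <- data.frame(onset = c(60L, 79L), offset = c(66L, 85L))
  b2 <- segment_bouts(traj[1:120, ], ev2, fs)
  expect_equal(nrow(b2[b2$start > 66 & b2$end < 79, ]), 0)
  # slow interval is rejected
  slow <- traj
  slow$speed[67:120] <- 3
  b3 <- segment_bouts(slow, ev, fs)
  expect_equal(nrow(b3[b3$start > 66 & b3$end < 121, ]), 0)
})

test_that("circular-arc straightness matches the closed-form geometry", {
  # R = 5 mm, speed 6 mm/s at 60 Hz -> window arc length exactly 2 mm
  fs <- 60
  R <- 5; v <- 6
  p <- circle_path(R, v, fs, 400)
  s <- straightness(p$x, p$y, fs)
  L <- 2
  chord_true <- 2 * R * sin(L / (2 * R))
  sagitta_true <- R * (1 - cos(L / (2 * R)))
  expect_equal(mean(s$per_point$chord_mm), chord_true, tolerance = 1e-6)
  expect_equal(mean(s$per_point$deviation_mm), sagitta_true,
               tolerance = 1e-6)
  expect_equal(s$straightness,
               sum(s$per_point$chord_mm) /
                 (sum(s$per_point$deviation_mm) + 0.01))
})

test_that("straight paths return the finite eps-floored sentinel", {
  fs <- 60
  x <- seq(0, 10, length.out = 300); y <- rep(2, 300)
  s <- straightness(x, y, fs)
  expect_true(s$straight)
  expect_equal(s$straightness, sum(s$per_point$chord_mm) / 0.01)
  expect_true(is.finite(s$straightness))
})

test_that("straightness is invariant to rigid motion and time reversal", {
  fs <- 60
  set.seed(2)
  p <- circle_path(4, 7, fs, 300)
  x <- p$x + cumsum(rnorm(300, sd = 0.01))
  y <- p$y + cumsum(rnorm(300, sd = 0.01))
  s0 <- straightness(x, y, fs)$straightness
  th <- 0.7
  xr <- cos(th) * x - sin(th) * y + 12
  yr <- sin(th) * x + cos(th) * y - 3
  expect_equal(straightness(xr, yr, fs)$straightness, s0,
               tolerance = 1e-10)
  expect_equal(straightness(rev(x), rev(y), fs)$straightness, s0,
               tolerance = 1e-10)
})

test_that("straightness increases with circle radius at fixed window", {
  fs <- 60
  vals <- vapply(c(3, 5, 8, 14), function(R) {
    p <- circle_path(R, 6, fs, 400)
    straightness(p$x, p$y, fs)$straightness
  }, numeric(1))
  expect_true(all(diff(vals) > 0))
  # small-angle limit: per-window ratio ~ 8R/L, so halving R halves it
  r5 <- straightness(circle_path(5, 6, fs, 400)$x,
                     circle_path(5, 6, fs, 400)$y, fs)
  r10 <- straightness(circle_path(10, 6, fs, 400)$x,
                      circle_path(10, 6, fs, 400)$y, fs)
  ratio5 <- mean(r5$per_point$chord_mm / r5$per_point$deviation_mm)
  ratio10 <- mean(r10$per_point$chord_mm / r10$per_point$deviation_mm)
  expect_equal(ratio10 / ratio5, 2, tolerance = 0.02)
})

test_that("bouts shorter than the window yield no straightness value", {
  fs <- 60
  s <- straightness(1:10, rep(0, 10), fs)
  expect_true(is.na(s$straightness))
})
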