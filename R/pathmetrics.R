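#' Segment forward-walking bouts
#'
#' Forward-walking bouts are the periods between consecutive saccades that
#' last longer than 333 ms (20 frames at 60 Hz) and have mean speed above
#' 5 mm/s. Trial edges delimit the first and last bout.
#'
#' @param traj one trial's trajectory data.frame with columns `x`, `y`,
#'   `speed` (mm/s); frames in order.
#' @param events saccade event table for that trial ([detect_saccades()]
#'   output); bouts are cut at event onsets/offsets.
#' @param fs sampling rate, Hz.
#' @param min_duration_s minimum bout duration (default 1/3 s).
#' @param min_speed minimum mean speed, mm/s (default 5).
#' @return data.frame of bouts: `start`, `end` (frame indices), `duration_s`,
#'   `mean_speed`.
#' @export
segment_bouts <- function(traj, events, fs, min_duration_s = 1 / 3,
                          min_speed = 5) {
  n <- nrow(traj)
  if (n == 0) return(data.frame(start = integer(0), end = integer(0),
                                duration_s = numeric(0),
                                mean_speed = numeric(0)))
  # bout boundaries: trial edges and saccade windows
  cuts <- rbind(data.frame(lo = 0L, hi = 0L),
                if (nrow(events))
                  data.frame(lo = events$onset, hi = events$offset)
                else NULL,
                data.frame(lo = n + 1L, hi = n + 1L))
  cuts <- cuts[order(cuts$lo), , drop = FALSE]
  out <- list()
  for (k in seq_len(nrow(cuts) - 1L)) {
    s <- cuts$hi[k] + 1L
    e <- cuts$lo[k + 1L] - 1L
    if (e <= s) next
    dur <- (e - s + 1L) / fs
    msp <- mean(traj$speed[s:e], na.rm = TRUE)
    if (dur > min_duration_s && msp > min_speed)
      out[[length(out) + 1L]] <- data.frame(start = s, end = e,
                                            duration_s = dur,
                                            mean_speed = msp)
  }
  if (!length(out)) return(data.frame(start = integer(0), end = integer(0),
                                      duration_s = numeric(0),
                                      mean_speed = numeric(0)))
  do.call(rbind, out)
}

#' Windowed path straightness of a walking bout
#'
#' For each interior point of a bout a window (default 333 ms) is centred on
#' it; the chord is the distance between the window endpoints and the
#' deviation is the perpendicular distance from the chord to the trajectory
#' point at the window's temporal centre. Bout straightness is
#' `sum(chord) / (sum(deviation) + eps)`; the `eps` floor (per the whole
#' bout) makes exactly straight paths return a finite value, flagged
#' `straight = TRUE`.
#'
#' For a circular arc of radius R traversed at constant speed with window arc
#' length L, every chord is `2R*sin(L/2R)` and every deviation is the sagitta
#' `R*(1 - cos(L/2R))`; these closed forms anchor the tests.
#'
#' @param x,y positions, mm.
#' @param fs sampling rate, Hz.
#' @param window_s window length, s (default 1/3; must correspond to an even
#'   number of frames, default 20 at 60 Hz).
#' @param eps denominator floor, mm (default 0.01).
#' @return list with `per_point` (data.frame: index, chord_mm, deviation_mm),
#'   `straightness` (scalar), `straight` (logical: all deviations zero),
#'   `mean_chord_mm`, `mean_deviation_mm`.
#' @export
straightness <- function(x, y, fs, window_s = 1 / 3, eps = 0.01) {
  n <- length(x)
  w <- round(window_s * fs)
  h <- w %/% 2L
  if (n < w + 1L)
    return(list(per_point = data.frame(index = integer(0),
                                       chord_mm = numeric(0),
                                       deviation_mm = numeric(0)),
                straightness = NA_real_, straight = NA,
                mean_chord_mm = NA_real_, mean_deviation_mm = NA_real_))
  idx <- (h + 1L):(n - h)
  x0 <- x[idx - h]; y0 <- y[idx - h]     # window start
  x1 <- x[idx + h]; y1 <- y[idx + h]     # window end
  xm <- x[idx]; ym <- y[idx]             # temporal-centre sample
  chord <- sqrt((x1 - x0)^2 + (y1 - y0)^2)
  # perpendicular distance from the midpoint to the chord line
  dev <- ifelse(chord > 0,
                abs((x1 - x0) * (y0 - ym) - (x0 - xm) * (y1 - y0)) / chord,
                sqrt((xm - x0)^2 + (ym - y0)^2))
  total_dev <- sum(dev)
  list(per_point = data.frame(index = idx, chord_mm = chord,
                              deviation_mm = dev),
       straightness = sum(chord) / (total_dev + eps),
       straight = total_dev == 0,
       mean_chord_mm = mean(chord), mean_deviation_mm = mean(dev))
}

#' Straightness table over bouts
#'
#' Applies [straightness()] to each bout of a trial and returns one row per
#' bout, the unit at which the statistic is usually aggregated (per-trial and
#' per-fly aggregation are simple means of this table).
#'
#' @param traj one trial's trajectory (columns `x`, `y`, `speed`).
#' @param events saccade events for the trial.
#' @param fs sampling rate, Hz.
#' @inheritParams straightness
#' @return data.frame: bout columns plus `straightness`, `straight`.
#' @export
bout_straightness <- function(traj, events, fs, window_s = 1 / 3,
                              eps = 0.01) {
  bouts <- segment_bouts(traj, events, fs)
  if (!nrow(bouts)) {
    bouts$straightness <- numeric(0)
    bouts$straight <- logical(0)
    return(bouts)
  }
  res <- lapply(seq_len(nrow(bouts)), function(k) {
    s <- straightness(traj$x[bouts$start[k]:bouts$end[k]],
                      traj$y[bouts$start[k]:bouts$end[k]],
                      fs, window_s, eps)
    c(straightness = s$straightness, straight = s$straight)
  })
  res <- do.call(rbind, res)
  bouts$straightness <- res[, "straightness"]
  bouts$straight <- as.logical(res[, "straight"])
  bouts
}
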