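#' Unwrap heading angles
#'
#' Resolves +/-180 degree jumps so the heading is continuous before
#' differencing.
#'
#' @param angle_deg heading in degrees (possibly wrapped to `[0, 360)`).
#' @return continuous angle series, degrees.
#' @export
unwrap_angle <- function(angle_deg) {
  if (length(angle_deg) < 2) return(angle_deg)
  d <- diff(angle_deg)
  d <- ((d + 180) %% 360) - 180
  angle_deg[1] + c(0, cumsum(d))
}

#' Rolling median followed by rolling mean
#'
#' The standard pose-denoising step: a centred rolling median (kills
#' single-frame tracking spikes) followed by a centred rolling average, both
#' with the same window (default 3 frames, ~50 ms at 60 Hz). Edges use
#' symmetric shrinking windows, so a window-3 smooth leaves the first and last
#' sample untouched by each stage. `NA` samples are ignored within windows and
#' stay `NA` in the output.
#'
#' @param x numeric series.
#' @param window odd window length in frames, >= 1.
#' @return smoothed series, same length.
#' @export
smooth_series <- function(x, window = 3L) {
  window <- as.integer(window)
  stopifnot(window >= 1L, window %% 2L == 1L)
  if (window == 1L || length(x) < 2) return(x)
  if (window == 3L && !anyNA(x) && length(x) >= 3) {
    # vectorised fast path: median-of-3 then mean-of-3, edges untouched
    n <- length(x)
    l <- x[1:(n - 2)]; c0 <- x[2:(n - 1)]; r <- x[3:n]
    med <- pmin(pmax(l, c0), pmax(pmin(l, c0), r))
    x1 <- c(x[1], med, x[n])
    l <- x1[1:(n - 2)]; c0 <- x1[2:(n - 1)]; r <- x1[3:n]
    return(c(x1[1], (l + c0 + r) / 3, x1[n]))
  }
  x1 <- .centered_roll(x, window, stats::median)
  .centered_roll(x1, window, mean)
}

.centered_roll <- function(x, window, fun) {
  n <- length(x)
  h <- (window - 1L) %/% 2L
  out <- x
  na_in <- is.na(x)
  for (i in seq_len(n)) {
    if (na_in[i]) next
    hw <- min(h, i - 1L, n - i)
    w <- x[(i - hw):(i + hw)]
    out[i] <- fun(w[!is.na(w)])
  }
  out
}

#' Derive speed and angular velocity from a pose series
#'
#' Speed is the framewise positional step times `fs`; angular velocity the
#' framewise change of the unwrapped heading times `fs`. Both are then passed
#' through [smooth_series()]. The first frame carries no step and is assigned
#' 0. Frames flagged invalid upstream propagate `valid = FALSE`.
#'
#' @param pose data.frame with columns `x`, `y` (mm), `heading` (deg) and
#'   optionally `valid`; one trial's frames in order.
#' @param fs sampling rate, Hz.
#' @param smoothing_window window for [smooth_series()] (default 3; use 1 to
#'   skip smoothing).
#' @return data.frame `pose` with added columns `heading_unwrapped`, `speed`
#'   (mm/s), `ang_vel` (deg/s, CCW-positive) and `valid`.
#' @export
derive_kinematics <- function(pose, fs, smoothing_window = 3L) {
  stopifnot(all(c("x", "y", "heading") %in% names(pose)))
  n <- nrow(pose)
  hu <- unwrap_angle(pose$heading)
  speed <- c(0, sqrt(diff(pose$x)^2 + diff(pose$y)^2) * fs)
  ang_vel <- c(0, diff(hu) * fs)
  valid <- if ("valid" %in% names(pose)) pose$valid else rep(TRUE, n)
  speed[!valid] <- NA_real_
  ang_vel[!valid] <- NA_real_
  pose$heading_unwrapped <- hu
  pose$speed <- smooth_series(speed, smoothing_window)
  pose$ang_vel <- smooth_series(ang_vel, smoothing_window)
  pose$valid <- valid & !is.na(pose$speed) & !is.na(pose$ang_vel)
  pose
}

#' Flag jump frames
#'
#' A frame is a jump when smoothed speed exceeds 100 mm/s or smoothed angular
#' speed exceeds 1000 deg/s.
#'
#' @param speed mm/s series.
#' @param ang_vel deg/s series.
#' @param speed_thresh,ang_vel_thresh thresholds (defaults 100 mm/s,
#'   1000 deg/s).
#' @return logical mask, `TRUE` on jump frames (`NA` treated as no jump).
#' @export
flag_jumps <- function(speed, ang_vel, speed_thresh = 100,
                       ang_vel_thresh = 1000) {
  j <- (speed > speed_thresh) | (abs(ang_vel) > ang_vel_thresh)
  j[is.na(j)] <- FALSE
  j
}

#' Cut a trajectory into trials and apply exclusion rules
#'
#' Trials are cut at the logged boundaries and excluded when they contain any
#' jump frame, any frame within `wall_margin` of the arena wall, or when the
#' fly was inactive (mean speed below `inactivity_speed`) throughout the whole
#' trial. A single reason is recorded with priority jump > wall > inactive.
#'
#' @param traj data.frame with columns `trial_id`, `x`, `y`, `speed`,
#'   `ang_vel` (one or more trials; [derive_kinematics()] output).
#' @param trial_log data.frame with `trial_id`, `kind`, `rotation_dir`,
#'   `t_motion_onset`, `n_frames`.
#' @param arena_radius mm.
#' @param wall_margin mm (default 5).
#' @param inactivity_speed mm/s (default 1).
#' @return `trial_log` with added columns `excluded`, `exclusion_reason`
#'   (`"jump"`, `"wall"`, `"inactive"`, or `"none"`) and `mirrored = FALSE`.
#' @export
segment_trials <- function(traj, trial_log, arena_radius, wall_margin = 5,
                           inactivity_speed = 1) {
  stopifnot(!anyDuplicated(trial_log$trial_id))
  ids <- trial_log$trial_id
  counts <- table(traj$trial_id)
  if (any(trial_log$n_frames != as.integer(counts[as.character(ids)])))
    stop("trial spans do not tile the trajectory (overlap or gap)")
  spl <- split(seq_len(nrow(traj)), traj$trial_id)
  reason <- vapply(as.character(ids), function(id) {
    i <- spl[[id]]
    .trial_excl_reason(traj$speed[i], traj$ang_vel[i], traj$x[i], traj$y[i],
                       arena_radius, wall_margin, inactivity_speed)
  }, character(1))
  excluded <- reason != "none"
  trial_log$excluded <- excluded
  trial_log$exclusion_reason <- reason
  trial_log$mirrored <- FALSE
  trial_log
}

# single-trial exclusion core shared by segment_trials() and the fast
# per-trial analysis path; priority jump > wall > inactive
.trial_excl_reason <- function(speed, ang_vel, x, y, arena_radius,
                               wall_margin = 5, inactivity_speed = 1) {
  if (any(flag_jumps(speed, ang_vel))) return("jump")
  if (any(x^2 + y^2 > (arena_radius - wall_margin)^2)) return("wall")
  if (mean(speed, na.rm = TRUE) < inactivity_speed) return("inactive")
  "none"
}

#' Align angular velocity to the stimulus direction
#'
#' Pools both rotation directions by mirroring so that positive angular
#' velocity always means turning with the stimulus. Under the package's
#' CCW-positive convention, a CCW stimulus already has syn turning positive,
#' so trials with CW rotation are negated and flagged `mirrored`. Idempotent:
#' already-mirrored trials are left alone.
#'
#' @param traj trajectory data.frame with `trial_id` and `ang_vel`.
#' @param trials trial table from [segment_trials()].
#' @return list with updated `traj` (added/updated column `ang_vel_aligned`)
#'   and `trials` (with `mirrored` set).
#' @export
align_to_stimulus <- function(traj, trials) {
  sgn <- vapply(trials$rotation_dir, stimulus_sign, numeric(1))
  mirror <- sgn < 0
  flip <- ifelse(mirror, -1, 1)[match(traj$trial_id, trials$trial_id)]
  flip[is.na(flip)] <- 1
  traj$ang_vel_aligned <- traj$ang_vel * flip
  trials$mirrored <- mirror
  list(traj = traj, trials = trials)
}
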