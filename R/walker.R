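#' Parameters of the synthetic closed-loop walker
#'
#' The generator emulates a fly walking in a 55 mm arena under closed-loop
#' pinwheel stimulation: body angle evolves as a smooth turning process
#' (condition-dependent drive plus low-pass-filtered noise) with raised-cosine
#' saccade velocity pulses injected at Poisson times; speed is a positive
#' low-pass noise process; the stimulus anchor follows the body angle with a
#' 3-frame delay. Ground truth (the exact smooth/saccadic split and every
#' injected event) is returned alongside the trajectory.
#'
#' Turning drives per condition (deg/s, stimulus-relative so positive = syn):
#' in `"linear"` mode the full-field drive and saccade rates are by
#' construction the sums of the two unilateral ones; in `"nonlinear"` mode the
#' unilateral FtB condition instead evokes anti-saccades with little smooth
#' turning while full-field rotation evokes strong smooth syn turning,
#' mirroring the antagonistic phenomenology seen in real flies.
#'
#' @param fs sampling rate, Hz (default 60).
#' @param arena_radius mm (default 27.5, i.e. the 55 mm arena).
#' @param speed_mean,speed_sd forward speed process, mm/s.
#' @param smooth_turn_gain deg/s of smooth drive per unit stimulus drive.
#' @param smooth_turn_noise_sd deg/s SD of the smooth turning noise after
#'   low-pass filtering at `noise_cutoff_hz`.
#' @param noise_cutoff_hz low-pass cutoff of the smooth noise (< 5 Hz keeps the
#'   background out of the saccade band).
#' @param smooth_turn_max deg/s cap on the smooth channel; trials are rescaled,
#'   never clipped, so the band limit is preserved.
#' @param syn_saccade_rate,anti_saccade_rate events/s during motion, named
#'   vectors over condition kinds (`full_field`, `unilateral_FtB`,
#'   `unilateral_BtF`, `static`).
#' @param spont_saccade_rate events/s of unsigned spontaneous saccades during
#'   the static period.
#' @param saccade_peak_range deg/s range of pulse peaks (uniform draw).
#' @param saccade_duration_range ms range of pulse support (uniform draw).
#' @param drive per-condition smooth drive (stimulus-relative, unit drive;
#'   multiplied by `smooth_turn_gain`).
#' @param linearity_mode `"linear"` or `"nonlinear"` (selects the built-in
#'   drive/rate tables unless you pass your own).
#' @param wall_buffer mm; travel is specularly reflected this far from the
#'   wall (`0` disables reflection so wall exclusions can be exercised).
#' @param start_radius mm; trials start uniformly within this radius.
#' @param delay_frames closed-loop update delay (default 3 frames).
#' @param seed integer RNG seed; every generated quantity is a pure function
#'   of (params, seed).
#' @return list of class `walker_params`.
#' @export
walker_params <- function(fs = 60, arena_radius = 27.5,
                          speed_mean = 10, speed_sd = 2,
                          smooth_turn_gain = 1,
                          smooth_turn_noise_sd = 20, noise_cutoff_hz = 2,
                          smooth_turn_max = 100,
                          syn_saccade_rate = NULL, anti_saccade_rate = NULL,
                          spont_saccade_rate = 0,
                          saccade_peak_range = c(300, 600),
                          saccade_duration_range = c(80, 200),
                          drive = NULL,
                          linearity_mode = c("linear", "nonlinear"),
                          wall_buffer = 5, start_radius = 8,
                          delay_frames = 3L, seed = 1L) {
  linearity_mode <- match.arg(linearity_mode)
  stopifnot(fs > 0, arena_radius > 0,
            all(saccade_duration_range > 0), all(saccade_duration_range <= 500),
            diff(saccade_peak_range) >= 0, diff(saccade_duration_range) >= 0)
  kinds <- c("full_field", "unilateral_FtB", "unilateral_BtF", "static")
  tbl <- function(ff, ftb, btf) stats::setNames(c(ff, ftb, btf, 0), kinds)
  if (linearity_mode == "linear") {
    # full-field values are exactly the sums of the two unilateral ones
    if (is.null(drive)) drive <- tbl(30, 20, 10)
    if (is.null(syn_saccade_rate)) syn_saccade_rate <- tbl(0.8, 0.3, 0.5)
    if (is.null(anti_saccade_rate)) anti_saccade_rate <- tbl(0.4, 0.2, 0.2)
  } else {
    # antagonistic mode: FtB evokes anti-saccades, full-field smooth syn turning
    if (is.null(drive)) drive <- tbl(35, -5, 8)
    if (is.null(syn_saccade_rate)) syn_saccade_rate <- tbl(0.8, 0.1, 0.4)
    if (is.null(anti_saccade_rate)) anti_saccade_rate <- tbl(0.2, 1.2, 0.2)
  }
  stopifnot(all(syn_saccade_rate >= 0), all(anti_saccade_rate >= 0),
            spont_saccade_rate >= 0)
  structure(list(fs = fs, arena_radius = arena_radius, speed_mean = speed_mean,
                 speed_sd = speed_sd, smooth_turn_gain = smooth_turn_gain,
                 smooth_turn_noise_sd = smooth_turn_noise_sd,
                 noise_cutoff_hz = noise_cutoff_hz,
                 smooth_turn_max = smooth_turn_max,
                 syn_saccade_rate = syn_saccade_rate,
                 anti_saccade_rate = anti_saccade_rate,
                 spont_saccade_rate = spont_saccade_rate,
                 saccade_peak_range = saccade_peak_range,
                 saccade_duration_range = saccade_duration_range,
                 drive = drive, linearity_mode = linearity_mode,
                 wall_buffer = wall_buffer, start_radius = start_radius,
                 delay_frames = as.integer(delay_frames),
                 seed = as.integer(seed)),
            class = "walker_params")
}

# raised-cosine (Hann) angular-velocity pulse sampled at fs; support dur_s
.saccade_pulse <- function(dur_s, peak, fs) {
  k <- max(3L, round(dur_s * fs))
  tt <- (seq_len(k) - 0.5) / k
  peak * 0.5 * (1 - cos(2 * pi * tt))
}

# zero-phase low-pass of white noise, rescaled to target sd
.lp_noise <- function(n, sd_target, cutoff_hz, fs) {
  if (sd_target <= 0 || n < 12) return(numeric(n))
  bf <- signal::butter(2, min(0.99, cutoff_hz / (fs / 2)))
  z <- signal::filtfilt(bf, stats::rnorm(n + 2 * 60))
  z <- z[60 + seq_len(n)]
  s <- stats::sd(z)
  if (s == 0) return(numeric(n))
  z * (sd_target / s)
}

#' Simulate closed-loop walking trials with known ground truth
#'
#' See [walker_params()] for the generative model. Each trial covers the
#' condition's static period followed by its motion period at `params$fs`.
#' Angular velocity is decomposed exactly: `smooth + saccadic = total`,
#' framewise, and every injected saccade is logged. Angular velocities are
#' stored in the arena frame (CCW-positive): stimulus-relative drives are
#' multiplied by the condition's rotation sign.
#'
#' @param params a [walker_params()].
#' @param condition a [stimulus_condition()].
#' @param n_trials number of trials.
#' @return list with `trajectory` (data.frame: trial_id, frame, t, x, y,
#'   body_angle, heading, speed_true, ang_vel_true, smooth_true, sacc_true,
#'   stim_anchor), `events` (ground-truth saccade table), and `trial_log`.
#' @export
simulate_walker <- function(params, condition, n_trials = 1L) {
  stopifnot(inherits(params, "walker_params"),
            inherits(condition, "stimulus_condition"), n_trials >= 1)
  fs <- params$fs
  set.seed(params$seed)
  n_static <- round(condition$static_duration * fs)
  n_motion <- round(condition$motion_duration * fs)
  n <- n_static + n_motion
  kind <- condition$kind
  sgn <- stimulus_sign(condition$rotation_dir)
  drive_arena <- params$smooth_turn_gain * params$drive[[kind]] * sgn
  # a rate whose expected refractory-padded occupancy exceeds the window
  # cannot be realised as non-overlapping events
  occ_per_event <- params$saccade_duration_range[2] / 1000 + 0.15
  max_rate <- params$syn_saccade_rate[[kind]] + params$anti_saccade_rate[[kind]]
  if (max_rate * occ_per_event > 1)
    stop("saccade rate too high: no non-overlapping placement exists")
  traj <- vector("list", n_trials)
  evs <- vector("list", n_trials)
  logs <- vector("list", n_trials)
  for (tr in seq_len(n_trials)) {
    smooth <- .lp_noise(n, params$smooth_turn_noise_sd, params$noise_cutoff_hz, fs)
    smooth[(n_static + 1):n] <- smooth[(n_static + 1):n] + drive_arena
    # keep the smooth channel band-limited: rescale (not clip) over-range trials
    mx <- max(abs(smooth))
    if (mx > params$smooth_turn_max) smooth <- smooth * (params$smooth_turn_max / mx)
    # saccade times: signed classes during motion, unsigned spontaneous before
    t_mot <- n_static / fs
    t_end <- n / fs
    dur_draw <- function(k) stats::runif(k, params$saccade_duration_range[1],
                                         params$saccade_duration_range[2]) / 1000
    peak_draw <- function(k) stats::runif(k, params$saccade_peak_range[1],
                                          params$saccade_peak_range[2])
    ev <- data.frame(onset_s = numeric(0), dur_s = numeric(0),
                     peak = numeric(0), klass = character(0))
    occupied <- NULL
    for (cls in c("syn", "anti", "spont")) {
      rate <- switch(cls, syn = params$syn_saccade_rate[[kind]],
                     anti = params$anti_saccade_rate[[kind]],
                     spont = params$spont_saccade_rate)
      window <- if (cls == "spont") c(0, t_mot) else c(t_mot, t_end)
      if (rate <= 0 || diff(window) <= 0) next
      k <- stats::rpois(1, rate * diff(window))
      # truncate extreme draws at the window's REMAINING packing capacity
      # (occupancy is shared between saccade classes)
      used <- if (!is.null(occupied) && nrow(occupied))
        sum(pmax(0, pmin(occupied$hi, window[2]) -
                    pmax(occupied$lo, window[1]))) else 0
      cap <- floor(0.85 * (diff(window) - used) /
                     (params$saccade_duration_range[2] / 1000 + 0.15))
      if (cap < 1 && rate > 0 && k > 0) next
      k <- min(k, cap)
      if (k == 0) next
      durs <- dur_draw(k)
      # 150 ms refractory between saccades: keeps successive events
      # separable without saturating the motion window at realistic rates
      ons <- .poisson_times_fixed(k, window[1], window[2], durs + 0.15,
                                  occupied)
      occupied <- attr(ons, "occupied")
      keep <- attr(ons, "placed_idx")
      sign_cls <- switch(cls,
        syn = rep(sgn, k), anti = rep(-sgn, k),
        spont = sample(c(-1, 1), k, replace = TRUE))
      peaks <- peak_draw(k)
      if (length(ons))
        ev <- rbind(ev, data.frame(onset_s = as.numeric(ons),
                                   dur_s = durs[keep],
                                   peak = sign_cls[keep] * peaks[keep],
                                   klass = cls))
    }
    sacc <- numeric(n)
    if (nrow(ev)) {
      ev <- ev[order(ev$onset_s), , drop = FALSE]
      ev$onset_frame <- pmin(n, pmax(1L, 1L + floor(ev$onset_s * fs)))
      ev$offset_frame <- NA_integer_
      for (i in seq_len(nrow(ev))) {
        pulse <- .saccade_pulse(ev$dur_s[i], ev$peak[i], fs)
        i0 <- ev$onset_frame[i]
        i1 <- min(n, i0 + length(pulse) - 1L)
        sacc[i0:i1] <- sacc[i0:i1] + pulse[seq_len(i1 - i0 + 1L)]
        ev$offset_frame[i] <- i1
      }
      ev$peak_deg_s <- ev$peak
      # exact discrete integral of the sampled Hann pulse
      ev$displacement_deg <- 0.5 * ev$peak *
        (ev$offset_frame - ev$onset_frame + 1L) / fs
      ev$pre_motion <- ev$onset_frame <= n_static
    }
    total <- smooth + sacc
    total[1] <- 0; smooth[1] <- 0; sacc[1] <- 0  # frame 1 carries no step
    theta0 <- stats::runif(1, 0, 360)
    theta <- theta0 + cumsum(total) / fs
    speed <- pmax(0, params$speed_mean +
                    .lp_noise(n, params$speed_sd, params$noise_cutoff_hz, fs))
    speed[1] <- 0
    r0 <- params$start_radius * sqrt(stats::runif(1))
    phi0 <- stats::runif(1, 0, 2 * pi)
    pos <- .integrate_position(speed / fs, theta, c(r0 * cos(phi0), r0 * sin(phi0)),
                               params$arena_radius, params$wall_buffer)
    if (length(pos$reflect_delta)) {
      # reflection turns are real turns: book them on the smooth channel
      for (j in seq_along(pos$reflect_frame)) {
        fidx <- pos$reflect_frame[j]
        smooth[fidx] <- smooth[fidx] + pos$reflect_delta[j] * fs
        total[fidx] <- total[fidx] + pos$reflect_delta[j] * fs
      }
      theta <- theta0 + cumsum(total) / fs
    }
    anchor <- closed_loop_angle(theta, params$delay_frames)
    traj[[tr]] <- list(x = pos$x, y = pos$y, body_angle = theta,
                       speed_true = speed, ang_vel_true = total,
                       smooth_true = smooth, sacc_true = sacc,
                       stim_anchor = anchor)
    evs[[tr]] <- if (nrow(ev)) cbind(trial_id = tr,
      ev[, c("onset_frame", "offset_frame", "peak_deg_s",
             "displacement_deg", "klass", "pre_motion")]) else NULL
    logs[[tr]] <- data.frame(trial_id = tr, kind = kind,
                             rotation_dir = condition$rotation_dir,
                             contrast = michelson_contrast(condition$pattern),
                             speed_deg_s = condition$rotation_speed,
                             t_start = 0, t_motion_onset = n_static / fs,
                             t_end = n / fs, n_frames = n)
  }
  # column-wise assembly (much cheaper than rbind of many data.frames)
  pull <- function(col) unlist(lapply(traj, `[[`, col), use.names = FALSE)
  trajectory <- data.frame(
    trial_id = rep(seq_len(n_trials), each = n),
    frame = rep(seq_len(n), n_trials),
    t = rep((seq_len(n) - 1) / fs, n_trials),
    x = pull("x"), y = pull("y"), body_angle = pull("body_angle"),
    heading = pull("body_angle") %% 360,
    speed_true = pull("speed_true"), ang_vel_true = pull("ang_vel_true"),
    smooth_true = pull("smooth_true"), sacc_true = pull("sacc_true"),
    stim_anchor = pull("stim_anchor"))
  events <- do.call(rbind, evs[!vapply(evs, is.null, logical(1))])
  if (is.null(events))
    events <- data.frame(trial_id = integer(0), onset_frame = integer(0),
                         offset_frame = integer(0), peak_deg_s = numeric(0),
                         displacement_deg = numeric(0), klass = character(0),
                         pre_motion = logical(0))
  list(trajectory = trajectory, events = events,
       trial_log = do.call(rbind, logs))
}

# place k events of given durations without overlap: random placement with a
# deterministic free-gap fallback; events that no longer fit are dropped
# (the caller guards against a-priori infeasible rates)
.poisson_times_fixed <- function(k, t0, t1, dur_s, existing = NULL) {
  onsets <- numeric(0)
  placed_idx <- integer(0)
  occupied <- existing
  for (i in seq_len(k)) {
    placed <- FALSE
    for (attempt in seq_len(100L)) {
      cand <- stats::runif(1, t0, max(t0 + 1e-9, t1 - dur_s[i]))
      lo <- cand; hi <- cand + dur_s[i]
      ok <- TRUE
      if (!is.null(occupied) && nrow(occupied) > 0)
        ok <- all(hi <= occupied$lo | lo >= occupied$hi)
      if (ok) {
        occupied <- rbind(occupied, data.frame(lo = lo, hi = hi))
        onsets <- c(onsets, cand)
        placed_idx <- c(placed_idx, i)
        placed <- TRUE
        break
      }
    }
    if (!placed) {
      # scan the free gaps of [t0, t1] for the first slot that fits
      occ <- occupied[order(occupied$lo), , drop = FALSE]
      occ$lo <- pmax(occ$lo, t0); occ$hi <- pmin(occ$hi, t1)
      edges_lo <- c(t0, occ$hi)
      edges_hi <- c(occ$lo, t1)
      fits <- which(edges_hi - edges_lo >= dur_s[i])
      if (!length(fits)) next   # window saturated: truncate the count
      cand <- edges_lo[fits[1]]
      occupied <- rbind(occupied,
                        data.frame(lo = cand, hi = cand + dur_s[i]))
      onsets <- c(onsets, cand)
      placed_idx <- c(placed_idx, i)
    }
  }
  attr(onsets, "occupied") <- occupied
  attr(onsets, "placed_idx") <- placed_idx
  onsets
}

# step-wise position integration with specular reflection of the travel
# direction at (radius - buffer); vectorised between wall contacts
.integrate_position <- function(step_mm, theta_deg, start, radius, buffer) {
  n <- length(step_mm)
  th <- theta_deg * pi / 180
  dx <- step_mm * cos(th); dy <- step_mm * sin(th)
  x <- numeric(n); y <- numeric(n)
  x[1] <- start[1]; y[1] <- start[2]
  rmax <- if (buffer > 0) radius - buffer else radius - 1e-9
  reflect_frame <- integer(0); reflect_delta <- numeric(0)
  i <- 1L
  dtheta <- 0  # accumulated reflection offset applied to travel direction
  while (i < n) {
    idx <- (i + 1L):n
    if (dtheta != 0) {
      thr <- th[idx] + dtheta
      cx <- x[i] + cumsum(step_mm[idx] * cos(thr))
      cy <- y[i] + cumsum(step_mm[idx] * sin(thr))
    } else {
      cx <- x[i] + cumsum(dx[idx]); cy <- y[i] + cumsum(dy[idx])
    }
    rr <- sqrt(cx^2 + cy^2)
    bad <- which(rr > rmax)
    if (!length(bad)) { x[idx] <- cx; y[idx] <- cy; break }
    j <- bad[1]                       # first frame outside the buffer
    if (j > 1L) {
      keep <- idx[seq_len(j - 1L)]
      x[keep] <- cx[seq_len(j - 1L)]; y[keep] <- cy[seq_len(j - 1L)]
    }
    i <- idx[j] - 1L                  # last in-bounds frame
    # specular reflection about the wall tangent at the contact point
    fidx <- i + 1L
    wall_normal <- atan2(cy[j], cx[j])
    inc <- th[fidx] + dtheta
    refl <- 2 * (wall_normal + pi / 2) - inc   # reflect about tangent line
    delta <- ((refl - inc + pi) %% (2 * pi)) - pi
    dtheta <- dtheta + delta
    reflect_frame <- c(reflect_frame, fidx)
    reflect_delta <- c(reflect_delta, delta * 180 / pi)
    # place the reflected step from the last in-bounds point
    thr <- th[fidx] + dtheta
    x[fidx] <- x[i] + step_mm[fidx] * cos(thr)
    y[fidx] <- y[i] + step_mm[fidx] * sin(thr)
    rr1 <- sqrt(x[fidx]^2 + y[fidx]^2)
    if (rr1 > rmax) {  # pathological: step straight back toward the centre
      thr <- atan2(-y[i], -x[i])
      extra <- ((thr - (th[fidx] + dtheta) + pi) %% (2 * pi)) - pi
      dtheta <- dtheta + extra
      reflect_delta[length(reflect_delta)] <-
        reflect_delta[length(reflect_delta)] + extra * 180 / pi
      x[fidx] <- x[i] + step_mm[fidx] * cos(thr)
      y[fidx] <- y[i] + step_mm[fidx] * sin(thr)
    }
    i <- fidx
  }
  list(x = x, y = y, reflect_frame = reflect_frame, reflect_delta = reflect_delta)
}
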