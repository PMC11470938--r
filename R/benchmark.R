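#' Planted-saccade benchmark traces
#'
#' Generates angular-velocity traces with raised-cosine saccade pulses planted
#' at known times on a smooth band-limited background, the standard benchmark
#' for the saccade detector: peaks drawn uniformly from `peak_range`
#' (>= 300 deg/s), supports from `width_range` (80-200 ms), events separated
#' by at least `min_sep_s`, background bounded by `bg_max` and band-limited
#' below 5 Hz. Setting `rate = 0` yields smooth-only null traces.
#'
#' @param n_trials number of traces.
#' @param duration_s trace duration (default 10 s).
#' @param fs sampling rate, Hz.
#' @param rate planted events/s (default 0.6).
#' @param peak_range deg/s (default `c(300, 600)`).
#' @param width_range ms pulse support (default `c(80, 200)`).
#' @param min_sep_s minimum separation between pulse supports (default 0.3).
#' @param bg_sd,bg_cutoff_hz,bg_max smooth background: SD (deg/s), low-pass
#'   cutoff (Hz, < 5), amplitude bound (deg/s; traces are rescaled, never
#'   clipped).
#' @param seed RNG seed.
#' @return list with `traces` (list of numeric series) and `truth`
#'   (data.frame: trial, onset_frame, offset_frame, peak_frame,
#'   half_peak_onset_frame, peak_deg_s, width_ms, displacement_deg, sign).
#' @export
simulate_saccade_benchmark <- function(n_trials = 50, duration_s = 10, fs = 60,
                                       rate = 0.6,
                                       peak_range = c(300, 600),
                                       width_range = c(80, 200),
                                       min_sep_s = 0.3,
                                       bg_sd = 30, bg_cutoff_hz = 2,
                                       bg_max = 100, seed = 1L) {
  stopifnot(bg_cutoff_hz < 5, rate >= 0)
  set.seed(as.integer(seed))
  n <- round(duration_s * fs)
  traces <- vector("list", n_trials)
  truth <- list()
  for (tr in seq_len(n_trials)) {
    bg <- .lp_noise(n, bg_sd, bg_cutoff_hz, fs)
    mx <- max(abs(bg))
    if (mx > bg_max) bg <- bg * (bg_max / mx)
    x <- bg
    k <- stats::rpois(1, rate * duration_s)
    usable <- duration_s - 0.4
    # truncate extreme draws at the packing capacity
    cap <- floor(0.85 * usable / (width_range[2] / 1000 + min_sep_s))
    if (cap < 1 && rate > 0 && k > 0)
      stop("planted rate too high: no non-overlapping placement exists")
    k <- min(k, cap)
    placed <- data.frame(lo = numeric(0), hi = numeric(0))
    for (i in seq_len(k)) {
      dur <- stats::runif(1, width_range[1], width_range[2]) / 1000
      t0 <- NA_real_
      for (attempt in seq_len(400L)) {
        # one-sided guard: >= min_sep_s between any two supports
        cand <- stats::runif(1, 0.2, duration_s - dur - 0.2)
        lo <- cand; hi <- cand + dur + min_sep_s
        if (!nrow(placed) || all(hi <= placed$lo | lo >= placed$hi)) {
          t0 <- cand
          break
        }
      }
      if (is.na(t0)) {
        # deterministic fallback: first free gap that fits
        occ <- placed[order(placed$lo), , drop = FALSE]
        edges_lo <- c(0.2, occ$hi)
        edges_hi <- c(occ$lo, duration_s - 0.2)
        fits <- which(edges_hi - edges_lo >= dur + min_sep_s)
        if (!length(fits))
          stop("planted rate too high: no non-overlapping placement exists")
        t0 <- edges_lo[fits[1]]
      }
      placed <- rbind(placed, data.frame(lo = t0, hi = t0 + dur + min_sep_s))
      peak <- stats::runif(1, peak_range[1], peak_range[2]) *
        sample(c(-1, 1), 1)
      pulse <- .saccade_pulse(dur, peak, fs)
      i0 <- 1L + floor(t0 * fs)
      i1 <- i0 + length(pulse) - 1L
      x[i0:i1] <- x[i0:i1] + pulse
      truth[[length(truth) + 1L]] <- data.frame(
        trial = tr, onset_frame = i0, offset_frame = i1,
        peak_frame = i0 + which.max(abs(pulse)) - 1L,
        half_peak_onset_frame = i0 + round(length(pulse) / 4),
        peak_deg_s = peak, width_ms = dur * 1000,
        displacement_deg = 0.5 * peak * length(pulse) / fs,
        sign = sign(peak))
    }
    traces[[tr]] <- x
  }
  truth <- if (length(truth)) do.call(rbind, truth) else
    data.frame(trial = integer(0), onset_frame = integer(0),
               offset_frame = integer(0), peak_frame = integer(0),
               half_peak_onset_frame = integer(0), peak_deg_s = numeric(0),
               width_ms = numeric(0), displacement_deg = numeric(0),
               sign = numeric(0))
  list(traces = traces, truth = truth)
}

#' Score detections against planted ground truth
#'
#' A detection is a hit when its `peak_frame` falls within `tol_frames` of a
#' planted event's support; each planted event can be claimed once. Onset
#' error compares the detected onset to the planted half-peak onset (the
#' detector reports half-height edges, so the half-peak landmark is the
#' commensurate ground-truth anchor).
#'
#' @param detections data.frame from [detect_saccades()] with a `trial`
#'   column added.
#' @param truth the `truth` table of [simulate_saccade_benchmark()].
#' @param fs sampling rate, Hz.
#' @param tol_frames matching slack beyond the planted support (default 3).
#' @return list with `hit_rate`, `false_discovery_rate`,
#'   `mean_onset_error_ms`, `n_true`, `n_detected`, `n_hits`.
#' @export
score_detections <- function(detections, truth, fs, tol_frames = 3L) {
  n_true <- nrow(truth)
  n_det <- nrow(detections)
  hits <- 0L
  onset_err <- numeric(0)
  matched <- rep(FALSE, n_true)
  for (d in seq_len(n_det)) {
    tr <- detections$trial[d]
    cand <- which(!matched & truth$trial == tr &
                  detections$peak_frame[d] >= truth$onset_frame - tol_frames &
                  detections$peak_frame[d] <= truth$offset_frame + tol_frames)
    if (length(cand)) {
      g <- cand[1]
      matched[g] <- TRUE
      hits <- hits + 1L
      onset_err <- c(onset_err,
                     (detections$onset[d] - truth$half_peak_onset_frame[g]) /
                       fs * 1000)
    }
  }
  list(hit_rate = if (n_true) hits / n_true else NA_real_,
       false_discovery_rate = if (n_det) 1 - hits / n_det else 0,
       mean_onset_error_ms = if (length(onset_err)) mean(abs(onset_err))
                             else NA_real_,
       n_true = n_true, n_detected = n_det, n_hits = hits)
}
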