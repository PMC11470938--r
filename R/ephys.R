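#' Rolling-baseline subtraction
#'
#' Removes slow drift from long intracellular recordings by subtracting a
#' centred rolling mean (default 60 s window), leaving only deviations from
#' baseline. Edges use shrinking windows. Records shorter than the window
#' fall back to global-mean subtraction and are flagged with
#' `attr(, "global_mean_used")`.
#'
#' @param v membrane potential, mV.
#' @param fs sampling rate, Hz (10000 nominal).
#' @param window_s rolling window, s (default 60).
#' @return baseline-subtracted series, same length.
#' @export
rolling_baseline_subtract <- function(v, fs, window_s = 60) {
  n <- length(v)
  w <- round(window_s * fs)
  if (n < w) {
    out <- v - mean(v)
    attr(out, "global_mean_used") <- TRUE
    return(out)
  }
  h <- w %/% 2L
  cs <- cumsum(c(0, v))
  lo <- pmax(0L, seq_len(n) - h - 1L)       # cumsum index before window start
  hi <- pmin(n, seq_len(n) + h)
  base <- (cs[hi + 1L] - cs[lo + 1L]) / (hi - lo)
  out <- v - base
  attr(out, "global_mean_used") <- FALSE
  out
}

#' Bin a voltage trace at the stimulus frame rate
#'
#' Averages the trace within each stimulus frame's bin (16.6 ms at 60 Hz),
#' time-locking the voltage to the per-frame stimulus log.
#'
#' @param v baseline-subtracted voltage, mV.
#' @param fs voltage sampling rate, Hz.
#' @param frame_times frame onset times, s (strictly increasing).
#' @param bin_s bin duration, s (default 1/60).
#' @return numeric vector, one mean per frame; empty bins are `NA` and
#'   flagged in `attr(, "empty_bins")`.
#' @export
bin_responses <- function(v, fs, frame_times, bin_s = 1 / 60) {
  if (is.unsorted(frame_times, strictly = TRUE))
    stop("frame times must be strictly increasing")
  n <- length(v)
  out <- vapply(frame_times, function(t0) {
    # samples with t0 <= (i-1)/fs < t0 + bin_s
    i0 <- as.integer(ceiling(t0 * fs - 1e-9)) + 1L
    i1 <- min(n, ceiling((t0 + bin_s) * fs - 1e-6))
    if (i0 > n || i1 < i0) return(NA_real_)
    mean(v[i0:i1])
  }, numeric(1))
  attr(out, "empty_bins") <- which(is.na(out))
  out
}

#' Scanning-bar protocol
#'
#' Frame-by-frame log of a small rectangle (10 deg high x 2 deg wide)
#' scanning the visual field along the four cardinal directions: horizontal
#' sweeps (one per elevation row, both azimuth directions) and vertical
#' sweeps (one per azimuth column, both elevation directions), repeated
#' `n_reps` times. Bar centres sit on the grid nodes; one frame per node.
#'
#' @param azimuths,elevations grid node positions, degrees (defaults: 5-deg
#'   spacing over -70..70 x -40..40, the screen span).
#' @param n_reps repetitions (default 1).
#' @param frame_s frame duration, s (default 1/60).
#' @return data.frame of class `scan_protocol`: `frame`, `t`, `azimuth`,
#'   `elevation`, `direction` (`"+az"`, `"-az"`, `"+el"`, `"-el"`), `rep`.
#' @export
scan_protocol <- function(azimuths = seq(-70, 70, by = 5),
                          elevations = seq(-40, 40, by = 5),
                          n_reps = 1L, frame_s = 1 / 60) {
  stopifnot(frame_s > 0, n_reps >= 1)
  one_rep <- list()
  for (el in elevations) {
    one_rep[[length(one_rep) + 1L]] <-
      data.frame(azimuth = azimuths, elevation = el, direction = "+az")
    one_rep[[length(one_rep) + 1L]] <-
      data.frame(azimuth = rev(azimuths), elevation = el, direction = "-az")
  }
  for (az in azimuths) {
    one_rep[[length(one_rep) + 1L]] <-
      data.frame(azimuth = az, elevation = elevations, direction = "+el")
    one_rep[[length(one_rep) + 1L]] <-
      data.frame(azimuth = az, elevation = rev(elevations), direction = "-el")
  }
  one_rep <- do.call(rbind, one_rep)
  out <- do.call(rbind, lapply(seq_len(n_reps), function(r)
    cbind(one_rep, rep = r)))
  out$frame <- seq_len(nrow(out))
  out$t <- (out$frame - 1) * frame_s
  rownames(out) <- NULL
  structure(out[, c("frame", "t", "azimuth", "elevation", "direction",
                    "rep")],
            class = c("scan_protocol", "data.frame"), frame_s = frame_s)
}

.dir_unit <- function(direction) {
  switch(direction,
         "+az" = c(1, 0), "-az" = c(-1, 0),
         "+el" = c(0, 1), "-el" = c(0, -1),
         stop("unknown scan direction"))
}

#' Plant a receptive-field vector field
#'
#' Ground-truth local-motion-sensitivity field for the synthetic scanning
#' experiment: a horizontally-tuned Gaussian hotspot (like an HS cell's
#' front-to-back preference) centred ipsilaterally, plus an optional
#' contralateral lobe of opposite horizontal preference whose share of the
#' total `sum(|F|)` mass is `contra_share`.
#'
#' @param azimuths,elevations grid, degrees (defaults as [scan_protocol()]).
#' @param centre c(azimuth, elevation) of the ipsilateral hotspot.
#' @param sigma Gaussian width, degrees.
#' @param peak_mv peak sensitivity, mV per unit bar motion.
#' @param contra_share fraction (0-1) of total `sum(|F|)` mass on the
#'   contralateral side (azimuth < `midline`); 0 disables the lobe.
#' @param contra_centre,contra_sigma contralateral lobe geometry.
#' @param midline azimuth separating the two visual hemifields (default 0).
#' @return data.frame of class `planted_rf`: `azimuth`, `elevation`, `vx`,
#'   `vy` (mV), with attributes `midline` and `contra_share`.
#' @export
planted_rf <- function(azimuths = seq(-70, 70, by = 5),
                       elevations = seq(-40, 40, by = 5),
                       centre = c(30, 10), sigma = 25, peak_mv = 8,
                       contra_share = 0, contra_centre = c(-40, 0),
                       contra_sigma = 18, midline = 0) {
  g <- expand.grid(azimuth = azimuths, elevation = elevations)
  ipsi <- peak_mv * exp(-((g$azimuth - centre[1])^2 +
                          (g$elevation - centre[2])^2) / (2 * sigma^2))
  ipsi[g$azimuth < midline] <- 0
  vx <- ipsi; vy <- rep(0, nrow(g))
  if (contra_share > 0) {
    stopifnot(contra_share < 1)
    lobe <- exp(-((g$azimuth - contra_centre[1])^2 +
                  (g$elevation - contra_centre[2])^2) / (2 * contra_sigma^2))
    lobe[g$azimuth >= midline] <- 0
    # scale the lobe so contralateral mass is the requested share
    lobe <- lobe * (contra_share / (1 - contra_share)) * sum(ipsi) / sum(lobe)
    vx <- vx - lobe    # opposite horizontal preference on the far side
  }
  structure(data.frame(azimuth = g$azimuth, elevation = g$elevation,
                       vx = vx, vy = vy),
            class = c("planted_rf", "data.frame"),
            midline = midline, contra_share = contra_share)
}

#' Simulate scanning-bar voltage responses from a planted field
#'
#' Per stimulus frame, the noiseless response is the dot product of the
#' planted field vector at the bar's position with the unit motion direction;
#' per-frame Gaussian noise and an optional slow sinusoidal drift are added,
#' and the value is held constant over the frame's voltage samples at
#' `fs` Hz.
#'
#' @param rf a [planted_rf()] (or any data.frame with azimuth, elevation,
#'   vx, vy).
#' @param protocol a [scan_protocol()]; its grid must lie within `rf`'s.
#' @param noise_sd per-frame Gaussian noise, mV.
#' @param fs voltage sampling rate, Hz (default 10000).
#' @param drift_amp_mv,drift_freq_hz optional slow drift (default 0).
#' @param seed RNG seed.
#' @return list: `v` (voltage trace, mV), `fs`, `frame_times` (s),
#'   `protocol`, `frame_response` (the noisy per-frame values).
#' @export
simulate_scan_responses <- function(rf, protocol, noise_sd = 0, fs = 10000,
                                    drift_amp_mv = 0, drift_freq_hz = 0.05,
                                    seed = 1L) {
  set.seed(as.integer(seed))
  key_rf <- paste(rf$azimuth, rf$elevation)
  key_pr <- paste(protocol$azimuth, protocol$elevation)
  hit <- match(key_pr, key_rf)
  if (anyNA(hit)) stop("protocol grid extends outside the planted field")
  dir_mat <- t(vapply(protocol$direction, .dir_unit, numeric(2)))
  clean <- rf$vx[hit] * dir_mat[, 1] + rf$vy[hit] * dir_mat[, 2]
  resp <- clean + stats::rnorm(nrow(protocol), 0, noise_sd)
  frame_s <- attr(protocol, "frame_s")
  # assign each voltage sample to the frame whose bin contains its time,
  # so binning recovers the per-frame values exactly
  n_samp <- ceiling(nrow(protocol) * frame_s * fs)
  fr_idx <- pmin(nrow(protocol),
                 floor((seq_len(n_samp) - 1) / fs / frame_s + 1e-9) + 1L)
  v <- resp[fr_idx]
  if (drift_amp_mv > 0) {
    tt <- (seq_along(v) - 1) / fs
    v <- v + drift_amp_mv * sin(2 * pi * drift_freq_hz * tt)
  }
  list(v = v, fs = fs, frame_times = protocol$t, protocol = protocol,
       frame_response = resp)
}

#' Reconstruct the receptive-field vector field from scan responses
#'
#' For each grid point, the binned voltage responses are averaged per motion
#' direction (across sweeps and repetitions) and the four cardinal direction
#' units are weighted by their mean response and summed. For a linear,
#' noiseless cell with planted field F this vector sum equals exactly `2 F`
#' (`sum_d (F . d) d = 2 F` over the 4 cardinal units). An optional constant
#' latency shift realigns responses to the stimulus log before attribution.
#'
#' @param binned per-frame binned responses ([bin_responses()] output).
#' @param protocol the [scan_protocol()] used.
#' @param latency_shift_frames non-negative integer shift applied to the
#'   responses before attribution (default 0).
#' @return data.frame of class `rf_field`: `azimuth`, `elevation`, `vx`,
#'   `vy`, `length`, plus attribute `norm_factor` (max vector length).
#' @export
reconstruct_rf <- function(binned, protocol, latency_shift_frames = 0L) {
  if (length(binned) != nrow(protocol))
    stop("binned responses and protocol length differ")
  need <- c("+az", "-az", "+el", "-el")
  if (!all(need %in% unique(protocol$direction)))
    stop("all four cardinal directions are required")
  k <- as.integer(latency_shift_frames)
  if (k > 0) binned <- c(binned[-seq_len(k)], rep(NA_real_, k))
  agg <- stats::aggregate(
    list(resp = binned),
    by = list(azimuth = protocol$azimuth, elevation = protocol$elevation,
              direction = protocol$direction),
    FUN = function(z) mean(z, na.rm = TRUE))
  g <- unique(agg[, c("azimuth", "elevation")])
  g <- g[order(g$elevation, g$azimuth), ]
  vx <- numeric(nrow(g)); vy <- numeric(nrow(g))
  for (d in need) {
    u <- .dir_unit(d)
    sub <- agg[agg$direction == d, ]
    m <- match(paste(g$azimuth, g$elevation),
               paste(sub$azimuth, sub$elevation))
    r <- sub$resp[m]
    r[is.na(r)] <- 0
    vx <- vx + r * u[1]
    vy <- vy + r * u[2]
  }
  len <- sqrt(vx^2 + vy^2)
  structure(data.frame(azimuth = g$azimuth, elevation = g$elevation,
                       vx = vx, vy = vy, length = len),
            class = c("rf_field", "data.frame"),
            norm_factor = max(len))
}

#' Receptive-field summary metrics
#'
#' Normalises the field to its maximum vector length and reports: the area
#' (solid-angle weighted, cos(elevation) per cell) above 30% and 60% of the
#' maximum; the contralateral/ipsilateral relative strength; and the
#' contralateral share of the total sensitivity under both readings of
#' "total": the sum of vector magnitudes (`share_sum_abs`) and the magnitude
#' of the vector sum (`share_vec_sum`).
#'
#' @param rf an `rf_field` (or planted field with vx, vy).
#' @param levels fractions of the maximum (default `c(0.3, 0.6)`).
#' @param midline azimuth separating the hemifields (default 0).
#' @param ipsi_side `"pos"` if ipsilateral azimuths are > midline (default).
#' @return list: `areas` (named, deg^2 solid-angle weighted), `max_length`,
#'   `contra_ipsi_ratio`, `share_sum_abs`, `share_vec_sum` (both in percent).
#' @export
rf_metrics <- function(rf, levels = c(0.3, 0.6), midline = 0,
                       ipsi_side = c("pos", "neg")) {
  ipsi_side <- match.arg(ipsi_side)
  len <- sqrt(rf$vx^2 + rf$vy^2)
  mx <- max(len)
  if (mx <= 0) stop("all-zero field: metrics undefined")
  az <- sort(unique(rf$azimuth)); el <- sort(unique(rf$elevation))
  daz <- if (length(az) > 1) stats::median(diff(az)) else 1
  del <- if (length(el) > 1) stats::median(diff(el)) else 1
  cell_w <- cos(rf$elevation * pi / 180) * daz * del
  areas <- vapply(levels, function(lv) sum(cell_w[len >= lv * mx]),
                  numeric(1))
  names(areas) <- paste0("area_", levels * 100, "pct")
  ipsi <- if (ipsi_side == "pos") rf$azimuth > midline else
    rf$azimuth < midline
  contra <- !ipsi & rf$azimuth != midline
  s_i <- sum(len[ipsi]); s_c <- sum(len[contra])
  vsum_all <- c(sum(rf$vx), sum(rf$vy))
  vsum_c <- c(sum(rf$vx[contra]), sum(rf$vy[contra]))
  list(areas = areas, max_length = mx,
       contra_ipsi_ratio = if (s_i > 0) s_c / s_i else Inf,
       share_sum_abs = 100 * s_c / (s_c + s_i),
       share_vec_sum = if (sqrt(sum(vsum_all^2)) > 0)
         100 * sqrt(sum(vsum_c^2)) / sqrt(sum(vsum_all^2)) else NA_real_)
}

#' Power-band fractions of a baseline trace
#'
#' One-sided periodogram normalised to unit total power, with the fraction of
#' power in the low band `[0, 10]` Hz (excluding DC) and the mid band
#' `(10, 50]` Hz. Half-open band edges avoid double-counting the 10 Hz bin.
#' Multiple repetitions are averaged spectrum-wise before normalisation.
#'
#' @param trace voltage trace (flash-OFF segments, global mean subtracted) or
#'   a list of repetition traces of equal length.
#' @param fs sampling rate, Hz.
#' @return list: `freq`, `power` (normalised spectrum, sums to 1),
#'   `low_fraction`, `mid_fraction`.
#' @export
power_bands <- function(trace, fs) {
  reps <- if (is.list(trace)) trace else list(trace)
  n <- length(reps[[1]])
  if (n < fs) stop("trace shorter than 1 s: insufficient resolution")
  if (any(vapply(reps, length, numeric(1)) != n))
    stop("repetitions must have equal length")
  spec <- Reduce(`+`, lapply(reps, function(x) {
    x <- x - mean(x)
    Mod(stats::fft(x))^2
  })) / length(reps)
  half <- floor(n / 2)
  p <- spec[2:(half + 1)]          # one-sided, DC removed
  freq <- (1:half) * fs / n
  p <- p / sum(p)
  list(freq = freq, power = p,
       low_fraction = sum(p[freq <= 10]),
       mid_fraction = sum(p[freq > 10 & freq <= 50]))
}

#' Flash ON/OFF transient amplitudes
#'
#' Per flash event, the peak absolute deviation from the pre-event baseline
#' within `window_s` of onset; averaged per event class.
#'
#' @param v baseline-subtracted voltage, mV.
#' @param fs sampling rate, Hz.
#' @param events data.frame with `time` (s) and `class` (e.g. "ON"/"OFF").
#' @param window_s response window after onset (default 0.5).
#' @param baseline_s pre-event baseline window (default 0.2).
#' @return data.frame: `class`, `n`, `mean_amplitude_mv`.
#' @export
flash_response <- function(v, fs, events, window_s = 0.5, baseline_s = 0.2) {
  n <- length(v)
  amp <- vapply(seq_len(nrow(events)), function(k) {
    i0 <- max(1L, round(events$time[k] * fs) + 1L)
    ib <- max(1L, i0 - round(baseline_s * fs)):max(1L, i0 - 1L)
    iw <- i0:min(n, i0 + round(window_s * fs))
    base <- mean(v[ib])
    max(abs(v[iw] - base))
  }, numeric(1))
  agg <- stats::aggregate(list(mean_amplitude_mv = amp),
                          by = list(class = events$class), FUN = mean)
  agg$n <- as.integer(table(events$class)[agg$class])
  agg[, c("class", "n", "mean_amplitude_mv")]
}

#' Grating tuning curves
#'
#' Response per trial = mean(voltage during motion) minus mean(voltage during
#' the preceding static period); direction tuning is additionally normalised
#' to the cell's maximum.
#'
#' @param v baseline-subtracted voltage, mV.
#' @param fs sampling rate, Hz.
#' @param trials data.frame with `t_static_on`, `t_motion_on`, `t_motion_off`
#'   (s) and a stimulus parameter column named by `by` (e.g. `direction`).
#' @param by name of the tuning variable column.
#' @return data.frame: one row per level of `by` with `response_mv` and, for
#'   `by = "direction"`, `normalised` (response / max response).
#' @export
tuning_curves <- function(v, fs, trials, by = "direction") {
  stopifnot(by %in% names(trials))
  if (any(trials$t_motion_on <= trials$t_static_on))
    stop("missing or malformed static period")
  n <- length(v)
  resp <- vapply(seq_len(nrow(trials)), function(k) {
    is_ <- (round(trials$t_static_on[k] * fs) + 1L):
      round(trials$t_motion_on[k] * fs)
    im <- (round(trials$t_motion_on[k] * fs) + 1L):
      min(n, round(trials$t_motion_off[k] * fs))
    mean(v[im]) - mean(v[is_])
  }, numeric(1))
  agg <- stats::aggregate(list(response_mv = resp),
                          by = stats::setNames(list(trials[[by]]), by),
                          FUN = mean)
  if (identical(by, "direction")) {
    mx <- max(agg$response_mv)
    agg$normalised <- if (mx != 0) agg$response_mv / mx else NA_real_
  }
  agg
}

#' Simulate a baseline membrane-potential trace
#'
#' Sum of sinusoids plus optional white noise and a random-walk drift, for
#' exercising the power-band analysis.
#'
#' @param duration_s trace length, s.
#' @param fs sampling rate, Hz.
#' @param components data.frame with `freq_hz`, `amp_mv` (may be empty).
#' @param noise_sd white-noise SD, mV.
#' @param drift_sd per-sample random-walk increment SD, mV.
#' @param seed RNG seed.
#' @return voltage trace, mV.
#' @export
simulate_baseline <- function(duration_s, fs,
                              components = data.frame(freq_hz = numeric(0),
                                                      amp_mv = numeric(0)),
                              noise_sd = 0, drift_sd = 0, seed = 1L) {
  if (nrow(components) && any(components$freq_hz >= fs / 2))
    stop("component frequency at or above the Nyquist rate: aliasing")
  set.seed(as.integer(seed))
  n <- round(duration_s * fs)
  tt <- (seq_len(n) - 1) / fs
  v <- numeric(n)
  for (k in seq_len(nrow(components)))
    v <- v + components$amp_mv[k] * sin(2 * pi * components$freq_hz[k] * tt)
  if (noise_sd > 0) v <- v + stats::rnorm(n, 0, noise_sd)
  if (drift_sd > 0) v <- v + cumsum(stats::rnorm(n, 0, drift_sd))
  v
}
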