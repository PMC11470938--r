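#' Linear prediction of the full-field response
#'
#' If the two visual hemifields contributed independently, the turning
#' response to full-field rotation would be the sum of the responses to
#' unilateral front-to-back and back-to-front motion. Both inputs must be
#' stimulus-aligned mean time series of equal length, aligned to motion onset.
#'
#' @param mean_ftb,mean_btf mean angular-velocity series (deg/s,
#'   stimulus-relative).
#' @return predicted series `mean_ftb + mean_btf`.
#' @export
linear_prediction <- function(mean_ftb, mean_btf) {
  if (length(mean_ftb) != length(mean_btf))
    stop("unilateral mean series have different lengths")
  mean_ftb + mean_btf
}

#' Prediction error of the linearity test
#'
#' Error series `actual - predicted` and its mean over the motion period.
#'
#' @param actual mean full-field angular-velocity series (deg/s).
#' @param predicted output of [linear_prediction()].
#' @param motion_idx frame indices of the motion period (default: all).
#' @return list with `error` (series) and `mean_error` (deg/s).
#' @export
prediction_error <- function(actual, predicted, motion_idx = NULL) {
  if (length(actual) != length(predicted))
    stop("actual and predicted series have different lengths")
  err <- actual - predicted
  if (is.null(motion_idx)) motion_idx <- seq_along(err)
  list(error = err, mean_error = mean(err[motion_idx]))
}

#' One-sample two-sided t-test against zero
#'
#' Thin wrapper around [stats::t.test()] returning the classical statistic,
#' degrees of freedom and two-sided p-value.
#'
#' @param values numeric sample (n >= 2, nonzero variance).
#' @return list: `test`, `statistic`, `df`, `p_value`, `n`, `mean`.
#' @export
one_sample_t <- function(values) {
  values <- values[!is.na(values)]
  if (length(values) < 2) stop("need at least two values")
  if (stats::sd(values) == 0) stop("zero variance: t statistic undefined")
  ht <- stats::t.test(values, mu = 0, alternative = "two.sided")
  list(test = "one_sample_t_two_sided",
       statistic = unname(ht$statistic), df = unname(ht$parameter),
       p_value = ht$p.value, n = length(values), mean = mean(values))
}

#' Two-sided Mann-Whitney U test
#'
#' Wrapper around [stats::wilcox.test()]: exact enumeration for small untied
#' samples, normal approximation with tie correction otherwise. The reported
#' statistic is the U of the first group.
#'
#' @param group_a,group_b numeric samples.
#' @return list: `test`, `statistic` (U), `p_value`, `n_a`, `n_b`.
#' @export
mann_whitney_u <- function(group_a, group_b) {
  group_a <- group_a[!is.na(group_a)]
  group_b <- group_b[!is.na(group_b)]
  if (!length(group_a) || !length(group_b)) stop("both groups must be non-empty")
  ties <- any(duplicated(c(group_a, group_b)))
  exact <- !ties && (length(group_a) + length(group_b)) <= 12
  ht <- suppressWarnings(stats::wilcox.test(group_a, group_b,
                                            alternative = "two.sided",
                                            exact = exact, correct = TRUE))
  list(test = "mann_whitney_u_two_sided",
       statistic = unname(ht$statistic), p_value = ht$p.value,
       n_a = length(group_a), n_b = length(group_b))
}

#' Run the full linearity experiment on simulated flies
#'
#' Simulates `n_flies` independent walkers, each tested with the three moving
#' conditions (full-field, unilateral FtB, unilateral BtF; `n_trials` each),
#' runs the complete analysis chain (kinematics, trial exclusion, stimulus
#' alignment, saccade detection, smooth/saccadic decomposition), forms each
#' fly's linear prediction from its unilateral means, and returns per-fly mean
#' prediction errors over the motion period for the total, smooth and saccadic
#' channels.
#'
#' @param n_flies number of simulated flies (default 15).
#' @param n_trials trials per condition per fly (default 200).
#' @param linearity_mode `"linear"` (null control: full-field drive is the sum
#'   of the unilateral drives) or `"nonlinear"` (antagonistic mode mirroring
#'   real flies).
#' @param seed integer; fly f uses seed `seed + f` offsets internally.
#' @param params_fun optional function(fly_seed, mode) returning
#'   [walker_params()]; defaults to package defaults.
#' @param rotation_dir stimulus rotation for all conditions (default "CW").
#' @param detect use saccade detection and channel decomposition (default
#'   TRUE; FALSE skips channels, total only, for quick checks).
#' @return list: `per_fly` (data.frame fly, mean_error, mean_error_smooth,
#'   mean_error_saccadic, n_kept per condition), `t_total` (group
#'   [one_sample_t()] on total-channel errors), `t_smooth`, `t_saccadic`,
#'   `mean_series` (list of per-condition group-mean aligned series).
#' @export
run_linearity_experiment <- function(n_flies = 15, n_trials = 200,
                                     linearity_mode = c("linear", "nonlinear"),
                                     seed = 1L, params_fun = NULL,
                                     rotation_dir = "CW", detect = TRUE) {
  linearity_mode <- match.arg(linearity_mode)
  conds <- list(
    full_field = stimulus_condition("full_field", rotation_dir),
    unilateral_FtB = stimulus_condition("unilateral_FtB"),
    unilateral_BtF = stimulus_condition("unilateral_BtF"))
  per_fly <- list()
  series_sum <- list()
  for (fly in seq_len(n_flies)) {
    means <- list()
    means_sm <- list()
    means_sc <- list()
    kept_n <- list()
    for (ck in names(conds)) {
      fly_seed <- as.integer(seed) + 7919L * fly +
        313L * match(ck, names(conds))
      p <- if (is.null(params_fun))
        walker_params(linearity_mode = linearity_mode, seed = fly_seed)
      else params_fun(fly_seed, linearity_mode)
      sim <- simulate_walker(p, conds[[ck]], n_trials)
      an <- analyse_walker_trials(sim, p, conds[[ck]], detect = detect)
      means[[ck]] <- an$mean_total
      means_sm[[ck]] <- an$mean_smooth
      means_sc[[ck]] <- an$mean_saccadic
      kept_n[[ck]] <- an$n_kept
    }
    n_all <- length(means$full_field)
    frac_motion <- conds$full_field$motion_duration /
      (conds$full_field$motion_duration + conds$full_field$static_duration)
    motion_idx <- (n_all - round(n_all * frac_motion) + 1):n_all
    pe <- prediction_error(means$full_field,
                           linear_prediction(means$unilateral_FtB,
                                             means$unilateral_BtF),
                           motion_idx)
    row <- data.frame(fly = fly, mean_error = pe$mean_error,
                      n_kept_full = kept_n$full_field,
                      n_kept_ftb = kept_n$unilateral_FtB,
                      n_kept_btf = kept_n$unilateral_BtF)
    if (detect) {
      pe_sm <- prediction_error(means_sm$full_field,
                                linear_prediction(means_sm$unilateral_FtB,
                                                  means_sm$unilateral_BtF),
                                motion_idx)
      pe_sc <- prediction_error(means_sc$full_field,
                                linear_prediction(means_sc$unilateral_FtB,
                                                  means_sc$unilateral_BtF),
                                motion_idx)
      row$mean_error_smooth <- pe_sm$mean_error
      row$mean_error_saccadic <- pe_sc$mean_error
    }
    per_fly[[fly]] <- row
    for (ck in names(conds)) {
      if (is.null(series_sum[[ck]])) series_sum[[ck]] <- means[[ck]]
      else series_sum[[ck]] <- series_sum[[ck]] + means[[ck]]
    }
  }
  per_fly <- do.call(rbind, per_fly)
  out <- list(per_fly = per_fly,
              t_total = one_sample_t(per_fly$mean_error),
              mean_series = lapply(series_sum, function(s) s / n_flies))
  if (detect) {
    out$t_smooth <- one_sample_t(per_fly$mean_error_smooth)
    out$t_saccadic <- one_sample_t(per_fly$mean_error_saccadic)
  }
  out
}

#' Analyse one simulated fly's trials for a single condition
#'
#' The per-condition leg of the analysis chain: derive kinematics per trial,
#' apply the exclusion rules, align to the stimulus, optionally detect
#' saccades and decompose turning, and average the aligned angular velocity
#' across kept trials into a trial-time mean series.
#'
#' @param sim output of [simulate_walker()].
#' @param params the [walker_params()] used.
#' @param condition the [stimulus_condition()] used.
#' @param detect run saccade detection + decomposition per trial.
#' @return list: `mean_total`, `mean_smooth`, `mean_saccadic` (aligned mean
#'   series over kept trials; smooth/saccadic `NULL` unless `detect`),
#'   `n_kept`, `trials` (trial table), `events` (detected, classified,
#'   aligned-sign events with trial_id).
#' @export
analyse_walker_trials <- function(sim, params, condition, detect = TRUE) {
  fs <- params$fs
  ids <- sim$trial_log$trial_id
  n <- sim$trial_log$n_frames[1]
  n_stat <- round(condition$static_duration * fs)
  motion_idx <- (n_stat + 1):n
  # positive = with the stimulus: flip trials whose rotation sign is negative
  sgn <- stimulus_sign(condition$rotation_dir)
  flip <- if (sgn < 0) -1 else 1
  tj <- sim$trajectory
  sum_tot <- numeric(n); sum_smo <- numeric(n); sum_sac <- numeric(n)
  n_kept <- 0L
  reasons <- character(length(ids))
  events <- list()
  for (k in seq_along(ids)) {
    i <- ((k - 1L) * n + 1L):(k * n)    # trials tile the trajectory in order
    kin <- derive_kinematics(
      data.frame(x = tj$x[i], y = tj$y[i], heading = tj$body_angle[i]), fs)
    reasons[k] <- .trial_excl_reason(kin$speed, kin$ang_vel, kin$x, kin$y,
                                     params$arena_radius)
    if (reasons[k] != "none") next
    n_kept <- n_kept + 1L
    v <- flip * kin$ang_vel
    sum_tot <- sum_tot + v
    if (detect) {
      ev <- detect_saccades(v, fs)
      ev <- classify_saccades(ev, n_stat + 1L)
      dec <- decompose_turning(v, ev, fs, motion_idx)
      sum_smo <- sum_smo + dec$smooth
      sum_sac <- sum_sac + dec$saccadic
      if (nrow(ev)) events[[length(events) + 1L]] <- cbind(trial_id = ids[k], ev)
    }
  }
  trials <- sim$trial_log
  trials$excluded <- reasons != "none"
  trials$exclusion_reason <- reasons
  trials$mirrored <- flip < 0
  list(mean_total = sum_tot / max(1L, n_kept),
       mean_smooth = if (detect) sum_smo / max(1L, n_kept) else NULL,
       mean_saccadic = if (detect) sum_sac / max(1L, n_kept) else NULL,
       n_kept = n_kept, trials = trials,
       events = if (length(events)) do.call(rbind, events) else NULL)
}
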