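#!/usr/bin/env Rscript
# Simulates the closed-loop walking experiment for one "fly" under the three
# moving pinwheel conditions and exports the raw tables the later stages
# consume. The walker is the antagonistic ("nonlinear") agent, so unilateral
# front-to-back motion drives anti-saccades while full-field rotation drives
# smooth syn turning, as in real flies.

library(optomotor)

dir.create("results", showWarnings = FALSE)
seed <- 2026L

conds <- list(full_field = stimulus_condition("full_field", "CW"),
              unilateral_FtB = stimulus_condition("unilateral_FtB"),
              unilateral_BtF = stimulus_condition("unilateral_BtF"))

for (ck in names(conds)) {
  p <- walker_params(linearity_mode = "nonlinear",
                     seed = seed + match(ck, names(conds)))
  sim <- simulate_walker(p, conds[[ck]], n_trials = 60)
  write.csv(sim$trajectory,
            file.path("results", paste0("trajectory_", ck, ".csv")),
            row.names = FALSE)
  write.csv(sim$events,
            file.path("results", paste0("ground_truth_events_", ck, ".csv")),
            row.names = FALSE)
  write.csv(sim$trial_log,
            file.path("results", paste0("trial_log_", ck, ".csv")),
            row.names = FALSE)
  cat(sprintf("%-15s %d trials, %d ground-truth saccades\n",
              ck, max(sim$trial_log$trial_id), nrow(sim$events)))
}
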