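#!/usr/bin/env Rscript
# Signal-behaviour regressions across sessions.
#
# Sessions are the regression unit. Three relations are fitted on
# desk-scale simulated blocks (10 sessions each):
#   1. dopamine Delta CS signal vs Delta approach time  (expected: positive)
#   2. dopamine reward AUC (CS+) vs CS+ approach time   (expected: negative)
#   3. ACh reward AUC (CS+) vs CS+ approach time, per genotype
#      (expected: negative in controls, flat in VAChTcKO)
# Writes results/regressions.csv.

suppressPackageStartupMessages(library(photoshape))

cfg <- session_config(n_trials_per_cs = 6, iti_min = 14, iti_max = 18)
art <- artifact_params(fs_raw = 500, noise_sd = 5e-4)

da <- run_experiment(cfg, behavior_preset("control"),
                     sensor_preset("grab_da"), art, n_sessions = 10,
                     seed = 801)
ach_ctrl <- run_experiment(cfg, behavior_preset("control"),
                           sensor_preset("ach3"), art, n_sessions = 10,
                           seed = 601)
ach_ko <- run_experiment(cfg, behavior_preset("vachtcko"),
                         sensor_preset("ach3"), art, n_sessions = 10,
                         seed = 701)

fits <- list(
  da_cs_vs_approach = regress_signal_vs_approach(
    da, "cs_mean", "mean", "delta", "delta_approach"),
  da_reward_vs_approach = regress_signal_vs_approach(
    da, "reward_auc", "auc", "plus_mean", "approach_plus"),
  ach_reward_vs_approach_control = regress_signal_vs_approach(
    ach_ctrl, "reward_auc", "auc", "plus_mean", "approach_plus"),
  ach_reward_vs_approach_vachtcko = regress_signal_vs_approach(
    ach_ko, "reward_auc", "auc", "plus_mean", "approach_plus"))

tab <- do.call(rbind, lapply(names(fits), function(nm) {
  f <- fits[[nm]]
  data.frame(analysis = nm, slope = f$slope, intercept = f$intercept,
             r_squared = f$r_squared, p_value = f$p_value, n = f$n)
}))
dir.create("results", showWarnings = FALSE)
write.csv(tab, "results/regressions.csv", row.names = FALSE)
print(tab, row.names = FALSE, digits = 3)

cat(sprintf(paste0("\nCS dopamine tracks approach (slope %.2f, R^2 %.2f);",
                   " reward dopamine fades as approach grows (slope %.2f).",
                   "\nThe ACh reward pause deepens with approach in",
                   " controls (slope %.2f) but not in VAChTcKO",
                   " (slope %.2f, R^2 %.2f).\n"),
            tab$slope[1], tab$r_squared[1], tab$slope[2], tab$slope[3],
            tab$slope[4], tab$r_squared[4]))
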