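#!/usr/bin/env Rscript
# One dopamine session through the full conditioning chain.
#
# Simulates a single study-scale session (40 trials, 10 s CS, ITI 45-90 s)
# of GRAB_DA recording at 1 kHz with photobleaching, shared motion
# artifacts and noise, then runs: decimation to 100 Hz -> 6 Hz zero-phase
# low-pass -> isosbestic least-squares fit -> dF/F -> peri-CS trial
# extraction (1 s baseline, 21 s window) -> baseline z-scores -> windowed
# metrics. Writes compact trial-average traces and per-trial metrics under
# results/; the full trial-by-trial heatmap goes to scratch/.

suppressPackageStartupMessages(library(photoshape))

cfg <- session_config(seed = 42)
par <- behavior_preset("control")
log <- simulate_session(cfg, par, session_index = 4)

set.seed(43)
art <- artifact_params()  # 1 kHz raw, bleaching + motion + noise defaults
trace <- simulate_photometry(log, sensor_preset("grab_da"), art,
                             L = learning_variable(par, 4))
cat(sprintf("Raw trace: %.0f min at %d Hz, %d TTL markers\n",
            length(trace$channels$sig_465) / art$fs_raw / 60, art$fs_raw,
            nrow(trace$ttl)))

pp <- preprocess_session(trace, log)
cat(sprintf("Isosbestic fit: slope %.4f, intercept %.3f\n",
            pp$fit$a, pp$fit$b))

m <- compute_trial_metrics(pp$tensor_z, log, default_window_specs("grab_da"))
b <- behavior_summary(log, cfg)

dir.create("results", showWarnings = FALSE)
dir.create("scratch", showWarnings = FALSE)
write.csv(m, "results/da_session_trial_metrics.csv", row.names = FALSE)

# full heatmap (40 trials x 2200 samples) is large -> scratch; a 10 Hz
# trial-average per CS type goes to results
hm <- heatmap_matrix(list(pp$tensor_z), "trial_by_trial")
write.csv(data.frame(time = hm$time, t(hm$matrix)),
          "scratch/da_session_heatmap.csv", row.names = FALSE)
ds <- seq(1, ncol(pp$tensor_z), by = 10)
avg <- data.frame(
  time = tensor_time(pp$tensor_z)[ds],
  cs_plus = colMeans(pp$tensor_z[attr(pp$tensor_z, "cs_type") == "plus",
                                 ds]),
  cs_minus = colMeans(pp$tensor_z[attr(pp$tensor_z, "cs_type") == "minus",
                                  ds]))
write.csv(avg, "results/da_session_trial_average.csv", row.names = FALSE)

mean_cs <- aggregate(value ~ cs_type, m[m$window == "cs_mean", ], mean)
auc <- aggregate(value ~ cs_type,
                 m[m$window == "reward_auc" & m$metric == "auc", ], mean,
                 na.rm = TRUE)
cat(sprintf("Mean CS z-score: CS+ %.2f vs CS- %.2f\n",
            mean_cs$value[mean_cs$cs_type == "plus"],
            mean_cs$value[mean_cs$cs_type == "minus"]))
cat(sprintf("Reward-window AUC (CS+ trials): %.2f z*s\n",
            auc$value[auc$cs_type == "plus"]))
cat(sprintf("Behaviour: CS+ approach %.1f s, CS- %.1f s, Delta %.1f s\n",
            b$per_cs$approach_time[1], b$per_cs$approach_time[2],
            b$delta_approach))
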