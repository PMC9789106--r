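# Example run configuration for run_pipeline() / read_run_config().
# Omitted keys fall back to the package defaults (the task constants:
# 20 trials per CS, 10 s CS, 45-90 s ITI, 60 min cap).
seed: 7
task:
  n_trials_per_cs: 4
  iti_min: 14
  iti_max: 18
  mode: deterministic
  n_sessions: 2
  phase: acquisition
behaviour:
  genotype: control
sensors:
  sensor: ach3
  artifacts:
    fs_raw: 500
preprocess:
  target_fs: 100
  cutoff_hz: 6
  baseline_s: 1
  window_pre_s: 1
  window_post_s: 21
paths:
  out_dir: scratch/example_run
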