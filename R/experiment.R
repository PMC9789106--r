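# Multi-session experiment driver: couples behaviour and sensor amplitudes
# through a shared per-session learning variable.

#' Per-session learning variable
#'
#' Fraction of learning completed by session `s` (0-based) of a phase:
#' `L_s = 1 - (1 - learn_rate)^s`. Because the behavioural expectation is
#' `init + (asym - init) * L_s`, both the approach behaviour and any kernel
#' amplitude with a `learning_gain` are linear in the same `L`, which is
#' what makes session-level signal-behaviour regressions meaningful.
#'
#' @param params A [behavior_params()].
#' @param session_index 0-based session index within the phase.
#' @return `L` in `[0, 1]`.
#' @export
learning_variable <- function(params, session_index) {
  stopifnot(inherits(params, "behavior_params"), session_index >= 0)
  1 - (1 - params$learn_rate)^session_index
}

#' Simulate and analyse a block of sessions end to end
#'
#' For each session: simulate the behavioural event log, synthesise the
#' photometry recording (with the session's learning variable scaling any
#' learning-coupled kernels), run the conditioning chain, quantify trials,
#' and summarise. Session `s` uses seed `seed + s`.
#'
#' @param config A [session_config()] template (its `seed` is overridden
#'   per session).
#' @param params A [behavior_params()].
#' @param model A [sensor_model()] (e.g. [sensor_preset()]).
#' @param art An [artifact_params()].
#' @param n_sessions Number of sessions in the block.
#' @param phase `"acquisition"` or `"reversal"`.
#' @param seed Base integer seed.
#' @param specs Window specs (default chosen by the model's preset name
#'   via [default_window_specs()] when recognised, else CS mean only).
#' @param genotype Genotype label applied to the sensor model; defaults to
#'   the behavioural `genotype_label`.
#' @param preprocess_args Named list of overrides for
#'   [preprocess_session()] (e.g. smaller `post_len`).
#' @param keep_tensors Keep each session's z-scored tensor (memory-heavy).
#' @return An `experiment_result`: list of per-session records
#'   (`log`, `summary`, optionally `tensor_z`) plus `params`, `phase`.
#' @export
run_experiment <- function(config, params, model, art,
                           n_sessions = 10, phase = "acquisition",
                           seed = 1, specs = NULL, genotype = NULL,
                           preprocess_args = list(),
                           keep_tensors = FALSE) {
  stopifnot(inherits(model, "sensor_model"))
  if (is.null(genotype)) genotype <- params$genotype_label
  if (is.null(specs)) {
    preset <- c(GRAB_DA = "grab_da", ACh3.0 = "ach3",
                `GCaMP6s-D1` = "gcamp_d1",
                `jRCaMP1a-D2` = "jrcamp_d2")[model$name]
    specs <- if (!is.na(preset))
      default_window_specs(preset, config$cs_duration)
    else list(window_spec("cs_mean", "cs_onset", 0, config$cs_duration,
                          "mean"))
  }
  sessions <- vector("list", n_sessions)
  for (s in seq_len(n_sessions) - 1L) {
    cfg <- config
    cfg$seed <- as.integer(seed + s)
    log <- simulate_session(cfg, params, session_index = s, phase = phase)
    L <- learning_variable(params, s)
    trace <- simulate_photometry(log, model, art, L = L,
                                 genotype = genotype)
    pp <- do.call(preprocess_session,
                  c(list(raw = trace, log = log), preprocess_args))
    metrics <- compute_trial_metrics(pp$tensor_z, log, specs)
    behav <- behavior_summary(log, cfg)
    summ <- summarize_session(metrics, behav, session_index = s,
                              phase = phase)
    rec <- list(log = log, summary = summ, L = L)
    if (keep_tensors) rec$tensor_z <- pp$tensor_z
    sessions[[s + 1L]] <- rec
  }
  structure(list(sessions = sessions, params = params, phase = phase,
                 genotype = genotype),
            class = "experiment_result")
}

#' Tidy table of per-session signal summaries
#'
#' @param res An `experiment_result`.
#' @return Data frame: `session_index`, `phase`, `genotype`, `window`,
#'   `metric`, `plus_mean`, `minus_mean`, `delta`.
#' @export
session_signal_table <- function(res) {
  stopifnot(inherits(res, "experiment_result"))
  do.call(rbind, lapply(res$sessions, function(se) {
    s <- se$summary
    cbind(data.frame(session_index = s$session_index, phase = s$phase,
                     genotype = res$genotype, stringsAsFactors = FALSE),
          s$signal)
  }))
}

#' Tidy table of per-session behaviour
#'
#' @param res An `experiment_result`.
#' @return Data frame: `session_index`, `phase`, `genotype`,
#'   `approach_plus`, `approach_minus`, `delta_approach`, `latency_mean`,
#'   `n_latency_missing`.
#' @export
session_behavior_table <- function(res) {
  stopifnot(inherits(res, "experiment_result"))
  do.call(rbind, lapply(res$sessions, function(se) {
    b <- se$summary$behaviour
    data.frame(session_index = se$summary$session_index,
               phase = se$summary$phase, genotype = res$genotype,
               approach_plus = b$per_cs$approach_time[1],
               approach_minus = b$per_cs$approach_time[2],
               delta_approach = b$delta_approach,
               latency_mean = b$latency_mean,
               n_latency_missing = b$n_latency_missing,
               stringsAsFactors = FALSE)
  }))
}

#' Regress a signal summary on approach behaviour across sessions
#'
#' Sessions are the regression unit. Typical uses: Delta CS-mean signal
#' vs Delta approach time (positive slope expected for dopamine in
#' controls) and CS+ reward AUC vs CS+ approach time (negative slope
#' expected for a reward response that fades with learning).
#'
#' @param res An `experiment_result`.
#' @param window,metric Which signal summary to use (e.g. `"cs_mean"`,
#'   `"mean"` or `"reward_auc"`, `"auc"`).
#' @param signal `"delta"` or `"plus_mean"` column of the signal table.
#' @param behaviour `"delta_approach"` or `"approach_plus"`.
#' @return A [linear_regression()] result.
#' @export
regress_signal_vs_approach <- function(res, window = "cs_mean",
                                       metric = "mean",
                                       signal = c("delta", "plus_mean"),
                                       behaviour = c("delta_approach",
                                                     "approach_plus")) {
  signal <- match.arg(signal)
  behaviour <- match.arg(behaviour)
  st <- session_signal_table(res)
  st <- st[st$window == window & st$metric == metric, ]
  bt <- session_behavior_table(res)
  m <- merge(st, bt, by = c("session_index", "phase", "genotype"))
  m <- m[order(m$session_index), ]
  linear_regression(m[[behaviour]], m[[signal]])
}
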