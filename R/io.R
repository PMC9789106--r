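# Plain-text readers/writers (event logs, traces, configs) and the
# end-to-end pipeline runner.

EVENT_LABELS <- c("trial_init", "cs_onset", "cs_offset", "reward_delivery",
                  "magazine_entry", "magazine_exit", "approach_enter",
                  "approach_exit")

#' Write / read a behavioural event log as tab-separated text
#'
#' Columns `timestamp` (seconds, microsecond precision), `event`,
#' `trial_index`, `cs_type`, `side`; missing fields are empty strings.
#' Reading validates the header, event labels and timestamp monotonicity,
#' reporting offending line numbers.
#'
#' @param log An `event_log` data frame.
#' @param path File path.
#' @return `write_event_log` returns `path` invisibly; `read_event_log`
#'   returns an `event_log`.
#' @export
write_event_log <- function(log, path) {
  df <- as.data.frame(log)
  df$timestamp <- sprintf("%.6f", df$timestamp)
  for (col in c("trial_index", "cs_type", "side"))
    df[[col]] <- ifelse(is.na(df[[col]]), "", as.character(df[[col]]))
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' @rdname write_event_log
#' @export
read_event_log <- function(path) {
  header <- strsplit(readLines(path, n = 1L), "\t")[[1]]
  expected <- c("timestamp", "event", "trial_index", "cs_type", "side")
  if (!identical(header, expected))
    stop("missing or malformed header in ", path,
         " (expected: ", paste(expected, collapse = ", "), ")")
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          colClasses = c("numeric", "character",
                                         "character", "character",
                                         "character"),
                          na.strings = "", stringsAsFactors = FALSE)
  bad <- which(!df$event %in% EVENT_LABELS)
  if (length(bad))
    stop("unknown event label '", df$event[bad[1]], "' at line ",
         bad[1] + 1L, " of ", path)
  drop <- which(diff(df$timestamp) < 0)
  if (length(drop))
    stop("non-monotone timestamp at line ", drop[1] + 2L, " of ", path)
  df$trial_index <- as.integer(df$trial_index)
  structure(df, class = c("event_log", "data.frame"))
}

ttl_sidecar_path <- function(path) {
  paste0(sub("\\.csv$", "", path), "_ttl.tsv")
}

#' Write / read a raw photometry trace as CSV with a TTL sidecar
#'
#' The main CSV holds `time` plus one column per channel (`ref_405`,
#' `sig_465`, optional `sig_560`); the TTL markers go to a sidecar TSV
#' (`<path minus .csv>_ttl.tsv`) with columns `timestamp`, `label`.
#'
#' @param trace A [raw_trace()].
#' @param path CSV file path.
#' @return `write_trace` returns `path` invisibly; `read_trace` returns a
#'   [raw_trace()].
#' @export
write_trace <- function(trace, path) {
  stopifnot(inherits(trace, "raw_trace"))
  df <- data.frame(time = trace_times(trace))
  for (nm in names(trace$channels)) df[[nm]] <- trace$channels[[nm]]
  utils::write.csv(format(df, digits = 15, trim = TRUE, scientific = FALSE),
                   path, row.names = FALSE, quote = FALSE)
  utils::write.table(trace$ttl, ttl_sidecar_path(path), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_trace
#' @export
read_trace <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!"time" %in% names(df)) stop("trace file lacks a time column")
  if (!"ref_405" %in% names(df))
    stop("trace file lacks the ref_405 reference channel")
  dt <- diff(df$time)
  if (length(dt) < 1 || any(abs(dt - dt[1]) > 1e-6))
    stop("trace time axis is not uniformly sampled")
  fs <- 1 / dt[1]
  ttl_path <- ttl_sidecar_path(path)
  ttl <- if (file.exists(ttl_path))
    utils::read.table(ttl_path, sep = "\t", header = TRUE,
                      colClasses = c("numeric", "character"))
  else data.frame(timestamp = numeric(), label = character())
  ch <- as.list(df[setdiff(names(df), "time")])
  raw_trace(round(fs, 6), ch, ttl)
}

run_config_sections <- function() list(
  task = c(names(formals(session_config)), "n_sessions", "phase"),
  behaviour = c("genotype", names(formals(behavior_params))),
  sensors = c("sensor", "artifacts", "channel"),
  preprocess = c("target_fs", "cutoff_hz", "baseline_s", "window_pre_s",
                 "window_post_s"),
  paths = c("out_dir"))

#' Read a run configuration from YAML
#'
#' Sections `task`, `behaviour`, `sensors`, `preprocess`, `paths` and the
#' top-level `seed`; unknown sections or keys are rejected. Missing keys
#' fall back to the package defaults.
#'
#' @param path YAML file path.
#' @return A `run_config` list.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  sections <- run_config_sections()
  unknown <- setdiff(names(cfg), c(names(sections), "seed"))
  if (length(unknown))
    stop("unknown config section(s): ", paste(unknown, collapse = ", "))
  for (sec in names(sections)) {
    bad <- setdiff(names(cfg[[sec]]), sections[[sec]])
    if (length(bad))
      stop("unknown key(s) in section '", sec, "': ",
           paste(bad, collapse = ", "))
  }
  if (!is.null(cfg$sensors$artifacts)) {
    bad <- setdiff(names(cfg$sensors$artifacts),
                   names(formals(artifact_params)))
    if (length(bad))
      stop("unknown key(s) in sensors$artifacts: ",
           paste(bad, collapse = ", "))
  }
  structure(cfg, class = "run_config")
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop("[", name, "] ", conditionMessage(e), call. = FALSE))
}

#' Run the full pipeline from a configuration
#'
#' Simulates the configured block of sessions, writes every intermediate
#' artifact (event logs, raw traces, trial metrics), the session summary
#' tables and a manifest recording the config hash, seed and package
#' version. Re-running with an identical config reproduces all numeric
#' outputs exactly. Session `s` uses seed `seed + s`.
#'
#' @param cfg A `run_config` (from [read_run_config()]) or a plain list of
#'   the same shape.
#' @param out_dir Output directory (default `cfg$paths$out_dir`).
#' @return The output directory, invisibly.
#' @export
run_pipeline <- function(cfg, out_dir = NULL) {
  if (is.null(out_dir)) out_dir <- cfg$paths$out_dir
  if (is.null(out_dir)) stop("[config] no output directory given")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  seed <- if (is.null(cfg$seed)) 1L else as.integer(cfg$seed)
  task <- cfg$task
  n_sessions <- if (is.null(task$n_sessions)) 1L
                else as.integer(task$n_sessions)
  phase <- if (is.null(task$phase)) "acquisition" else task$phase
  task[c("n_sessions", "phase")] <- NULL
  config <- stage("config", do.call(session_config, task))

  genotype <- if (is.null(cfg$behaviour$genotype)) "control"
              else cfg$behaviour$genotype
  bpar <- cfg$behaviour
  bpar$genotype <- NULL
  params <- stage("config", if (length(bpar)) do.call(behavior_params, bpar)
                  else behavior_preset(genotype))

  sensor <- if (is.null(cfg$sensors$sensor)) "grab_da" else cfg$sensors$sensor
  model <- stage("config", sensor_preset(sensor))
  art <- stage("config", do.call(artifact_params,
                                 c(cfg$sensors$artifacts)))
  pp <- cfg$preprocess
  pre_args <- list(
    target_fs = if (is.null(pp$target_fs)) 100 else pp$target_fs,
    cutoff = if (is.null(pp$cutoff_hz)) 6 else pp$cutoff_hz,
    baseline_len = if (is.null(pp$baseline_s)) 1 else pp$baseline_s,
    pre = if (is.null(pp$window_pre_s)) 1 else pp$window_pre_s,
    post_len = if (is.null(pp$window_post_s)) 21 else pp$window_post_s)
  specs <- default_window_specs(sensor, config$cs_duration)

  files <- character()
  all_signal <- list(); all_behav <- list(); all_metrics <- list()
  for (s in seq_len(n_sessions) - 1L) {
    cfg_s <- config
    cfg_s$seed <- seed + s
    tag <- sprintf("s%02d", s + 1L)
    log <- stage("simulate",
                 simulate_session(cfg_s, params, session_index = s,
                                  phase = phase))
    L <- learning_variable(params, s)
    trace <- stage("simulate",
                   simulate_photometry(log, model, art, L = L,
                                       genotype = genotype))
    f_log <- file.path(out_dir, paste0("events_", tag, ".tsv"))
    f_tr <- file.path(out_dir, paste0("trace_", tag, ".csv"))
    write_event_log(log, f_log)
    write_trace(trace, f_tr)
    proc <- stage("preprocess",
                  do.call(preprocess_session,
                          c(list(raw = trace, log = log), pre_args)))
    metrics <- stage("metrics",
                     compute_trial_metrics(proc$tensor_z, log, specs))
    behav <- stage("summarize", behavior_summary(log, cfg_s))
    summ <- stage("summarize",
                  summarize_session(metrics, behav, session_index = s,
                                    phase = phase))
    all_metrics[[tag]] <- cbind(session_index = s, genotype = genotype,
                                as.data.frame(metrics))
    all_signal[[tag]] <- cbind(
      data.frame(session_index = s, phase = phase, genotype = genotype,
                 stringsAsFactors = FALSE), summ$signal)
    all_behav[[tag]] <- data.frame(
      session_index = s, phase = phase, genotype = genotype,
      approach_plus = behav$per_cs$approach_time[1],
      approach_minus = behav$per_cs$approach_time[2],
      delta_approach = behav$delta_approach,
      latency_mean = behav$latency_mean,
      n_latency_missing = behav$n_latency_missing,
      stringsAsFactors = FALSE)
    files <- c(files, f_log, f_tr)
  }
  f_metrics <- file.path(out_dir, "trial_metrics.csv")
  f_signal <- file.path(out_dir, "session_signal.csv")
  f_behav <- file.path(out_dir, "session_behaviour.csv")
  utils::write.csv(do.call(rbind, all_metrics), f_metrics,
                   row.names = FALSE)
  utils::write.csv(do.call(rbind, all_signal), f_signal, row.names = FALSE)
  utils::write.csv(do.call(rbind, all_behav), f_behav, row.names = FALSE)
  files <- c(files, f_metrics, f_signal, f_behav)

  f_cfg <- file.path(out_dir, "config.yaml")
  yaml::write_yaml(unclass(cfg), f_cfg)
  manifest <- list(config_md5 = unname(tools::md5sum(f_cfg)),
                   seed = seed, n_sessions = n_sessions,
                   package_version =
                     as.character(utils::packageVersion("photoshape")),
                   files = basename(files))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(out_dir)
}
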