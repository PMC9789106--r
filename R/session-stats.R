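# Session-level aggregation: behavioural summaries, per-CS signal means
# and Delta(CS+ - CS-) contrasts, signal-behaviour regression, heatmaps.

pair_intervals <- function(enter, exit, t_end) {
  # pair alternating enter/exit times; close an unmatched final enter at
  # t_end
  if (length(exit) < length(enter)) exit <- c(exit, t_end)
  stopifnot(length(enter) == length(exit), all(exit >= enter))
  cbind(start = enter, end = exit)
}

interval_overlap <- function(ivs, lo, hi) {
  if (is.null(ivs) || !nrow(ivs)) return(0)
  sum(pmax(0, pmin(ivs[, "end"], hi) - pmax(ivs[, "start"], lo)))
}

#' Behavioural summary of one session
#'
#' The primary performance measure is the time spent in the approach zone
#' of the lit CS during its presentation: for each trial, the summed
#' overlap of approach intervals on the trial's side with the CS window,
#' totalled per CS type. Also computed: magazine time during the CS,
#' and per-trial reward-collection latency (first magazine entry after
#' reward delivery); rewards never collected are recorded as missing and
#' counted.
#'
#' @param log An `event_log`.
#' @param config The [session_config()] that generated the session (for
#'   the CS duration).
#' @return A `behavior_summary` list: `per_trial` data frame
#'   (`trial_index`, `cs_type`, `side`, `approach_time`, `magazine_time`,
#'   `collect_latency`), `per_cs` data frame (`cs_type`, `approach_time`,
#'   `magazine_time`), `delta_approach`, `latency_mean`,
#'   `n_latency_missing`.
#' @export
behavior_summary <- function(log, config) {
  stopifnot(inherits(config, "session_config"))
  cs_dur <- config$cs_duration
  t_end <- if (nrow(log)) max(log$timestamp) else 0
  onsets <- log[log$event == "cs_onset", , drop = FALSE]

  # approach intervals per side
  app <- lapply(c("left", "right"), function(sd) {
    ent <- log$timestamp[log$event == "approach_enter" & log$side == sd]
    ext <- log$timestamp[log$event == "approach_exit" & log$side == sd]
    pair_intervals(ent, ext, t_end)
  })
  names(app) <- c("left", "right")
  mag_ent <- log$timestamp[log$event == "magazine_entry"]
  mag_ext <- log$timestamp[log$event == "magazine_exit"]
  mag <- pair_intervals(mag_ent, mag_ext, t_end)

  per_trial <- do.call(rbind, lapply(seq_len(nrow(onsets)), function(i) {
    on <- onsets$timestamp[i]
    off <- on + cs_dur
    tr <- onsets$trial_index[i]
    lat <- NA_real_
    if (onsets$cs_type[i] == "plus") {
      rew <- log$timestamp[log$event == "reward_delivery" &
                           log$trial_index == tr]
      if (length(rew)) {
        entry <- mag_ent[mag_ent >= rew[1]]
        if (length(entry)) lat <- entry[1] - rew[1]
      }
    }
    data.frame(trial_index = tr, cs_type = onsets$cs_type[i],
               side = onsets$side[i],
               approach_time = interval_overlap(app[[onsets$side[i]]],
                                                on, off),
               magazine_time = interval_overlap(mag, on, off),
               collect_latency = lat, stringsAsFactors = FALSE)
  }))
  if (is.null(per_trial))
    per_trial <- data.frame(trial_index = integer(), cs_type = character(),
                            side = character(), approach_time = numeric(),
                            magazine_time = numeric(),
                            collect_latency = numeric())
  agg <- function(cs) {
    sel <- per_trial$cs_type == cs
    data.frame(cs_type = cs,
               approach_time = sum(per_trial$approach_time[sel]),
               magazine_time = sum(per_trial$magazine_time[sel]),
               stringsAsFactors = FALSE)
  }
  per_cs <- rbind(agg("plus"), agg("minus"))
  lats <- per_trial$collect_latency[per_trial$cs_type == "plus"]
  structure(list(
    per_trial = per_trial, per_cs = per_cs,
    delta_approach = per_cs$approach_time[1] - per_cs$approach_time[2],
    latency_mean = if (any(!is.na(lats))) mean(lats, na.rm = TRUE)
                   else NA_real_,
    n_latency_missing = sum(is.na(lats)),
    cs_duration = cs_dur,
    genotype = attr(log, "genotype")), class = "behavior_summary")
}

#' Summarise one session's signal metrics and behaviour
#'
#' Per-CS means over trials of every (window, metric) pair from
#' [compute_trial_metrics()], their Delta (CS+ mean minus CS- mean), and
#' the session's behavioural summary.
#'
#' @param metrics A `trial_metrics` data frame.
#' @param behaviour A [behavior_summary()] from the same session.
#' @param session_index 0-based session index within the phase.
#' @param phase `"acquisition"` or `"reversal"`.
#' @return A `session_summary` list: `signal` data frame (`window`,
#'   `metric`, `plus_mean`, `minus_mean`, `delta`), plus `behaviour`,
#'   `session_index`, `phase`, `genotype`.
#' @export
summarize_session <- function(metrics, behaviour, session_index = 0,
                              phase = "acquisition") {
  stopifnot(inherits(metrics, "trial_metrics"),
            inherits(behaviour, "behavior_summary"))
  key <- unique(metrics[, c("window", "metric")])
  sig <- do.call(rbind, lapply(seq_len(nrow(key)), function(i) {
    sel <- metrics$window == key$window[i] & metrics$metric == key$metric[i]
    v <- metrics[sel, ]
    pm <- function(cs) {
      x <- v$value[v$cs_type == cs]
      if (!length(x)) stop("no trials of cs_type '", cs, "' to summarise")
      mean(x, na.rm = TRUE)
    }
    p <- pm("plus"); m <- pm("minus")
    data.frame(window = key$window[i], metric = key$metric[i],
               plus_mean = p, minus_mean = m, delta = p - m,
               stringsAsFactors = FALSE)
  }))
  structure(list(signal = sig, behaviour = behaviour,
                 session_index = session_index, phase = phase,
                 genotype = behaviour$genotype),
            class = "session_summary")
}

#' Simple linear regression with slope test
#'
#' Ordinary least squares of `y` on `x`; `r_squared` is the squared
#' Pearson correlation and `p_value` the two-sided test on the slope's t
#' statistic with `n - 2` degrees of freedom.
#'
#' @param x,y Numeric vectors of equal length >= 3; `x` must vary.
#' @return A `regression_result` list: `slope`, `intercept`, `r_squared`,
#'   `p_value`, `n`.
#' @export
linear_regression <- function(x, y) {
  if (length(x) != length(y)) stop("x and y lengths differ")
  if (length(x) < 3) stop("need at least 3 points")
  if (stats::var(x) == 0) stop("degenerate regressor: x is constant")
  if (stats::var(y) == 0)
    return(structure(list(slope = 0, intercept = mean(y), r_squared = 0,
                          p_value = 1, n = length(x)),
                     class = "regression_result"))
  fit <- stats::lm(y ~ x)
  sm <- suppressWarnings(summary(fit))  # exact fits are legitimate inputs
  structure(list(slope = unname(stats::coef(fit)[2]),
                 intercept = unname(stats::coef(fit)[1]),
                 r_squared = sm$r.squared,
                 p_value = unname(sm$coefficients[2, 4]),
                 n = length(x)),
            class = "regression_result")
}

#' Stack trial tensors into a heatmap matrix
#'
#' `trial_by_trial` stacks all matching rows in session order then trial
#' order (e.g. 10 acquisition sessions x 20 CS+ trials give rows 1-200);
#' `session_average` emits one mean row per session.
#'
#' @param tensors List of `trial_tensor` objects in session order.
#' @param mode `"trial_by_trial"` or `"session_average"`.
#' @param cs_type `"plus"`, `"minus"` or `"both"`.
#' @return List with `matrix` and `time` (seconds relative to anchor).
#' @export
heatmap_matrix <- function(tensors,
                           mode = c("trial_by_trial", "session_average"),
                           cs_type = "both") {
  mode <- match.arg(mode)
  stopifnot(length(tensors) >= 1,
            all(vapply(tensors, inherits, TRUE, "trial_tensor")))
  nc <- vapply(tensors, ncol, 1L)
  fs <- vapply(tensors, function(t) attr(t, "fs"), 1)
  t0 <- vapply(tensors, function(t) attr(t, "t0_offset"), 1)
  if (length(unique(nc)) != 1L || length(unique(fs)) != 1L ||
      length(unique(t0)) != 1L)
    stop("window mismatch: tensors differ in fs or window extent")
  pick <- function(t) {
    if (cs_type == "both") return(t[, , drop = FALSE])
    t[attr(t, "cs_type") == cs_type, , drop = FALSE]
  }
  mat <- switch(mode,
    trial_by_trial = do.call(rbind, lapply(tensors, pick)),
    session_average = do.call(rbind, lapply(tensors, function(t)
      colMeans(pick(t)))))
  list(matrix = mat, time = tensor_time(tensors[[1]]))
}
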