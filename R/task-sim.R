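# Touchscreen autoshaping task: session configuration, trial scheduling and
# behavioural event-log simulation.

#' Session configuration for the autoshaping task
#'
#' Holds the task constants of a single autoshaping session: 40 trials
#' (20 per CS contingency) presented pseudorandomly with no more than
#' `max_run` identical CS types in a row, a 10 s CS, a variable 45-90 s
#' inter-trial interval, and a 60 min session cap.
#'
#' @param n_trials_per_cs Number of trials of each CS type (default 20).
#' @param cs_duration CS presentation length in seconds (default 10).
#' @param iti_min,iti_max Bounds of the uniform inter-trial interval in
#'   seconds (defaults 45 and 90).
#' @param reward_volume Reward volume in microlitres (default 10); recorded
#'   for provenance, not used by the dynamics.
#' @param session_cap Maximum session length in minutes (default 60).
#' @param mode Scheduling mode: `"deterministic"` (CS+ side fixed),
#'   `"reversal"` (CS+ presented at the opposite side), or
#'   `"non_deterministic"` (side of each trial drawn at random, 50/50).
#' @param cs_plus_side Screen side bearing the CS+ in deterministic mode
#'   (`"left"` or `"right"`); ignored in non-deterministic mode.
#' @param max_run Longest permitted run of identical CS types (default 2).
#' @param seed Optional integer seed; when set, [simulate_session()] is
#'   fully reproducible.
#' @return An object of class `session_config` (a validated list).
#' @export
session_config <- function(n_trials_per_cs = 20, cs_duration = 10,
                           iti_min = 45, iti_max = 90,
                           reward_volume = 10, session_cap = 60,
                           mode = c("deterministic", "reversal",
                                    "non_deterministic"),
                           cs_plus_side = c("right", "left"),
                           max_run = 2, seed = NULL) {
  mode <- match.arg(mode)
  cs_plus_side <- match.arg(cs_plus_side)
  stopifnot(n_trials_per_cs >= 1, cs_duration > 0,
            iti_min > 0, iti_min <= iti_max,
            session_cap > 0, max_run >= 1)
  structure(list(n_trials_per_cs = as.integer(n_trials_per_cs),
                 cs_duration = cs_duration,
                 iti_min = iti_min, iti_max = iti_max,
                 reward_volume = reward_volume,
                 session_cap = session_cap,
                 mode = mode, cs_plus_side = cs_plus_side,
                 max_run = as.integer(max_run),
                 seed = if (!is.null(seed)) as.integer(seed)),
            class = "session_config")
}

#' Behavioural parameters of the simulated learning agent
#'
#' Parametric agent whose expected approach fraction follows an exponential
#' acquisition law toward CS-type-specific asymptotes (see
#' [learning_curve()]). All fractions are of the CS window.
#'
#' @param init_approach_frac Approach fraction on session 0.
#' @param asym_plus,asym_minus Asymptotic approach fractions for CS+ / CS-.
#' @param learn_rate Per-session learning rate in `[0, 1]`.
#' @param approach_noise_sd SD of the per-trial Gaussian jitter around the
#'   session's expected approach fraction (truncated to `[0, 1]`).
#' @param collect_latency_mean,collect_latency_sd Mean and SD (seconds) of
#'   the log-normal reward-collection latency.
#' @param genotype_label Free-text label carried through to summaries.
#' @return An object of class `behavior_params`.
#' @export
behavior_params <- function(init_approach_frac = 0.25,
                            asym_plus = 0.70, asym_minus = 0.10,
                            learn_rate = 0.35, approach_noise_sd = 0.08,
                            collect_latency_mean = 1.5,
                            collect_latency_sd = 0.8,
                            genotype_label = "control") {
  fr <- c(init_approach_frac, asym_plus, asym_minus, learn_rate)
  stopifnot(all(fr >= 0), all(fr <= 1),
            approach_noise_sd >= 0,
            collect_latency_mean > 0, collect_latency_sd > 0)
  structure(list(init_approach_frac = init_approach_frac,
                 asym_plus = asym_plus, asym_minus = asym_minus,
                 learn_rate = learn_rate,
                 approach_noise_sd = approach_noise_sd,
                 collect_latency_mean = collect_latency_mean,
                 collect_latency_sd = collect_latency_sd,
                 genotype_label = genotype_label),
            class = "behavior_params")
}

#' Behavioural presets by genotype
#'
#' `control` acquires a strong CS+/CS- discrimination; `vachtcko`
#' (impaired acetylcholine release from cholinergic interneurons) keeps a
#' near-zero approach difference throughout acquisition; `vglut3cko`
#' (impaired glutamate co-release) behaves like controls.
#'
#' @param genotype One of `"control"`, `"vachtcko"`, `"vglut3cko"`.
#' @return A [behavior_params()] object.
#' @export
behavior_preset <- function(genotype = c("control", "vachtcko", "vglut3cko")) {
  genotype <- match.arg(genotype)
  switch(genotype,
    control = behavior_params(genotype_label = "control"),
    vachtcko = behavior_params(init_approach_frac = 0.25,
                               asym_plus = 0.28, asym_minus = 0.24,
                               learn_rate = 0.15,
                               genotype_label = "vachtcko"),
    vglut3cko = behavior_params(genotype_label = "vglut3cko"))
}

# Feasibility of the run-length constraint for counts (n_a, n_b):
# the larger count must fit into the slots left by the smaller.
schedule_feasible <- function(n_a, n_b, max_run) {
  max(n_a, n_b) <= max_run * (min(n_a, n_b) + 1L)
}

max_run_length <- function(x) max(rle(as.character(x))$lengths)

# Completion counts for run-constrained binary sequences.
# counts[p+1, m+1, last, run] = number of valid ways to lay down p more
# "plus" and m more "minus" trials when the current run is `run` trials of
# type `last` (1 = plus, 2 = minus). Built bottom-up; the totals fit
# exactly in doubles for any session size used here (~1e8 at 20+20).
run_constrained_counts <- function(n, max_run) {
  counts <- array(0, dim = c(n + 1L, n + 1L, 2L, max_run))
  counts[1L, 1L, , ] <- 1
  for (p in 0:n) for (m in 0:n) {
    if (p == 0L && m == 0L) next
    for (last in 1:2) for (run in seq_len(max_run)) {
      tot <- 0
      if (p > 0L) {  # place a plus next
        if (last != 1L) tot <- tot + counts[p, m + 1L, 1L, 1L]
        else if (run < max_run) tot <- tot + counts[p, m + 1L, 1L, run + 1L]
      }
      if (m > 0L) {  # place a minus next
        if (last != 2L) tot <- tot + counts[p + 1L, m, 2L, 1L]
        else if (run < max_run) tot <- tot + counts[p + 1L, m, 2L, run + 1L]
      }
      counts[p + 1L, m + 1L, last, run] <- tot
    }
  }
  counts
}

# cache count tables per (n, max_run)
count_cache <- new.env(parent = emptyenv())

get_counts <- function(n, max_run) {
  key <- paste(n, max_run, sep = "_")
  if (is.null(count_cache[[key]]))
    count_cache[[key]] <- run_constrained_counts(n, max_run)
  count_cache[[key]]
}

#' Schedule the CS sequence of one session
#'
#' Draws a pseudorandom trial order with exactly `n_trials_per_cs` trials
#' of each CS type and no run of identical CS types longer than
#' `config$max_run`, uniformly over all orderings satisfying the
#' constraint. The draw is exact: each position is sampled with
#' probability proportional to the number of valid completions
#' (precomputed by dynamic programming), which reproduces the uniform
#' distribution over valid sequences without rejection. Screen sides
#' follow the mode: deterministic puts the CS+ at `cs_plus_side`, reversal
#' at the opposite side, and non-deterministic draws each trial's side
#' independently with probability 1/2.
#'
#' @param config A [session_config()].
#' @return A data frame (`trial_schedule`) with columns `trial_index`,
#'   `cs_type` (`"plus"`/`"minus"`) and `side` (`"left"`/`"right"`).
#' @export
schedule_trials <- function(config) {
  stopifnot(inherits(config, "session_config"))
  n <- config$n_trials_per_cs
  if (!schedule_feasible(n, n, config$max_run))
    stop("unsatisfiable schedule: max_run = ", config$max_run,
         " too small for ", n, " trials per CS type")
  counts <- get_counts(n, config$max_run)
  max_run <- config$max_run
  cs <- character(2L * n)
  p <- n; m <- n; last <- 0L; run <- 0L
  for (i in seq_len(2L * n)) {
    # completions if the next trial is plus / minus
    w_plus <- if (p == 0L || (last == 1L && run >= max_run)) 0
      else counts[p, m + 1L, 1L, if (last == 1L) run + 1L else 1L]
    w_minus <- if (m == 0L || (last == 2L && run >= max_run)) 0
      else counts[p + 1L, m, 2L, if (last == 2L) run + 1L else 1L]
    take_plus <- stats::runif(1L) * (w_plus + w_minus) < w_plus
    if (take_plus) {
      cs[i] <- "plus"
      run <- if (last == 1L) run + 1L else 1L
      last <- 1L; p <- p - 1L
    } else {
      cs[i] <- "minus"
      run <- if (last == 2L) run + 1L else 1L
      last <- 2L; m <- m - 1L
    }
  }
  side <- switch(config$mode,
    deterministic = ifelse(cs == "plus", config$cs_plus_side,
                           other_side(config$cs_plus_side)),
    reversal = ifelse(cs == "plus", other_side(config$cs_plus_side),
                      config$cs_plus_side),
    non_deterministic = sample(c("left", "right"), 2L * n, replace = TRUE))
  structure(data.frame(trial_index = seq_len(2L * n),
                       cs_type = cs, side = side,
                       stringsAsFactors = FALSE),
            class = c("trial_schedule", "data.frame"))
}

other_side <- function(side) ifelse(side == "left", "right", "left")

#' Draw one inter-trial interval
#'
#' Uniform on `[iti_min, iti_max]` seconds.
#'
#' @param config A [session_config()].
#' @return ITI in seconds.
#' @export
sample_iti <- function(config) {
  stopifnot(inherits(config, "session_config"))
  stats::runif(1L, config$iti_min, config$iti_max)
}

#' Expected approach fraction across training
#'
#' Exponential acquisition law: on session `s` (0-based) of acquisition the
#' expected fraction of the CS window spent approaching is
#' `m_s = asym + (init - asym) * (1 - learn_rate)^s`, with `asym` chosen by
#' CS type. On entry into reversal the CS roles swap and the curve restarts
#' from the pre-reversal value of the swapped stimulus, relaxing toward the
#' asymptote of the new role.
#'
#' @param params A [behavior_params()].
#' @param session_index 0-based session index within the phase.
#' @param phase `"acquisition"` or `"reversal"`.
#' @param cs_type `"plus"` or `"minus"` (the trial's current role).
#' @param n_acquisition Number of acquisition sessions preceding reversal
#'   (default 10), used to locate the pre-reversal starting values.
#' @return Expected approach fraction in `[0, 1]`.
#' @export
learning_curve <- function(params, session_index,
                           phase = c("acquisition", "reversal"),
                           cs_type = c("plus", "minus"),
                           n_acquisition = 10) {
  stopifnot(inherits(params, "behavior_params"), session_index >= 0)
  phase <- match.arg(phase)
  cs_type <- match.arg(cs_type)
  asym <- if (cs_type == "plus") params$asym_plus else params$asym_minus
  decay <- (1 - params$learn_rate)^session_index
  if (phase == "acquisition") {
    m <- asym + (params$init_approach_frac - asym) * decay
  } else {
    # restart from the last-acquisition value of the *swapped* stimulus
    swapped <- if (cs_type == "plus") "minus" else "plus"
    start <- learning_curve(params, n_acquisition - 1, "acquisition", swapped,
                            n_acquisition)
    m <- asym + (start - asym) * decay
  }
  min(max(m, 0), 1)
}

rlnorm_ms <- function(n, mean, sd) {
  # log-normal parameterised by its arithmetic mean and sd
  cv2 <- (sd / mean)^2
  sdlog <- sqrt(log1p(cv2))
  meanlog <- log(mean) - sdlog^2 / 2
  stats::rlnorm(n, meanlog, sdlog)
}

#' Simulate one autoshaping session as an event log
#'
#' Generates the full behavioural event stream of a session: for each
#' scheduled trial an ITI, a trial initiation (back-beam break), CS onset
#' and offset; after each CS+ offset a reward delivery followed by a
#' magazine entry/exit at a log-normal collection latency; and per-trial
#' approach-zone beam crossings on the lit side whose total duration within
#' the CS window is a truncated Gaussian draw around [learning_curve()].
#' The session ends after all trials or at `session_cap`, whichever comes
#' first. With `config$seed` set the log is fully deterministic.
#'
#' @param config A [session_config()].
#' @param params A [behavior_params()].
#' @param session_index 0-based session index within `phase`.
#' @param phase `"acquisition"` or `"reversal"`.
#' @param n_acquisition Acquisition sessions before reversal (default 10).
#' @return An `event_log` data frame with columns `timestamp` (s from
#'   session start), `event`, `trial_index`, `cs_type`, `side`.
#' @export
simulate_session <- function(config, params, session_index = 0,
                             phase = c("acquisition", "reversal"),
                             n_acquisition = 10) {
  stopifnot(inherits(config, "session_config"),
            inherits(params, "behavior_params"))
  phase <- match.arg(phase)
  if (!is.null(config$seed)) set.seed(config$seed)
  sched <- schedule_trials(config)
  cap <- config$session_cap * 60
  cs_dur <- config$cs_duration

  m <- list(plus = learning_curve(params, session_index, phase, "plus",
                                  n_acquisition),
            minus = learning_curve(params, session_index, phase, "minus",
                                   n_acquisition))
  rows <- vector("list", nrow(sched) * 8L)
  k <- 0L
  add <- function(ts, ev, tr, cs, side) {
    k <<- k + 1L
    rows[[k]] <<- list(timestamp = ts, event = ev, trial_index = tr,
                       cs_type = cs, side = side)
  }
  t_now <- 0
  for (i in seq_len(nrow(sched))) {
    iti <- sample_iti(config)
    onset <- t_now + iti
    offset <- onset + cs_dur
    if (offset > cap) break  # session cap: drop trials that cannot complete
    tr <- sched$trial_index[i]
    cs <- sched$cs_type[i]
    side <- sched$side[i]
    add(onset, "trial_init", tr, cs, side)
    add(onset, "cs_onset", tr, cs, side)

    # approach bout on the lit side within the CS window
    frac <- stats::rnorm(1L, m[[cs]], params$approach_noise_sd)
    frac <- min(max(frac, 0), 1)
    dur <- frac * cs_dur
    if (dur > 0) {
      a_start <- onset + stats::runif(1L, 0, cs_dur - dur)
      add(a_start, "approach_enter", tr, cs, side)
      add(a_start + dur, "approach_exit", tr, cs, side)
    }
    add(offset, "cs_offset", tr, cs, side)
    t_end <- offset
    if (cs == "plus") {
      add(offset, "reward_delivery", tr, cs, side)
      lat <- rlnorm_ms(1L, params$collect_latency_mean,
                       params$collect_latency_sd)
      entry <- offset + lat
      dwell <- rlnorm_ms(1L, 1.2, 0.5)
      add(entry, "magazine_entry", tr, cs, side)
      add(entry + dwell, "magazine_exit", tr, cs, side)
      t_end <- entry + dwell  # new ITI begins once the mouse pulls away
    }
    t_now <- t_end
  }
  ev <- do.call(rbind.data.frame, rows[seq_len(k)])
  ev <- ev[order(ev$timestamp, ev$trial_index), , drop = FALSE]
  rownames(ev) <- NULL
  structure(ev, class = c("event_log", "data.frame"),
            cs_duration = cs_dur, session_index = session_index,
            phase = phase, genotype = params$genotype_label)
}

#' Recover the learning rate from per-session approach fractions
#'
#' Fits the exponential acquisition law
#' `m_s = asym + (init - asym) * (1 - rate)^s` to per-session mean approach
#' fractions by nonlinear least squares (with a grid-initialised
#' `optim` fallback when `nls` fails to converge).
#'
#' @param frac Vector of mean approach fractions for sessions `0..S-1`.
#' @return List with `init`, `asym`, `learn_rate` and `fitted`.
#' @export
fit_learning_curve <- function(frac) {
  stopifnot(length(frac) >= 4, all(is.finite(frac)))
  s <- seq_along(frac) - 1
  sse <- function(p) {
    m <- p[2] + (p[1] - p[2]) * (1 - p[3])^s
    sum((frac - m)^2)
  }
  fit <- tryCatch({
    nl <- stats::nls(frac ~ asym + (init - asym) * (1 - rate)^s,
                     start = list(init = frac[1], asym = frac[length(frac)],
                                  rate = 0.3),
                     lower = c(0, 0, 1e-4), upper = c(1, 1, 1),
                     algorithm = "port",
                     control = stats::nls.control(warnOnly = TRUE))
    co <- stats::coef(nl)
    c(co[["init"]], co[["asym"]], co[["rate"]])
  }, error = function(e) {
    best <- NULL
    for (r0 in seq(0.05, 0.95, by = 0.1)) {
      op <- stats::optim(c(frac[1], frac[length(frac)], r0), sse,
                         method = "L-BFGS-B",
                         lower = c(0, 0, 1e-4), upper = c(1, 1, 1))
      if (is.null(best) || op$value < best$value) best <- op
    }
    best$par
  })
  list(init = fit[1], asym = fit[2], learn_rate = fit[3],
       fitted = fit[2] + (fit[1] - fit[2]) * (1 - fit[3])^s)
}
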