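# Synthetic multi-channel fibre-photometry traces: event-locked sensor
# kernels superposed on shared photobleaching / motion artifacts and noise.

#' Event-locked sensor response kernel
#'
#' A double-exponential transient anchored at a behavioural event:
#' zero before `delay`, then
#' `sign * A_eff * (1 - exp(-(t - delay)/rise_tau)) * exp(-(t - delay)/decay_tau)`
#' with `A_eff = amplitude * (1 + learning_gain * L)` clipped at 0, where
#' `L` is the per-session learning variable. `anchor = "cs_window"` kernels
#' are instead held constant at `sign * A_eff` over the CS interval.
#'
#' @param anchor Event the kernel locks to: `"cs_onset"`, `"cs_offset"`,
#'   `"reward_delivery"` or `"cs_window"`.
#' @param cs_filter Which trials trigger it: `"plus"`, `"minus"`, `"both"`.
#' @param sign `+1` (transient increase) or `-1` (pause/dip).
#' @param amplitude Peak-scale amplitude in dF/F units (>= 0).
#' @param delay Onset latency after the anchor event (s).
#' @param rise_tau,decay_tau Rise and decay time constants (s), > 0.
#' @param learning_gain Slope coupling the effective amplitude to the
#'   session learning variable `L` (negative values shrink the response as
#'   learning progresses).
#' @return A `sensor_kernel` object.
#' @export
sensor_kernel <- function(anchor = c("cs_onset", "cs_offset",
                                     "reward_delivery", "cs_window"),
                          cs_filter = c("both", "plus", "minus"),
                          sign = 1, amplitude = 0.02, delay = 0,
                          rise_tau = 0.1, decay_tau = 0.5,
                          learning_gain = 0) {
  anchor <- match.arg(anchor)
  cs_filter <- match.arg(cs_filter)
  stopifnot(sign %in% c(-1, 1), amplitude >= 0,
            rise_tau > 0, decay_tau > 0, delay >= 0)
  structure(list(anchor = anchor, cs_filter = cs_filter, sign = sign,
                 amplitude = amplitude, delay = delay,
                 rise_tau = rise_tau, decay_tau = decay_tau,
                 learning_gain = learning_gain),
            class = "sensor_kernel")
}

#' Evaluate a kernel at times relative to its anchor
#'
#' @param k A [sensor_kernel()].
#' @param t_rel Seconds since the anchor event (vectorised).
#' @param L Session learning variable (default 0).
#' @return dF/F contribution at each `t_rel`.
#' @export
kernel_response <- function(k, t_rel, L = 0) {
  stopifnot(inherits(k, "sensor_kernel"))
  a_eff <- max(0, k$amplitude * (1 + k$learning_gain * L))
  tt <- t_rel - k$delay
  out <- numeric(length(t_rel))
  on <- tt >= 0
  out[on] <- k$sign * a_eff *
    (1 - exp(-tt[on] / k$rise_tau)) * exp(-tt[on] / k$decay_tau)
  out
}

#' Sensor model: a named repertoire of kernels with genotype scalers
#'
#' @param name Sensor label (e.g. `"GRAB_DA"`, `"ACh3.0"`).
#' @param kernels Named list of [sensor_kernel()] objects.
#' @param genotype_scalers Named list (genotype -> named numeric multipliers
#'   keyed by kernel name); kernels not listed keep multiplier 1.
#' @return A `sensor_model` object.
#' @export
sensor_model <- function(name, kernels, genotype_scalers = list()) {
  stopifnot(length(kernels) >= 1,
            all(vapply(kernels, inherits, TRUE, "sensor_kernel")),
            !is.null(names(kernels)), all(nzchar(names(kernels))))
  for (g in genotype_scalers) stopifnot(all(unlist(g) >= 0))
  structure(list(name = name, kernels = kernels,
                 genotype_scalers = genotype_scalers),
            class = "sensor_model")
}

#' Built-in sensor presets
#'
#' Response repertoires emulating the recorded dynamics:
#' \describe{
#'   \item{`grab_da`}{Dopamine: ~1 s phasic CS-onset response to both CS
#'     plus a CS+-specific component that grows with learning; reward
#'     response whose amplitude decays as learning progresses.}
#'   \item{`ach3`}{Acetylcholine: ~1 s phasic onset response to both CS; a
#'     5-8 s reward-evoked pause (negative) that deepens with learning and
#'     is abolished in `vachtcko`; a CS+-offset phasic response, also
#'     impaired in `vachtcko`.}
#'   \item{`gcamp_d1`}{D1-SPN calcium: bi-phasic reward burst then pause.}
#'   \item{`jrcamp_d2`}{D2-SPN calcium: monophasic reward response.}
#' }
#'
#' @param sensor One of `"grab_da"`, `"ach3"`, `"gcamp_d1"`, `"jrcamp_d2"`.
#' @return A [sensor_model()].
#' @export
sensor_preset <- function(sensor = c("grab_da", "ach3", "gcamp_d1",
                                     "jrcamp_d2")) {
  sensor <- match.arg(sensor)
  switch(sensor,
    grab_da = sensor_model("GRAB_DA", list(
      cs_onset = sensor_kernel("cs_onset", "both", +1, amplitude = 0.010,
                               rise_tau = 0.10, decay_tau = 0.35),
      # sustained CS+ response that grows with learning; smooth rise and a
      # decay shorter than the CS so it has faded by reward time
      cs_plus_learned = sensor_kernel("cs_onset", "plus", +1,
                                      amplitude = 0.006,
                                      rise_tau = 0.4, decay_tau = 3,
                                      learning_gain = 2.0),
      # reward response peaking ~1 s after delivery, fading with learning
      reward = sensor_kernel("reward_delivery", "plus", +1,
                             amplitude = 0.030, delay = 0.1,
                             rise_tau = 0.5, decay_tau = 1.5,
                             learning_gain = -0.8))),
    ach3 = sensor_model("ACh3.0", list(
      cs_onset = sensor_kernel("cs_onset", "both", +1, amplitude = 0.008,
                               rise_tau = 0.08, decay_tau = 0.30),
      cs_plus_offset = sensor_kernel("cs_offset", "plus", +1,
                                     amplitude = 0.008,
                                     rise_tau = 0.08, decay_tau = 0.30),
      # 5-8 s reward-evoked pause, trough ~2 s after delivery, deepening
      # with learning
      reward_pause = sensor_kernel("reward_delivery", "plus", -1,
                                   amplitude = 0.020, delay = 0.5,
                                   rise_tau = 1.2, decay_tau = 2.2,
                                   learning_gain = 0.8)),
      genotype_scalers = list(
        vachtcko = list(reward_pause = 0, cs_plus_offset = 0.2))),
    gcamp_d1 = sensor_model("GCaMP6s-D1", list(
      cs_onset = sensor_kernel("cs_onset", "both", +1, amplitude = 0.010,
                               rise_tau = 0.15, decay_tau = 0.6),
      reward_burst = sensor_kernel("reward_delivery", "plus", +1,
                                   amplitude = 0.025, delay = 0.1,
                                   rise_tau = 0.2, decay_tau = 0.8),
      reward_pause = sensor_kernel("reward_delivery", "plus", -1,
                                   amplitude = 0.012, delay = 1.8,
                                   rise_tau = 0.6, decay_tau = 2.0))),
    jrcamp_d2 = sensor_model("jRCaMP1a-D2", list(
      cs_onset = sensor_kernel("cs_onset", "both", +1, amplitude = 0.008,
                               rise_tau = 0.15, decay_tau = 0.6),
      reward = sensor_kernel("reward_delivery", "plus", +1,
                             amplitude = 0.020, delay = 0.2,
                             rise_tau = 0.3, decay_tau = 1.2))))
}

#' Apply a genotype's kernel scalers to a sensor model
#'
#' @param model A [sensor_model()].
#' @param genotype Genotype label; unknown labels leave the model unchanged.
#' @return The scaled [sensor_model()].
#' @export
apply_genotype <- function(model, genotype) {
  stopifnot(inherits(model, "sensor_model"))
  sc <- model$genotype_scalers[[genotype]]
  if (is.null(sc)) return(model)
  for (nm in names(sc)) {
    if (!nm %in% names(model$kernels))
      stop("genotype scaler refers to unknown kernel: ", nm)
    model$kernels[[nm]]$amplitude <- model$kernels[[nm]]$amplitude * sc[[nm]]
  }
  model
}

#' Artifact parameters of the raw recording
#'
#' Magnitudes of the processes the isosbestic correction exists to remove:
#' a shared single-exponential photobleaching trend, shared multiplicative
#' motion transients, and independent white noise per channel. Defaults are
#' stated choices about a plausible recording, not measurements.
#'
#' @param f0_ref,f0_sig Baseline fluorescence of the reference (405 nm) and
#'   signal channels (arbitrary units).
#' @param bleach_tau Bleaching time constant (s).
#' @param bleach_frac Asymptotic fraction of F0 lost to bleaching, `[0, 1)`.
#' @param motion_rate Motion transients per minute.
#' @param motion_amp_sd SD of motion transient amplitude (fraction of F0).
#' @param noise_sd White-noise SD (fraction of F0).
#' @param fs_raw Raw sampling rate in Hz (default 1000).
#' @return An `artifact_params` object.
#' @export
artifact_params <- function(f0_ref = 80, f0_sig = 120,
                            bleach_tau = 1200, bleach_frac = 0.2,
                            motion_rate = 2, motion_amp_sd = 0.01,
                            noise_sd = 0.002, fs_raw = 1000) {
  stopifnot(f0_ref > 0, f0_sig > 0, bleach_tau > 0,
            bleach_frac >= 0, bleach_frac < 1,
            motion_rate >= 0, motion_amp_sd >= 0, noise_sd >= 0, fs_raw > 0)
  structure(as.list(environment()), class = "artifact_params")
}

#' Construct a raw multi-channel trace container
#'
#' @param fs Sampling rate (Hz).
#' @param channels Named list of equal-length numeric vectors; must include
#'   `ref_405` and at least one signal channel (`sig_465`, optionally
#'   `sig_560`).
#' @param ttl Data frame with `timestamp` and `label` columns.
#' @return A `raw_trace` object.
#' @export
raw_trace <- function(fs, channels, ttl = data.frame(timestamp = numeric(),
                                                     label = character())) {
  stopifnot(fs > 0, "ref_405" %in% names(channels))
  len <- vapply(channels, length, 1L)
  if (length(unique(len)) != 1L)
    stop("all channels must have the same length")
  dur <- len[[1]] / fs
  if (nrow(ttl) && any(ttl$timestamp < 0 | ttl$timestamp > dur))
    stop("TTL timestamps outside trace duration")
  structure(list(fs = fs, channels = channels, ttl = ttl),
            class = "raw_trace")
}

trace_times <- function(trace) {
  (seq_along(trace$channels[[1]]) - 1) / trace$fs
}

event_times <- function(log, event, cs_filter = "both") {
  sel <- log$event == event
  if (cs_filter != "both") sel <- sel & log$cs_type == cs_filter
  log$timestamp[sel]
}

#' Build the noiseless dF/F signal implied by an event log
#'
#' Linear superposition of each kernel's response anchored at its matching
#' events. `cs_window` kernels contribute a constant `sign * A_eff` over
#' each matching CS interval.
#'
#' @param log An `event_log`.
#' @param model A [sensor_model()].
#' @param L Session learning variable passed to every kernel (default 0).
#' @param fs Sampling rate of the output (Hz).
#' @param duration Trace length in seconds; default covers the log plus a
#'   15 s tail.
#' @return Numeric dF/F vector of length `round(duration * fs)`.
#' @export
build_ideal_signal <- function(log, model, L = 0, fs = 1000,
                               duration = NULL) {
  stopifnot(inherits(model, "sensor_model"), fs > 0)
  if (is.null(duration))
    duration <- (if (nrow(log)) max(log$timestamp) else 0) + 15
  n <- round(duration * fs)
  out <- numeric(n)
  for (k in model$kernels) {
    if (k$anchor == "cs_window") {
      a_eff <- max(0, k$amplitude * (1 + k$learning_gain * L))
      on_t <- event_times(log, "cs_onset", k$cs_filter)
      off_t <- event_times(log, "cs_offset", k$cs_filter)
      for (j in seq_along(on_t)) {
        i0 <- floor(on_t[j] * fs) + 1L
        i1 <- min(ceiling(off_t[j] * fs), n)
        if (i0 <= i1) out[i0:i1] <- out[i0:i1] + k$sign * a_eff
      }
    } else {
      ev_t <- event_times(log, k$anchor, k$cs_filter)
      # support: delay + rise to peak + ~8 decay constants
      support <- k$delay + 8 * k$decay_tau + 3 * k$rise_tau
      n_sup <- min(n, ceiling(support * fs))
      template <- kernel_response(k, (seq_len(n_sup) - 1) / fs, L)
      for (t0 in ev_t) {
        i0 <- round(t0 * fs) + 1L
        if (i0 > n) next
        i1 <- min(i0 + n_sup - 1L, n)
        idx <- i0:i1
        out[idx] <- out[idx] + template[seq_along(idx)]
      }
    }
  }
  out
}

motion_signal <- function(n, fs, rate_per_min, amp_sd) {
  m <- numeric(n)
  if (rate_per_min <= 0 || amp_sd <= 0) return(m)
  dur_min <- n / fs / 60
  n_ev <- stats::rpois(1L, rate_per_min * dur_min)
  if (n_ev == 0) return(m)
  t0 <- stats::runif(n_ev, 0, n / fs)
  amp <- stats::rnorm(n_ev, 0, amp_sd)
  n_sup <- min(n, ceiling(2 * fs))  # ~2 s transient support
  tt <- (seq_len(n_sup) - 1) / fs
  template <- (1 - exp(-tt / 0.05)) * exp(-tt / 0.3)
  for (j in seq_len(n_ev)) {
    i0 <- round(t0[j] * fs) + 1L
    if (i0 > n) next
    i1 <- min(i0 + n_sup - 1L, n)
    idx <- i0:i1
    m[idx] <- m[idx] + amp[j] * template[seq_along(idx)]
  }
  m
}

#' Generate a raw two-channel trace from an ideal dF/F signal
#'
#' Applies the generative model of the recording:
#' `sig = f0_sig * B(t) * (1 + ideal(t) + m(t)) + noise` and
#' `ref = f0_ref * B(t) * (1 + m(t)) + noise`, with a shared bleaching
#' trend `B(t) = 1 - bleach_frac * (1 - exp(-t / bleach_tau))` and shared
#' multiplicative motion transients `m(t)`; noise is independent white
#' Gaussian per channel. TTL markers (CS onsets and reward deliveries) are
#' copied from the event log.
#'
#' @param ideal Noiseless dF/F vector (see [build_ideal_signal()]).
#' @param art An [artifact_params()].
#' @param log Optional `event_log` supplying TTL markers.
#' @param channel Name for the signal channel (default `"sig_465"`).
#' @return A [raw_trace()] with channels `ref_405` and `channel`.
#' @export
generate_raw_trace <- function(ideal, art, log = NULL,
                               channel = "sig_465") {
  stopifnot(inherits(art, "artifact_params"), all(is.finite(ideal)))
  n <- length(ideal)
  fs <- art$fs_raw
  t <- (seq_len(n) - 1) / fs
  B <- 1 - art$bleach_frac * (1 - exp(-t / art$bleach_tau))
  m <- motion_signal(n, fs, art$motion_rate, art$motion_amp_sd)
  sig <- art$f0_sig * B * (1 + ideal + m)
  ref <- art$f0_ref * B * (1 + m)
  if (art$noise_sd > 0) {
    sig <- sig + stats::rnorm(n, 0, art$noise_sd * art$f0_sig)
    ref <- ref + stats::rnorm(n, 0, art$noise_sd * art$f0_ref)
  }
  ttl <- data.frame(timestamp = numeric(), label = character())
  if (!is.null(log) && nrow(log)) {
    sel <- log$event %in% c("cs_onset", "reward_delivery") &
      log$timestamp <= n / fs
    ttl <- data.frame(timestamp = log$timestamp[sel],
                      label = log$event[sel])
  }
  ch <- stats::setNames(list(ref, sig), c("ref_405", channel))
  raw_trace(fs, ch, ttl)
}

#' Simulate the photometry recording of one session
#'
#' Convenience wrapper: builds the ideal dF/F from the event log and sensor
#' model (after applying the genotype's kernel scalers) and passes it
#' through the artifact model.
#'
#' @inheritParams build_ideal_signal
#' @inheritParams generate_raw_trace
#' @param genotype Genotype label used to scale kernels (see
#'   [apply_genotype()]).
#' @return A [raw_trace()].
#' @export
simulate_photometry <- function(log, model, art, L = 0,
                                genotype = "control", channel = "sig_465") {
  model <- apply_genotype(model, genotype)
  ideal <- build_ideal_signal(log, model, L, fs = art$fs_raw)
  generate_raw_trace(ideal, art, log = log, channel = channel)
}
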