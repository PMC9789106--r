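# Signal conditioning: decimation to 100 Hz, 6 Hz zero-phase low-pass,
# isosbestic least-squares correction, dF/F, peri-event trial extraction
# and per-trial baseline z-scoring.

# Zero-phase filtering with odd-reflection end padding. signal::filtfilt
# starts both passes from zero state, which corrupts the ends of the
# trace; padding with the point-reflected signal absorbs the startup
# transient and is trimmed off afterwards.
filtfilt_padded <- function(b, a, x, pad) {
  n <- length(x)
  pad <- min(pad, n - 1L)
  head_pad <- 2 * x[1] - x[(pad + 1L):2L]
  tail_pad <- 2 * x[n] - x[(n - 1L):(n - pad)]
  y <- signal::filtfilt(filt = b, a = a, x = c(head_pad, x, tail_pad))
  y[(pad + 1L):(pad + n)]
}

#' Decimate a raw trace to a lower sampling rate
#'
#' FIR anti-alias low-pass (zero-phase, cutoff at 80% of the target
#' Nyquist) followed by keeping every `fs/target_fs`-th sample. Only
#' integer decimation factors are supported, so results are
#' bit-reproducible. TTL timestamps are unchanged.
#'
#' @param raw A [raw_trace()].
#' @param target_fs Target sampling rate in Hz (default 100).
#' @return A [raw_trace()] at `target_fs`.
#' @export
decimate_trace <- function(raw, target_fs = 100) {
  stopifnot(inherits(raw, "raw_trace"), target_fs > 0)
  q <- raw$fs / target_fs
  if (abs(q - round(q)) > 1e-9)
    stop("unsupported rate: fs = ", raw$fs,
         " is not an integer multiple of target_fs = ", target_fs)
  q <- as.integer(round(q))
  if (q == 1L) return(raw)
  ord <- max(64L, 10L * q)  # narrow cutoffs need proportionally long FIRs
  b <- as.numeric(signal::fir1(ord, 0.8 / q, "low"))
  b <- b / sum(b)  # exact unit DC gain
  keep <- seq(1L, length(raw$channels[[1]]), by = q)
  ch <- lapply(raw$channels, function(x) {
    filtfilt_padded(b, 1, x, pad = 3L * length(b))[keep]
  })
  raw_trace(target_fs, ch, raw$ttl)
}

#' Zero-phase low-pass filter
#'
#' 4th-order Butterworth applied forward-backward (`filtfilt`), so the
#' pass band keeps unit gain and zero phase shift and event latencies are
#' not displaced. Default cutoff 6 Hz removes events above the band of the
#' sensors of interest.
#'
#' @param x Numeric sample vector.
#' @param fs Sampling rate (Hz).
#' @param cutoff Cutoff frequency (Hz), must be below Nyquist.
#' @return Filtered vector, same length as `x`.
#' @export
lowpass_filter <- function(x, fs, cutoff = 6) {
  if (cutoff >= fs / 2)
    stop("config error: cutoff (", cutoff, " Hz) must be below Nyquist (",
         fs / 2, " Hz)")
  bt <- signal::butter(4, cutoff / (fs / 2), "low")
  pad <- ceiling(10 * fs / cutoff)  # several filter settle times
  filtfilt_padded(bt$b, bt$a, x, pad = pad)
}

#' Least-squares fit of the isosbestic reference onto the signal
#'
#' Ordinary least squares of the signal channel on the 405 nm reference
#' over the whole session, producing the fitted reference
#' `a * ref + b` used as the dF/F denominator.
#'
#' @param ref Reference (405 nm) sample vector.
#' @param sig Signal (465/560 nm) sample vector, same length.
#' @return A `fitted_reference` list with `a`, `b` and `fitted`.
#' @export
fit_isosbestic <- function(ref, sig) {
  if (length(ref) != length(sig))
    stop("input error: ref and sig lengths differ (",
         length(ref), " vs ", length(sig), ")")
  if (length(ref) < 2) stop("input error: need at least 2 samples")
  if (stats::var(ref) == 0)
    stop("degenerate fit: reference channel is constant")
  fit <- stats::lm.fit(cbind(intercept = 1, ref = ref), sig)
  a <- unname(fit$coefficients["ref"])
  b <- unname(fit$coefficients["intercept"])
  structure(list(a = a, b = b, fitted = b + a * ref),
            class = "fitted_reference")
}

#' Fractional fluorescence change
#'
#' `dF/F = (sig - fitted) / fitted`, elementwise.
#'
#' @param sig Signal sample vector.
#' @param fitted Fitted reference vector (strictly positive).
#' @return dF/F vector.
#' @export
compute_dff <- function(sig, fitted) {
  if (length(sig) != length(fitted))
    stop("input error: sig and fitted lengths differ")
  if (any(fitted <= 0))
    stop("nonpositive baseline: fitted reference has values <= 0")
  (sig - fitted) / fitted
}

#' Extract peri-event trial windows into a trial x sample matrix
#'
#' One row per matching trial, spanning `[anchor - pre, anchor + post_len)`
#' with nearest-sample alignment. Trials whose window would leave the trace
#' raise an error naming the trial.
#'
#' @param dff dF/F sample vector (session-long).
#' @param fs Sampling rate of `dff` (Hz).
#' @param log The session `event_log`.
#' @param anchor Anchoring event label (default `"cs_onset"`).
#' @param pre Seconds of pre-anchor context (default 1).
#' @param post_len Seconds after the anchor (default 21: 10 s CS + 11 s
#'   post-offset).
#' @param cs_filter `"both"`, `"plus"` or `"minus"`.
#' @return A `trial_tensor`: matrix with attributes `fs`, `t0_offset`,
#'   `anchor`, `cs_type`, `trial_index`, `anchor_time`, `scale = "dff"`.
#' @export
extract_trials <- function(dff, fs, log, anchor = "cs_onset", pre = 1,
                           post_len = 21, cs_filter = "both") {
  stopifnot(fs > 0, pre >= 0, post_len > 0)
  sel <- log$event == anchor
  if (cs_filter != "both") sel <- sel & log$cs_type == cs_filter
  t_anchor <- log$timestamp[sel]
  trial_index <- log$trial_index[sel]
  cs_type <- log$cs_type[sel]
  n_samp <- round((pre + post_len) * fs)
  out <- matrix(NA_real_, nrow = length(t_anchor), ncol = n_samp)
  for (i in seq_along(t_anchor)) {
    i0 <- round((t_anchor[i] - pre) * fs) + 1L
    i1 <- i0 + n_samp - 1L
    if (i0 < 1L || i1 > length(dff))
      stop("truncated trial: window of trial ", trial_index[i],
           " [", i0, ", ", i1, "] exceeds trace bounds (n = ",
           length(dff), ")")
    out[i, ] <- dff[i0:i1]
  }
  structure(out, fs = fs, t0_offset = pre, anchor = anchor,
            cs_type = cs_type, trial_index = trial_index,
            anchor_time = t_anchor, scale = "dff",
            class = c("trial_tensor", "matrix", "array"))
}

#' Time axis of a trial tensor
#'
#' @param tensor A `trial_tensor`.
#' @return Seconds relative to the anchor, one value per column.
#' @export
tensor_time <- function(tensor) {
  (seq_len(ncol(tensor)) - 1) / attr(tensor, "fs") - attr(tensor, "t0_offset")
}

#' Per-trial baseline z-scoring
#'
#' Each row is centred and scaled by the mean and population standard
#' deviation of its own baseline segment (the `baseline_len` seconds
#' immediately before the anchor):
#' `z = (dF/F - mu_baseline) / sigma_baseline`.
#'
#' @param tensor A dF/F `trial_tensor` with `t0_offset >= baseline_len`.
#' @param baseline_len Baseline length in seconds (default 1).
#' @return The z-scored `trial_tensor` (`scale = "zscore"`).
#' @export
zscore_trials <- function(tensor, baseline_len = 1) {
  stopifnot(inherits(tensor, "trial_tensor"))
  fs <- attr(tensor, "fs")
  t0 <- attr(tensor, "t0_offset")
  if (baseline_len > t0 + 1e-9)
    stop("baseline_len exceeds the tensor's pre-anchor context")
  i1 <- round(t0 * fs)           # last pre-anchor column
  i0 <- i1 - round(baseline_len * fs) + 1L
  stopifnot(i0 >= 1, i1 >= i0)
  out <- tensor
  for (r in seq_len(nrow(tensor))) {
    b <- tensor[r, i0:i1]
    mu <- mean(b)
    sigma <- sqrt(mean((b - mu)^2))  # population convention
    if (sigma == 0)
      stop("flat baseline: trial ", attr(tensor, "trial_index")[r],
           " has zero baseline standard deviation")
    out[r, ] <- (tensor[r, ] - mu) / sigma
  }
  attr(out, "scale") <- "zscore"
  attr(out, "baseline_len") <- baseline_len
  out
}

#' Run the full conditioning chain on one session
#'
#' Fixed order: decimate both channels to `target_fs`, zero-phase low-pass
#' both at `cutoff`, fit the reference onto the signal over the whole
#' session, compute dF/F, extract peri-CS trials and z-score them against
#' the pre-CS baseline.
#'
#' @param raw A [raw_trace()].
#' @param log The matching `event_log`.
#' @param channel Signal channel to process (default `"sig_465"`).
#' @param target_fs,cutoff,pre,post_len,baseline_len,cs_filter See the
#'   stage functions.
#' @return List with `dff` (session vector), `fit`, `tensor_dff`,
#'   `tensor_z` and `fs`.
#' @export
preprocess_session <- function(raw, log, channel = "sig_465",
                               target_fs = 100, cutoff = 6, pre = 1,
                               post_len = 21, baseline_len = 1,
                               cs_filter = "both") {
  stopifnot(inherits(raw, "raw_trace"))
  if (!channel %in% names(raw$channels))
    stop("channel ", channel, " absent from trace")
  dec <- decimate_trace(raw, target_fs)
  ref <- lowpass_filter(dec$channels$ref_405, dec$fs, cutoff)
  sig <- lowpass_filter(dec$channels[[channel]], dec$fs, cutoff)
  fit <- fit_isosbestic(ref, sig)
  dff <- compute_dff(sig, fit$fitted)
  tensor <- extract_trials(dff, dec$fs, log, anchor = "cs_onset",
                           pre = pre, post_len = post_len,
                           cs_filter = cs_filter)
  list(dff = dff, fit = fit, tensor_dff = tensor,
       tensor_z = zscore_trials(tensor, baseline_len), fs = dec$fs)
}
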