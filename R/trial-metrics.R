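# Windowed quantification of aligned trial signals: endpoint-weighted
# baseline, signed AUC and peak height, derivative-based transient counts.

#' Endpoint-weighted straight-line baseline of a window
#'
#' Estimates the within-window baseline as the straight line through two
#' anchor points: (centre of the first `frac` of samples, their mean) and
#' (centre of the last `frac` of samples, their mean). With the default
#' `frac = 0.15` the line is anchored on the outer 15% of the search
#' window, so activity confined to the interior does not bias it.
#'
#' @param w Numeric sample vector (the search window), length >= 2.
#' @param frac Fraction of samples in each endpoint segment, `(0, 0.5]`.
#' @return Baseline vector the same length as `w`.
#' @export
endpoint_baseline <- function(w, frac = 0.15) {
  n <- length(w)
  if (n < 2) stop("window too short for endpoint baseline (n = ", n, ")")
  stopifnot(frac > 0, frac <= 0.5)
  k <- max(1L, round(frac * n))
  x1 <- mean(seq_len(k)); y1 <- mean(w[seq_len(k)])
  idx2 <- (n - k + 1L):n
  x2 <- mean(idx2); y2 <- mean(w[idx2])
  if (x2 == x1) return(rep(mean(w), n))
  slope <- (y2 - y1) / (x2 - x1)
  y1 + slope * (seq_len(n) - x1)
}

#' Signed area under the curve and peak height of a window
#'
#' Works on the residual `r = w - baseline`: `auc` is its trapezoidal
#' integral over the window (units value x seconds, dips negative), and
#' `height` is the residual extremum of largest magnitude with its sign
#' (earliest sample wins ties).
#'
#' @param w Numeric sample vector.
#' @param fs Sampling rate (Hz).
#' @param baseline Baseline vector, same length as `w`.
#' @return List with `auc` and `height`.
#' @export
auc_and_height <- function(w, fs, baseline = numeric(length(w))) {
  if (length(w) != length(baseline))
    stop("window and baseline lengths differ")
  r <- w - baseline
  n <- length(r)
  auc <- if (n < 2) 0 else (sum(r) - (r[1] + r[n]) / 2) / fs
  i <- which.max(abs(r))
  list(auc = auc, height = r[i])
}

#' Count signal transients from the smoothed first derivative
#'
#' Savitzky-Golay first-derivative smoothing of the window followed by
#' threshold crossing: a transient onset is an upward crossing of the
#' derivative (in units per second) above `min_prominence / sg_window`,
#' i.e. a rise of at least `min_prominence` within about one smoothing
#' window. After each onset a refractory period of one kernel width
#' suppresses re-triggering.
#'
#' @param x Numeric sample vector.
#' @param fs Sampling rate (Hz).
#' @param sg_window Savitzky-Golay window length in seconds (default 0.5).
#' @param sg_order Polynomial order (default 3).
#' @param min_prominence Minimum transient amplitude counted (signal
#'   units, default 0.5).
#' @return Integer count of transient onsets.
#' @export
count_transients <- function(x, fs, sg_window = 0.5, sg_order = 3,
                             min_prominence = 0.5) {
  klen <- round(sg_window * fs)
  if (klen < sg_order + 2)
    stop("config error: sg_window * fs must be at least sg_order + 2")
  if (klen %% 2 == 0) klen <- klen + 1L
  if (length(x) < klen) stop("config error: window shorter than SG kernel")
  deriv <- signal::sgolayfilt(x, p = sg_order, n = klen, m = 1) * fs
  thr <- min_prominence / sg_window
  above <- deriv > thr
  count <- 0L
  i <- 2L
  while (i <= length(above)) {
    if (above[i] && !above[i - 1L]) {
      count <- count + 1L
      i <- i + klen  # refractory: one kernel width
    } else i <- i + 1L
  }
  count
}

#' Declare a quantification window
#'
#' @param name Label carried into the metric table (e.g. `"cs_mean"`,
#'   `"reward_auc"`).
#' @param anchor Event the window is anchored to (`"cs_onset"`,
#'   `"cs_offset"`, `"reward_delivery"`).
#' @param start Window start in seconds relative to the anchor.
#' @param length Window length in seconds (> 0).
#' @param metric `"mean"`, `"auc_peak"` or `"count"`.
#' @param frac Endpoint fraction for `auc_peak` windows (default 0.15).
#' @param ... Extra parameters for `"count"` windows, passed to
#'   [count_transients()].
#' @return A `window_spec` object.
#' @export
window_spec <- function(name, anchor, start, length,
                        metric = c("mean", "auc_peak", "count"),
                        frac = 0.15, ...) {
  metric <- match.arg(metric)
  stopifnot(length > 0)
  structure(list(name = name, anchor = anchor, start = start,
                 length = length, metric = metric, frac = frac,
                 extra = list(...)),
            class = "window_spec")
}

#' Default quantification windows per sensor
#'
#' Dopamine: mean during the 10 s CS and reward AUC/peak over the 5 s
#' after CS+ offset. Acetylcholine: mean during the CS and reward AUC/peak
#' over the 10 s after CS offset. Calcium (D1/D2 SPN): mean during the CS
#' and mean over the 10 s immediately post CS offset.
#'
#' @param sensor `"grab_da"`, `"ach3"`, `"gcamp_d1"` or `"jrcamp_d2"`.
#' @param cs_duration CS length in seconds (default 10).
#' @return List of [window_spec()] objects.
#' @export
default_window_specs <- function(sensor = c("grab_da", "ach3", "gcamp_d1",
                                            "jrcamp_d2"),
                                 cs_duration = 10) {
  sensor <- match.arg(sensor)
  cs_mean <- window_spec("cs_mean", "cs_onset", 0, cs_duration, "mean")
  switch(sensor,
    grab_da = list(cs_mean,
                   window_spec("reward_auc", "cs_offset", 0, 5, "auc_peak")),
    ach3 = list(cs_mean,
                window_spec("reward_auc", "cs_offset", 0, 10, "auc_peak")),
    list(cs_mean,
         window_spec("post_cs_mean", "cs_offset", 0, 10, "mean")))
}

#' Apply quantification windows to every trial of a tensor
#'
#' For each trial row and each [window_spec()], locates the window via the
#' trial's own anchor event in the log, then computes the requested
#' metric: plain arithmetic mean, endpoint-baselined AUC + peak height, or
#' a transient count. Trials lacking the anchor event (e.g. reward windows
#' on CS- trials when anchored to `reward_delivery`) yield `NA`.
#'
#' @param tensor A (typically z-scored) `trial_tensor`.
#' @param log The session `event_log` the tensor was extracted from.
#' @param specs List of [window_spec()] objects.
#' @return Tidy data frame: `trial_index`, `cs_type`, `window`, `metric`,
#'   `value`.
#' @export
compute_trial_metrics <- function(tensor, log, specs) {
  stopifnot(inherits(tensor, "trial_tensor"))
  if (inherits(specs, "window_spec")) specs <- list(specs)
  fs <- attr(tensor, "fs")
  t0 <- attr(tensor, "t0_offset")
  anchor_time <- attr(tensor, "anchor_time")
  trial_index <- attr(tensor, "trial_index")
  cs_type <- attr(tensor, "cs_type")
  out <- list()
  for (sp in specs) {
    for (r in seq_len(nrow(tensor))) {
      ts <- log$timestamp[log$event == sp$anchor &
                          log$trial_index == trial_index[r]]
      vals <- if (!length(ts)) {
        switch(sp$metric,
               mean = list(mean = NA_real_),
               count = list(count = NA_real_),
               auc_peak = list(auc = NA_real_, height = NA_real_))
      } else {
        # window start relative to the row's first sample
        rel <- (ts[1] - anchor_time[r]) + t0 + sp$start
        i0 <- round(rel * fs) + 1L
        i1 <- i0 + round(sp$length * fs) - 1L
        if (i0 < 1L || i1 > ncol(tensor))
          stop("window '", sp$name, "' of trial ", trial_index[r],
               " lies outside the tensor extent")
        w <- tensor[r, i0:i1]
        switch(sp$metric,
          mean = list(mean = mean(w)),
          auc_peak = {
            bl <- endpoint_baseline(w, sp$frac)
            ah <- auc_and_height(w, fs, bl)
            list(auc = ah$auc, height = ah$height)
          },
          count = list(count = do.call(count_transients,
                                       c(list(w, fs), sp$extra))))
      }
      for (mn in names(vals))
        out[[length(out) + 1L]] <- data.frame(
          trial_index = trial_index[r], cs_type = cs_type[r],
          window = sp$name, metric = mn, value = vals[[mn]],
          stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  structure(res, class = c("trial_metrics", "data.frame"))
}
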