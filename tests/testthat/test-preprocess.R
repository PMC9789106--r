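# Decimation, filtering, isosbestic fit, dF/F, trial extraction, z-scoring.

make_trace <- function(ref, sig, fs) raw_trace(fs, list(ref_405 = ref,
                                                        sig_465 = sig))

test_that("decimation keeps every q-th sample at the target rate", {
  fs <- 1000
  x <- rep(3.5, fs * 10)
  tr <- make_trace(x, x, fs)
  dec <- decimate_trace(tr, 100)
  expect_equal(dec$fs, 100)
  expect_length(dec$channels$sig_465, 1000L)
  # DC preserved (edges included: zero-phase FIR has unit DC gain)
  expect_equal(dec$channels$sig_465, rep(3.5, 1000), tolerance = 1e-6)
  # identity when target equals the input rate
  expect_identical(decimate_trace(tr, fs), tr)
  expect_error(decimate_trace(tr, 300), "integer multiple")
})

test_that("decimated band-limited signals interpolate back within 1% RMS", {
  fs <- 1000
  t <- (0:(fs * 10 - 1)) / fs
  x <- sin(2 * pi * 2 * t) + 0.5 * cos(2 * pi * 5 * t)  # <= 6 Hz content
  dec <- decimate_trace(make_trace(x, x, fs), 100)
  td <- (seq_along(dec$channels$sig_465) - 1) / 100
  back <- stats::spline(td, dec$channels$sig_465, xout = t)$y
  keep <- t > 0.5 & t < 9.5  # trim edges
  rms <- sqrt(mean((back[keep] - x[keep])^2)) / sqrt(mean(x[keep]^2))
  expect_lt(rms, 0.01)
})

test_that("low-pass filter has unit DC gain, flat pass band and strong stop band", {
  fs <- 100
  expect_equal(lowpass_filter(rep(2, 500), fs), rep(2, 500),
               tolerance = 1e-9)
  t <- (0:(fs * 20 - 1)) / fs
  keep <- t > 2 & t < 18
  pass <- lowpass_filter(sin(2 * pi * 1 * t), fs)
  expect_lt(abs(max(abs(pass[keep])) - 1), 0.05)
  stopb <- lowpass_filter(sin(2 * pi * 30 * t), fs)
  expect_lt(max(abs(stopb[keep])), 0.01)
  expect_error(lowpass_filter(t, fs, cutoff = 50), "Nyquist")
})

test_that("isosbestic fit matches exact affine relations and OLS oracle", {
  sig <- c(1, 3, 5)
  fit <- fit_isosbestic(c(0, 1, 2), sig)
  expect_equal(fit$a, 2, tolerance = 1e-12)
  expect_equal(fit$b, 1, tolerance = 1e-12)
  expect_equal(fit$fitted, sig, tolerance = 1e-12)
  fit_id <- fit_isosbestic(sig, sig)
  expect_equal(fit_id$a, 1, tolerance = 1e-12)
  expect_equal(fit_id$b, 0, tolerance = 1e-12)
  set.seed(11)
  for (i in 1:50) {
    ref <- rnorm(100, 10, 2)
    s <- 1.7 * ref + rnorm(100)
    got <- fit_isosbestic(ref, s)
    want <- ols_oracle(ref, s)
    expect_equal(got$a, want$a, tolerance = 1e-10)
    expect_equal(got$b, want$b, tolerance = 1e-10)
  }
  expect_error(fit_isosbestic(rep(1, 10), rnorm(10)), "constant")
  expect_error(fit_isosbestic(1:5, 1:4), "lengths differ")
})

test_that("dF/F is the elementwise fractional deviation", {
  f <- c(10, 20, 40)
  expect_equal(compute_dff(f, f), c(0, 0, 0))
  expect_equal(compute_dff(2 * f, f), c(1, 1, 1))
  expect_equal(compute_dff(11, 10), 0.1)
  expect_error(compute_dff(c(1, 2), c(1, 0)), "nonpositive")
  expect_error(compute_dff(1:3, 1:2), "lengths differ")
})

test_that("trial extraction does exact index bookkeeping", {
  fs <- 100
  log <- structure(data.frame(
    timestamp = c(5, 15, 30, 40), event = rep(c("cs_onset", "cs_offset"), 2),
    trial_index = c(1L, 1L, 2L, 2L), cs_type = c("plus", "plus", "minus",
                                                 "minus"),
    side = "left"), class = c("event_log", "data.frame"))
  dff <- rep(0.25, 60 * fs)
  tens <- extract_trials(dff, fs, log, pre = 1, post_len = 21)
  expect_equal(dim(tens), c(2L, 2200L))
  expect_true(all(tens == 0.25))
  expect_equal(attr(tens, "cs_type"), c("plus", "minus"))
  # an impulse placed exactly at CS onset lands at column pre*fs + 1
  dff2 <- numeric(60 * fs)
  dff2[round(5 * fs) + 1] <- 7
  tens2 <- extract_trials(dff2, fs, log, pre = 1, post_len = 2)
  expect_equal(which(tens2[1, ] != 0), 1 * fs + 1)
  expect_equal(tens2[1, 1 * fs + 1], 7)
  # CS filtering and bounds checking
  expect_equal(nrow(extract_trials(dff, fs, log, cs_filter = "plus",
                                   post_len = 2)), 1L)
  expect_error(extract_trials(dff, fs, log, pre = 6, post_len = 2),
               "truncated trial")
  expect_error(extract_trials(dff[1:3500], fs, log, post_len = 21),
               "trial 2")
})

test_that("z-scoring normalises each trial by its own baseline", {
  fs <- 10
  # baseline alternates 0, 2: mu = 1, population sigma = 1
  row1 <- c(rep(c(0, 2), 5), rep(3, 20))
  row2 <- row1 + 10  # shift invariance
  tens <- structure(rbind(row1, row2), fs = fs, t0_offset = 1,
                    anchor = "cs_onset", cs_type = c("plus", "minus"),
                    trial_index = 1:2, anchor_time = c(1, 2), scale = "dff",
                    class = c("trial_tensor", "matrix", "array"))
  z <- zscore_trials(tens, baseline_len = 1)
  expect_equal(unname(z[1, 11]), 2)   # (3 - 1) / 1
  expect_equal(unname(z[1, ]), unname(z[2, ]))
  expect_equal(attr(z, "scale"), "zscore")
  # every baseline segment has mean 0 and population sigma 1
  b <- z[, 1:10]
  expect_equal(rowMeans(b), c(row1 = 0, row2 = 0), tolerance = 1e-12)
  expect_equal(apply(b, 1, function(x) sqrt(mean(x^2))),
               c(row1 = 1, row2 = 1), tolerance = 1e-12)
  flat <- tens
  flat[1, 1:10] <- 5
  expect_error(zscore_trials(flat), "flat baseline")
  expect_error(zscore_trials(tens, baseline_len = 2), "exceeds")
})

test_that("the full chain recovers an injected ideal dF/F (zero noise)", {
  cfg <- quick_config(n = 3, seed = 21)
  log <- simulate_session(cfg, behavior_preset("control"), 0)
  model <- sensor_preset("grab_da")
  art <- artifact_params(fs_raw = 500, bleach_tau = 120, bleach_frac = 0.3,
                         motion_rate = 6, motion_amp_sd = 0.02,
                         noise_sd = 0)
  set.seed(22)
  ideal <- build_ideal_signal(log, model, L = 0.5, fs = art$fs_raw)
  trace <- generate_raw_trace(ideal, art, log)
  dec <- decimate_trace(trace, 100)
  ref <- lowpass_filter(dec$channels$ref_405, 100)
  sig <- lowpass_filter(dec$channels$sig_465, 100)
  fit <- fit_isosbestic(ref, sig)
  dff <- compute_dff(sig, fit$fitted)
  # oracle: the injected ideal through the same decimate + low-pass path
  oracle <- lowpass_filter(
    decimate_trace(raw_trace(art$fs_raw,
                             list(ref_405 = ideal, sig_465 = ideal)),
                   100)$channels$sig_465, 100)
  n <- length(dff)
  keep <- seq(2 * 100, n - 2 * 100)  # trim filter edges
  err <- dff[keep] - oracle[keep]
  # the session fit absorbs the signal component spanned by {1, ref}; the
  # chain recovers everything outside that span (per-trial baselining
  # removes the slow remainder downstream)
  err <- stats::lm.fit(cbind(1, ref[keep]), err)$residuals
  nrmse <- sqrt(mean(err^2)) / diff(range(oracle[keep]))
  expect_lt(nrmse, 0.01)
})
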