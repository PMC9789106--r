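# Endpoint-weighted baseline, AUC/peak quantification, transient counting.

test_that("endpoint baseline reproduces flats and ramps, ignores interior pulses", {
  expect_equal(endpoint_baseline(rep(4, 100)), rep(4, 100))
  ramp <- seq(-2, 5, length.out = 200)
  expect_equal(endpoint_baseline(ramp), ramp, tolerance = 1e-12)
  w <- numeric(100)
  w[26:75] <- 3  # pulse confined to the middle 50%
  expect_equal(endpoint_baseline(w, frac = 0.15), numeric(100),
               tolerance = 1e-12)
  expect_error(endpoint_baseline(1), "too short")
  expect_error(endpoint_baseline(1:10, frac = 0.6), "frac")
})

test_that("auc and height match construction on a rectangular pulse", {
  fs <- 100
  w <- numeric(10 * fs)
  w[(2 * fs + 1):(4 * fs)] <- 1
  got <- auc_and_height(w, fs, numeric(length(w)))
  expect_equal(got$auc, 2.0, tolerance = 0.01)
  expect_equal(got$height, 1)
  # w equal to its baseline gives exactly (0, 0)
  z <- auc_and_height(w, fs, w)
  expect_equal(z$auc, 0)
  expect_equal(z$height, 0)
  # odd symmetry
  neg <- auc_and_height(-w, fs, numeric(length(w)))
  expect_equal(neg$auc, -got$auc)
  expect_equal(neg$height, -got$height)
})

test_that("auc and height agree with brute-force oracles on random windows", {
  set.seed(31)
  for (i in 1:300) {
    n <- sample(5:200, 1)
    fs <- sample(c(10, 50, 100), 1)
    w <- rnorm(n)
    bl <- rnorm(n, sd = 0.3)
    got <- auc_and_height(w, fs, bl)
    expect_equal(got$auc, trapz_oracle(w - bl, fs), tolerance = 1e-10)
    expect_equal(got$height, extremum_oracle(w - bl), tolerance = 1e-12)
  }
})

test_that("metrics are linear in the residual scale", {
  set.seed(5)
  w <- rnorm(500)
  base <- auc_and_height(w, 100)
  for (k in c(-2, 0.5, 10)) {
    sc <- auc_and_height(k * w, 100)
    expect_equal(sc$auc, k * base$auc, tolerance = 1e-12)
    expect_equal(sc$height, k * base$height, tolerance = 1e-12)
  }
})

test_that("transient counting finds injected events and rejects tiny ones", {
  fs <- 50
  n <- 10 * 60 * fs  # a 10 min search window
  x <- numeric(n)
  onsets <- seq(30, 570, length.out = 7)
  for (t0 in onsets)
    x <- x + make_transient(n, fs, t0, amp = 2.5, rise = 0.1, decay = 1)
  expect_equal(count_transients(x, fs, min_prominence = 0.5), 7L)
  expect_equal(count_transients(numeric(n), fs), 0L)
  expect_equal(count_transients(x * 0.04 / 2.5, fs, min_prominence = 0.4), 0L)
  expect_error(count_transients(x, fs, sg_window = 0.02, sg_order = 3),
               "config error")
})

test_that("high-rate transients outnumber low-rate ones across seeds", {
  # emulates the saline-vs-cocaine validation: 10-min windows with
  # low vs high injected transient rates
  fs <- 20
  n <- 10 * 60 * fs
  correct <- 0L
  for (seed in 1:40) {
    set.seed(seed)
    mk <- function(rate_per_min) {
      k <- rpois(1, rate_per_min * 10)
      t0 <- sort(runif(k, 5, 590))
      t0 <- t0[c(TRUE, diff(t0) > 3)]  # enforce separation
      x <- numeric(n)
      for (t in t0) x <- x + make_transient(n, fs, t, amp = 2, rise = 0.1,
                                            decay = 1)
      x + rnorm(n, sd = 0.05)
    }
    saline <- count_transients(mk(0.8), fs, min_prominence = 0.5)
    cocaine <- count_transients(mk(6), fs, min_prominence = 0.5)
    if (cocaine > saline) correct <- correct + 1L
  }
  expect_gte(correct / 40, 0.95)
})

test_that("measured height is linear in injected kernel amplitude", {
  fs <- 100
  n <- 12 * fs
  amps <- seq(0.2, 4, length.out = 20)
  heights <- sapply(amps, function(a) {
    w <- make_transient(n, fs, 3, amp = a, rise = 0.15, decay = 0.8)
    auc_and_height(w, fs, endpoint_baseline(w))$height
  })
  slopes <- heights / amps
  expect_lt((max(slopes) - min(slopes)) / mean(slopes), 0.1)
  fit <- linear_regression(amps, heights)
  expect_gt(fit$r_squared, 0.999)
})

test_that("trial metrics apply each window to each matching trial", {
  fs <- 50
  log <- structure(data.frame(
    timestamp = c(5, 5, 15, 15, 40, 40, 50),
    event = c("trial_init", "cs_onset", "cs_offset", "reward_delivery",
              "trial_init", "cs_onset", "cs_offset"),
    trial_index = c(1L, 1L, 1L, 1L, 2L, 2L, 2L),
    cs_type = c(rep("plus", 4), rep("minus", 3)),
    side = "left"), class = c("event_log", "data.frame"))
  dff <- rep(2, 70 * fs)
  tens <- extract_trials(dff, fs, log, pre = 1, post_len = 16)
  specs <- list(window_spec("cs_mean", "cs_onset", 0, 10, "mean"),
                window_spec("reward_auc", "reward_delivery", 0, 5,
                            "auc_peak"))
  m <- compute_trial_metrics(tens, log, specs)
  expect_s3_class(m, "trial_metrics")
  cm <- m[m$window == "cs_mean", ]
  expect_equal(cm$value, c(2, 2))
  ra <- m[m$window == "reward_auc", ]
  expect_equal(ra$value[ra$cs_type == "plus"], c(0, 0))  # flat: auc/height 0
  expect_true(all(is.na(ra$value[ra$cs_type == "minus"])))  # no reward event
  # all-zero tensor gives all-zero metrics
  tens0 <- extract_trials(numeric(70 * fs), fs, log, pre = 1, post_len = 16)
  m0 <- compute_trial_metrics(tens0, log,
                              list(window_spec("cs_mean", "cs_onset", 0, 10,
                                               "mean")))
  expect_true(all(m0$value == 0))
  # windows outside the tensor extent are reported with the window name
  expect_error(compute_trial_metrics(tens, log,
                 list(window_spec("late", "cs_offset", 0, 10, "auc_peak"))),
               "late")
})

test_that("a simulated ACh pause yields negative reward-window auc and height", {
  cfg <- quick_config(n = 3, seed = 41)
  log <- simulate_session(cfg, behavior_preset("control"), 0)
  art <- artifact_params(fs_raw = 500, noise_sd = 5e-4)
  set.seed(42)
  trace <- simulate_photometry(log, sensor_preset("ach3"), art, L = 0.8)
  pp <- preprocess_session(trace, log, post_len = 21)
  m <- compute_trial_metrics(pp$tensor_z, log,
                             default_window_specs("ach3"))
  auc_plus <- m$value[m$window == "reward_auc" & m$metric == "auc" &
                      m$cs_type == "plus"]
  expect_true(all(auc_plus < 0))
})
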