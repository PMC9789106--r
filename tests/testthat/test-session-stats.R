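# Behavioural summaries, session aggregation, regression, heatmaps.

elog <- function(df) structure(df, class = c("event_log", "data.frame"))

test_that("approach time is the interval overlap with the lit-CS window", {
  cfg <- session_config(n_trials_per_cs = 2, iti_min = 5, iti_max = 5)
  # three hand-built trials with partial overlaps
  log <- elog(data.frame(
    timestamp = c(10, 20, 8, 12,          # trial 1 (plus, right)
                  40, 50, 39, 45, 47, 52, # trial 2 (minus, left)
                  70, 80, 70, 80, 75, 78, 80, 80.5),
    event = c("cs_onset", "cs_offset", "approach_enter", "approach_exit",
              "cs_onset", "cs_offset", "approach_enter", "approach_exit",
              "approach_enter", "approach_exit",
              "cs_onset", "cs_offset", "approach_enter", "approach_exit",
              "approach_enter", "approach_exit", "reward_delivery",
              "magazine_entry"),
    trial_index = c(1L, 1L, 1L, 1L, 2L, 2L, 2L, 2L, 2L, 2L,
                    3L, 3L, 3L, 3L, 3L, 3L, 3L, 3L),
    cs_type = c("plus", "plus", "plus", "plus",
                rep("minus", 6), rep("plus", 8)),
    side = c("right", "right", "right", "right", rep("left", 6),
             rep("right", 6), "right", "right")))
  log <- log[order(log$timestamp), ]
  b <- behavior_summary(log, cfg)
  # oracle: brute-force interval intersection per trial
  expect_equal(b$per_trial$approach_time[1],
               overlap_oracle(8, 12, 10, 20))              # 2
  expect_equal(b$per_trial$approach_time[2],
               overlap_oracle(c(39, 47), c(45, 52), 40, 50))  # 5 + 3
  expect_equal(b$per_trial$approach_time[3],
               overlap_oracle(c(70, 75), c(80, 78), 70, 80))  # 10 + 3
  expect_equal(b$per_cs$approach_time,
               c(2 + 13, 8))  # plus trials 1 and 3; minus trial 2
  expect_equal(b$delta_approach, 15 - 8)
  expect_equal(b$latency_mean, 0.5)
})

test_that("empty approach logs give zero approach time; full overlap gives cs_duration", {
  cfg <- quick_config(n = 2, seed = 51)
  log <- simulate_session(cfg, behavior_params(init_approach_frac = 0,
                                               asym_plus = 0, asym_minus = 0,
                                               approach_noise_sd = 0), 0)
  b <- behavior_summary(log, cfg)
  expect_true(all(b$per_trial$approach_time == 0))
  full <- elog(data.frame(
    timestamp = c(10, 10, 20, 20, 20.5),
    event = c("cs_onset", "approach_enter", "approach_exit", "cs_offset",
              "reward_delivery"),
    trial_index = 1L, cs_type = "plus", side = "right"))
  bf <- behavior_summary(full, session_config())
  expect_equal(bf$per_trial$approach_time, 10)
  expect_equal(bf$n_latency_missing, 1L)  # reward never collected
  expect_true(is.na(bf$latency_mean))
})

test_that("per-trial approach times never exceed the CS duration", {
  cfg <- quick_config(n = 6)
  for (seed in 1:20) {
    cfg$seed <- seed
    b <- behavior_summary(simulate_session(cfg, behavior_preset("control"),
                                           4), cfg)
    expect_true(all(b$per_trial$approach_time >= 0 &
                    b$per_trial$approach_time <= cfg$cs_duration + 1e-9))
  }
})

test_that("session summaries take per-CS means and their differences", {
  mk <- function(vals_plus, vals_minus) {
    structure(data.frame(
      trial_index = seq_len(length(vals_plus) + length(vals_minus)),
      cs_type = rep(c("plus", "minus"), c(length(vals_plus),
                                          length(vals_minus))),
      window = "cs_mean", metric = "mean",
      value = c(vals_plus, vals_minus)),
      class = c("trial_metrics", "data.frame"))
  }
  cfg <- quick_config(n = 2, seed = 3)
  log <- simulate_session(cfg, behavior_preset("control"), 0)
  behav <- behavior_summary(log, cfg)
  s <- summarize_session(mk(c(2, 2, 2), c(0.5, 0.5)), behav)
  expect_equal(s$signal$plus_mean, 2)
  expect_equal(s$signal$minus_mean, 0.5)
  expect_equal(s$signal$delta, 1.5)
  # permuting trials leaves the summary unchanged
  m <- mk(c(1, 4, 1), c(2, 0))
  mp <- m[c(4, 2, 5, 1, 3), ]
  class(mp) <- class(m)
  expect_equal(summarize_session(m, behav)$signal,
               summarize_session(mp, behav)$signal)
  expect_error(summarize_session(mk(1:3, numeric(0)), behav), "minus")
})

test_that("linear regression matches closed-form OLS, Pearson r and t test", {
  ex <- linear_regression(c(1, 2, 3), c(3, 5, 7))  # y = 2x + 1
  expect_equal(ex$slope, 2, tolerance = 1e-12)
  expect_equal(ex$intercept, 1, tolerance = 1e-12)
  expect_equal(ex$r_squared, 1, tolerance = 1e-12)
  ex3 <- linear_regression(c(1, 2, 3), c(1, 3, 2))
  expect_equal(ex3$slope, 0.5, tolerance = 1e-12)
  expect_equal(ex3$r_squared, 0.25, tolerance = 1e-12)
  flat <- linear_regression(1:10, rep(2, 10))
  expect_equal(flat$slope, 0)
  expect_equal(flat$r_squared, 0)
  set.seed(61)
  for (i in 1:50) {
    n <- sample(5:50, 1)
    x <- rnorm(n); y <- 0.3 * x + rnorm(n)
    got <- linear_regression(x, y)
    want <- regression_oracle(x, y)
    expect_equal(got$slope, want$slope, tolerance = 1e-10)
    expect_equal(got$intercept, want$intercept, tolerance = 1e-10)
    expect_equal(got$r_squared, want$r_squared, tolerance = 1e-10)
    expect_equal(got$p_value, want$p_value, tolerance = 1e-10)
  }
  expect_error(linear_regression(rep(1, 5), 1:5), "degenerate")
  expect_error(linear_regression(1:2, 1:2), "3 points")
})

test_that("heatmap matrices stack trials in session then trial order", {
  mk_tensor <- function(vals, cs) {
    structure(outer(vals, rep(1, 4)),
              fs = 2, t0_offset = 1, anchor = "cs_onset", cs_type = cs,
              trial_index = seq_along(cs), anchor_time = seq_along(cs),
              scale = "zscore", class = c("trial_tensor", "matrix",
                                          "array"))
  }
  t1 <- mk_tensor(c(1, 2), c("plus", "minus"))
  t2 <- mk_tensor(c(3, 4), c("plus", "minus"))
  hb <- heatmap_matrix(list(t1, t2), "trial_by_trial", "both")
  expect_equal(hb$matrix[, 1], c(1, 2, 3, 4))
  expect_equal(hb$time, c(-1, -0.5, 0, 0.5))
  hp <- heatmap_matrix(list(t1, t2), "trial_by_trial", "plus")
  expect_equal(hp$matrix[, 1], c(1, 3))
  hs <- heatmap_matrix(list(t1, t2), "session_average", "both")
  expect_equal(hs$matrix[, 1], c(1.5, 3.5))
  # identical rows average to themselves; single trial equals its row
  one <- heatmap_matrix(list(mk_tensor(7, "plus")), "trial_by_trial")
  expect_equal(as.numeric(one$matrix), rep(7, 4))
  t_bad <- mk_tensor(c(1, 2), c("plus", "minus"))
  attr(t_bad, "fs") <- 4
  expect_error(heatmap_matrix(list(t1, t_bad)), "mismatch")
})

test_that("full sessions stack to the documented 20-trials-per-session order", {
  cfg <- quick_config(n = 2)
  tensors <- lapply(1:3, function(s) {
    cfg$seed <- 70 + s
    log <- simulate_session(cfg, behavior_preset("control"), s - 1)
    set.seed(700 + s)
    tr <- simulate_photometry(log, sensor_preset("grab_da"), quick_art())
    preprocess_session(tr, log, post_len = 12)$tensor_z
  })
  h <- heatmap_matrix(tensors, "trial_by_trial", "plus")
  expect_equal(nrow(h$matrix), 3 * 2)
  hs <- heatmap_matrix(tensors, "session_average", "plus")
  expect_equal(nrow(hs$matrix), 3)
  expect_equal(hs$matrix[1, ], colMeans(h$matrix[1:2, ]))
})
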