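# Shared fixtures and independent oracles. Test problem sizes are scaled
# down (short ITIs, few trials, reduced sampling rates) so the suite stays
# fast; the generator's defaults are exercised where the property under
# test concerns the default configuration itself.

quick_config <- function(n = 4, iti_min = 14, iti_max = 18, seed = 1, ...) {
  session_config(n_trials_per_cs = n, iti_min = iti_min, iti_max = iti_max,
                 seed = seed, ...)
}

quick_art <- function(...) {
  artifact_params(fs_raw = 500, bleach_tau = 300, ...)
}

# --- independent oracles -------------------------------------------------

# OLS via the normal equations (closed form), independent of lm/lm.fit
ols_oracle <- function(x, y) {
  n <- length(x)
  sxx <- sum(x^2) - sum(x)^2 / n
  sxy <- sum(x * y) - sum(x) * sum(y) / n
  a <- sxy / sxx
  b <- mean(y) - a * mean(x)
  list(a = a, b = b)
}

# brute-force trapezoid: explicit loop over panels
trapz_oracle <- function(r, fs) {
  s <- 0
  for (i in seq_len(length(r) - 1)) s <- s + (r[i] + r[i + 1]) / 2
  s / fs
}

# signed extremum of largest magnitude, earliest wins
extremum_oracle <- function(r) {
  best <- r[1]
  for (v in r) if (abs(v) > abs(best)) best <- v
  best
}

# Pearson r and two-sided slope p-value from first principles
regression_oracle <- function(x, y) {
  n <- length(x)
  a <- ols_oracle(x, y)
  res <- y - (a$b + a$a * x)
  sxx <- sum((x - mean(x))^2)
  se <- sqrt(sum(res^2) / (n - 2) / sxx)
  tstat <- a$a / se
  r <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  list(slope = a$a, intercept = a$b, r_squared = r^2,
       p_value = 2 * stats::pt(-abs(tstat), n - 2))
}

# total overlap of a list of [start, end) intervals with [lo, hi)
overlap_oracle <- function(starts, ends, lo, hi) {
  tot <- 0
  for (i in seq_along(starts)) {
    s <- max(starts[i], lo); e <- min(ends[i], hi)
    if (e > s) tot <- tot + (e - s)
  }
  tot
}

# all CS orderings with the given per-type counts whose longest run of
# identical types is <= max_run (exhaustive enumeration)
enumerate_valid_sequences <- function(n_per_cs, max_run) {
  slots <- utils::combn(2 * n_per_cs, n_per_cs)
  out <- list()
  for (j in seq_len(ncol(slots))) {
    cs <- rep("minus", 2 * n_per_cs)
    cs[slots[, j]] <- "plus"
    if (max(rle(cs)$lengths) <= max_run)
      out[[length(out) + 1]] <- paste(cs, collapse = ",")
  }
  unlist(out)
}

# a double-exponential transient (matches the simulator's kernel shape)
make_transient <- function(n, fs, t0, amp, rise = 0.1, decay = 1) {
  t <- (seq_len(n) - 1) / fs - t0
  out <- numeric(n)
  on <- t >= 0
  out[on] <- amp * (1 - exp(-t[on] / rise)) * exp(-t[on] / decay)
  out
}
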