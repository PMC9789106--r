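---
title: "Methods: simulating and analysing fibre photometry in touchscreen autoshaping"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating and analysing fibre photometry in touchscreen autoshaping}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(photoshape)
```

## What this package models

`photoshape` is a tested re-implementation of a common analysis workflow in
behavioural neuroscience: bulk fluorescence (fibre photometry) recordings of
genetically encoded sensors — dopamine (GRAB_DA), acetylcholine (ACh3.0) and
calcium (GCaMP6s in D1-SPNs, jRCaMP1a in D2-SPNs) — made in the nucleus
accumbens of mice learning a touchscreen Pavlovian autoshaping task. Because
the package is built around synthetic data, every stage can be validated
against ground truth: the generator knows exactly which signal it injected,
and the analysis chain must recover it.

The package has three layers:

1. **Task and behaviour simulation** (`session_config()`,
   `schedule_trials()`, `simulate_session()`): session schedules and
   behavioural event logs from a parametric learning agent.
2. **Photometry simulation** (`sensor_preset()`, `build_ideal_signal()`,
   `generate_raw_trace()`): multi-channel raw traces with event-locked
   sensor transients, photobleaching, shared motion artifacts and noise.
3. **Analysis** (`preprocess_session()`, `compute_trial_metrics()`,
   `behavior_summary()`, `summarize_session()`, `linear_regression()`):
   the standard conditioning chain and the windowed metrics and
   session-level statistics computed from it.

## The task

A session consists of 40 trials — 20 presentations of a reward-predicting
stimulus (CS+) and 20 of a neutral one (CS−) — in pseudorandom order with
no more than two identical CS types in a row. Each trial begins after a
variable 45–90 s inter-trial interval (ITI); the CS is lit for 10 s; after
CS+ offset a 10 µl reward is delivered to the magazine. Sessions end after
all 40 trials or 60 min, whichever comes first. These constants are the
defaults of `session_config()`. Three modes exist: *deterministic* (CS+
side fixed), *reversal* (sides swapped: the former CS+ location becomes
CS−), and *non-deterministic* (each trial's side drawn 50/50, so the
animal cannot predict the rewarded location).

### Scheduling

The run-length rule ("no more than two alike in a row") is enforced
exactly. Rather than rejection-sampling permutations — for 20+20 trials
only about 9.4×10⁷ of the C(40,20) ≈ 1.4×10¹¹ orderings are valid, an
acceptance rate near 7×10⁻⁴ — `schedule_trials()` draws each position with
probability proportional to the number of valid completions, precomputed
by dynamic programming. This is an exact sequential sampler from the same
distribution (uniform over valid sequences) at ~40 draws per schedule. The
tests verify uniformity by exhaustive enumeration at small n.

### The behavioural agent

The task's primary performance measure is the time spent in front of each
CS screen during its presentation. The agent is deliberately simple: the
expected fraction of the CS window spent approaching follows an
exponential acquisition law,

$$m_s = \mathrm{asym} + (\mathrm{init} - \mathrm{asym})\,(1 - \lambda)^s,$$

with per-CS asymptotes and learning rate λ per session *s*
(`learning_curve()`). On reversal the CS roles swap and each curve
restarts from the pre-reversal value of the swapped stimulus. Per-trial
approach time is a Gaussian draw around \(m_s\) (SD
`approach_noise_sd`), truncated to the CS window, placed as a single
approach bout at a uniform position; reward-collection latencies are
log-normal. None of this is a claim about mouse cognition — it is the
minimal generative model whose replay through `behavior_summary()` and
`fit_learning_curve()` recovers its own parameters, and whose genotype
presets reproduce the qualitative group differences: `control` acquires a
strong CS+/CS− discrimination, `vachtcko` (no acetylcholine release from
striatal cholinergic interneurons) stays near-flat through acquisition,
`vglut3cko` behaves like controls.

A single per-session learning variable \(L_s = 1 - (1-\lambda)^s\) drives
both behaviour (which is affine in \(L\)) and, through each kernel's
`learning_gain`, the sensor amplitudes. This shared dependence is what
makes session-level signal–behaviour regressions meaningful rather than
coincidental.

## The photometry generator

Each sensor is a repertoire of event-locked kernels (`sensor_kernel()`):
zero before `delay`, then
\(\pm A_\mathrm{eff}\,(1 - e^{-t/\tau_r})\,e^{-t/\tau_d}\) with
\(A_\mathrm{eff} = A\,(1 + g L)\) clipped at zero. Presets encode the
qualitative response shapes of each sensor: a ~1 s phasic onset response
to both CS; for dopamine a sustained CS+ component growing with learning
and a reward response peaking ~1 s after delivery that fades as learning
progresses; for acetylcholine a 5–8 s reward-evoked pause (trough ~2 s
after delivery) that deepens with learning, abolished in the `vachtcko`
preset; bi-phasic (burst–pause) and monophasic reward responses for D1-
and D2-SPN calcium. Kernel time constants are stated choices made to
match the published average-trace shapes (peak latencies and durations),
not fitted values; two cautionary notes from development are recorded
below under *Numerical choices*.

The raw recording model is

$$\mathrm{sig}(t) = F_0^{sig}\,B(t)\,[1 + \mathrm{ideal}(t) + m(t)] + \varepsilon, \qquad
  \mathrm{ref}(t) = F_0^{ref}\,B(t)\,[1 + m(t)] + \varepsilon,$$

with a shared single-exponential bleaching trend
\(B(t) = 1 - \beta\,(1 - e^{-t/\tau_b})\) and shared multiplicative motion
transients \(m(t)\) (Poisson arrivals, signed Gaussian amplitudes, ~0.3 s
shapes). This is precisely the regime in which a linear isosbestic
regression is a valid corrector: both artifact processes enter the two
channels with the same fractional effect. Artifact magnitudes
(`artifact_params()` defaults) are plausible-recording choices, not
measurements. Raw traces are generated at 1 kHz by default — enough to
exercise the decimation path without simulating the hardware's 12 kHz
lock-in carriers, which are out of scope.

## The conditioning chain

`preprocess_session()` applies, in a fixed order:

1. **Decimation to 100 Hz** — zero-phase FIR anti-alias filter, then
   keeping every q-th sample; only integer factors are supported, so
   results are bit-reproducible.
2. **6 Hz low-pass** — 4th-order Butterworth applied forward–backward
   (zero phase), to both channels *before* fitting, so the fit does not
   chase out-of-band noise. Phase-preserving filtering matters because a
   causal filter would displace event latencies.
3. **Isosbestic fit** — one ordinary least-squares fit of the signal
   channel on the 405 nm reference over the whole session (not per
   trial), giving the fitted reference \(a\,\mathrm{ref} + b\).
4. **ΔF/F** — \((\mathrm{sig} - \mathrm{fitted})/\mathrm{fitted}\).
5. **Trial extraction** — peri-CS windows (default 1 s baseline + 21 s),
   nearest-sample alignment, half-open intervals; windows that would
   leave the trace raise an error naming the trial.
6. **Baseline z-scoring** — each trial is centred and scaled by the mean
   and *population* standard deviation of its own 1 s pre-CS baseline.

### Numerical choices

- *Filter edges.* `signal::filtfilt` starts both passes from zero state,
  which corrupts trace ends; all filtering therefore uses odd-reflection
  end padding (several settle times long), trimmed after filtering.
- *Recovery up to an offset.* The reference fit absorbs the component of
  the true signal spanned by the reference and a constant; recovered
  ΔF/F therefore matches the injected signal only up to a small additive
  offset (the session mean of the injected signal). The recovery tests
  compare mean-centred traces; downstream per-trial baselining removes
  the offset in any case.
- *Population σ.* The z-score denominator divides by *n* (population
  convention), the plain reading of the formula; switching to the sample
  convention is a one-line change in `zscore_trials()`.
- *Kernel smoothness matters.* Two generator pathologies found during
  development are worth recording. A CS-long boxcar component (an
  instantaneous step at CS onset) leaks backward through the zero-phase
  filter into the pre-CS baseline, inflating the baseline SD of exactly
  the trials whose signal is largest; sustained components should rise
  smoothly. And a transient that peaks inside the first endpoint segment
  of its search window (see below) tilts the estimated baseline through
  the peak and can flip the sign of its own AUC. Neither is a defect of
  the analysis chain — both are properties a real recording would show —
  but they constrain what a faithful generator must look like.
- *Ties.* Peak height takes the residual extremum of largest magnitude;
  on ties the earliest sample wins.

## Windowed metrics

`compute_trial_metrics()` applies declarative `window_spec()`s per trial:
the mean during CS presentation; signed AUC and peak height against an
**endpoint-weighted baseline** (the straight line through the means of the
first and last 15% of the search window, each anchored at its segment
centre — the fraction is configurable); or a transient count. The search
windows are the study's: 5 s after CS+ offset for the dopamine reward
response, 10 s for acetylcholine, 10 s post-offset means for SPN calcium.
AUC is signed (dips negative) because the acetylcholine reward pause is
reported as a *decrease*; a sign convention must exist and this one is
stated. Transient counting smooths the first derivative with a
Savitzky–Golay filter and counts upward crossings of
`min_prominence / sg_window` (a rise of at least the prominence within
about one smoothing window), with a one-kernel refractory lockout; the
threshold default (0.5 z) is calibrated on the simulator, as no printed
value exists.

## Session statistics

`behavior_summary()` computes approach time as the summed overlap of
approach-zone intervals (on the trial's lit side) with the CS window;
collection latency as reward-to-magazine-entry time, with uncollected
rewards counted and excluded pairwise. `summarize_session()` takes per-CS
means and Δ(CS+ − CS−) contrasts. `linear_regression()` is ordinary least
squares with the two-sided t-test on the slope; *sessions are the
regression unit*, matching how signal–behaviour correlations are
presented. No multiple-testing adjustment is applied, matching the source
analyses. `heatmap_matrix()` stacks trials in session-then-trial order
(acquisition trials 1→200, reversal 201→400 in the full design) or one
averaged row per session.

## Problem sizes

The test suite and the analysis drivers run the full chain on desk-scale
blocks chosen as the package's own defaults for fast, deterministic
validation: typically 4–6 trials per CS, ITIs of 14–18 s, 500 Hz raw
traces, 10-session blocks, and 100–10⁴ seeds for property checks
(scheduler fuzzing uses 10⁴ seeds; oracle-equivalence checks use 10³
random instances). The task constants that the quantification depends on
— 10 s CS, 1 s baseline, 100 Hz analysis rate, 6 Hz cutoff, the 5 s and
10 s reward search windows — are always the study's. `analysis/02` runs
one full-scale session (40 trials, 45–90 s ITI, 1 kHz) end to end.

## What passing tests do and do not show

The synthetic generator emulates event-locked transients, bleaching,
shared multiplicative motion and white noise. It does not emulate
hemodynamic contamination, sensor photoswitching, wavelength-dependent
motion (which breaks the shared-artifact assumption behind isosbestic
regression), non-exponential bleaching, correlated noise, or behavioural
phenomena beyond the exponential approach law (no satiety, no
within-session dynamics, no goal-tracking/sign-tracking individual
differences). Passing tests therefore certify the *analysis chain* —
that it recovers what the generative model injects, at the stated
tolerances — not that the generative model captures real recordings.
Statistical inference beyond simple regression (repeated-measures ANOVA,
mixed-effects models, post-hoc tests) is deliberately out of scope;
exported tidy CSVs are intended for standard statistics software.
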