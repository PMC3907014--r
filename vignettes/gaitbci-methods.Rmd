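---
title: "Decoding idling vs. walking motor imagery for BCI gait control: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decoding idling vs. walking motor imagery for BCI gait control}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gaitbci)
```

## The problem

A two-state, self-paced brain–computer interface (BCI) turns scalp EEG into
a binary walk/idle command for a robotic gait orthosis. The user performs
*kinesthetic motor imagery* (KMI): vividly imagining walking engages
sensorimotor rhythms — most prominently the 8–12 Hz band — whose power is
modulated relative to relaxed idling (event-related
(de)synchronization). `gaitbci` implements the full processing chain around
that physiological signal: offline model training, online sliding-window
decoding through a hysteretic state machine, session scoring, and a
Monte-Carlo significance control, plus a synthetic-data module so every
stage is testable without recordings.

## Offline model

Training data are cue-locked: the subject alternates 30-s epochs of idling
and walking KMI for 10 minutes (20 epochs) at 256 Hz. Processing:

1. **Artifact channel screen.** A channel is retained when the robust
   z-scores (median/MAD) of both its log-variance and its moment kurtosis
   are below 3. The threshold is a config knob
   (`exclude_artifact_channels(rec, z_thresh)`); the statistic pair targets
   the two dominant failure modes (drift/movement → variance; pops/spikes →
   kurtosis). No algorithm is prescribed for this step in the source
   protocol; this is the simplest reproducible stand-in.
2. **Spectral features.** Each 0.75-s analysis window is linearly
   detrended, Hamming-tapered, and a single periodogram per channel is
   integrated over half-open 2-Hz bins covering the analysis band
   \([F_L, F_H)\), giving a \(B \times C\) matrix \(d\) (bins × retained
   channels). Welch averaging is impossible at this window length; a single
   taper keeps the estimate deterministic and fast enough for the 4 Hz
   online clock. Band powers are log10-transformed before modelling
   (approximate Gaussianization of power).
3. **Classwise PCA (CPCA).** After global mean centering, a PCA subspace is
   fitted per class, retaining `var_retained` (default 0.9) of that class's
   variance. The piecewise map \(\Phi_C\) assigns a vector to the class
   subspace with the smallest class-centered reconstruction error (ties to
   idling) and projects it there linearly.
4. **1-D discriminant.** In each class subspace, a unit row vector \(T_A\)
   maximizes the Gaussian approximation of the mutual information between
   the projected feature and the class label,
   \(J(w) = \tfrac12\log(w^\top S_T w) - \tfrac12\sum_c p_c \log(w^\top
   \Sigma_c w)\), optimized quasi-Newton from the Fisher direction. A
   closed-form Fisher/LDA fallback is selectable (`method = "lda"`); in the
   equal-covariance case both coincide, which the tests exploit as an
   oracle. The composed feature is the scalar \(f = T_A \Phi_C(d)\).
5. **Bayesian classifier.** Per-class univariate Gaussians on \(f\) with
   empirical priors; the decision takes idling only when
   \(P(I\mid f^\star) > P(W\mid f^\star)\), so exact ties go to walking.
6. **Validation and band search.** Stratified 10-fold cross-validation
   refits the whole chain per fold. `optimize_band()` grows the band
   greedily on a 2-Hz grid from a seed band (default \([8,10)\) Hz, the
   alpha range): the bound whose 2-Hz extension improves mean CV accuracy
   most is extended until neither improves by > 0.5 percentage points,
   within \([0.5, 40]\) Hz. The search is contiguous by construction; with
   two disjoint informative bands it settles on one of them.

Open choices made here (the source protocol is silent): mean centering per
training fold; log-power features; half-open bin edges, zero-based sample
indexing, seconds on the session clock; `var_retained = 0.9` and the
\([8,10)\) seed band as explicit defaults.

## Online decoding

Every 0.25 s the last 0.75 s of EEG is featurized with the model's band and
channels, reduced to \(f^\star\), and converted to the instantaneous
posterior \(P(W\mid f^\star)\). The posterior is averaged over a trailing
2-s window (8 values; during warm-up, over what exists, so the trace stays
aligned with the cue clock) and fed to a binary state machine: idle→walk
only when \(\bar P > T_W\), walk→idle only when \(\bar P < T_I\) (strict
inequalities; initial state idling, since sessions begin at rest). The gap
between \(T_I \le T_W\) provides hysteresis against chatter.

`calibrate_thresholds()` formalizes what is done manually at the rig with a
histogram of \(\bar P\): with tail quantiles \(q_{I} = Q_{0.95}(\bar
P\,|\,\text{idle})\) and \(q_{W} = Q_{0.05}(\bar P\,|\,\text{walk})\), a
separated calibration (\(q_W \ge q_I\)) puts both thresholds symmetrically
inside the gap (midpoint ∓ a quarter gap); interleaved tails fall back, with
a warning, to \((T_I, T_W) = (q_W, q_I)\) — the midpoint ± half the crossed
quantile gap — which is the realistic overlapping-class case and yields
threshold pairs of the kind used in practice (e.g. 0.50/0.90). The
histograms are returned so an operator can override the proposal.

## Session metrics

Cues and decoded states are sampled as 0/1 sequences on the shared 4 Hz
clock. `max_cross_correlation()` reports the maximum Pearson correlation
over response lags 0–30 s (0.25-s grid, overlap region only, ties to the
smallest lag). An *omission* is a Walk cue never answered by a walking
state; a *false alarm* is a walking episode whose onset falls inside an
Idle cue, its duration running to the episode's end even across a
subsequent cue boundary (attribution by onset — episodes persisting from a
Walk cue into Idle are not new false alarms). `aggregate_sessions()` pools
sessions per subject and overall; when only per-session false-alarm
duration summaries are available, episode durations are reconstructed
exactly for up to two episodes (the two-point inverse of mean/SD) and
mean-replicated otherwise.

## Significance control

Decoded-vs-cue correlation can be inflated by the autocorrelation the 2-s
averaging and the hysteresis introduce, so significance is assessed against
a surrogate that preserves the posterior dynamics but carries no cue
information: \(X_{k+1} = \alpha X_k + \beta W_k\), \(W_k \sim U(0,1)\),
\(X_0 \sim U(0,1)\), \(Y_k = h(X_k)\) with \(h\) a hard clip to \([0,1]\)
(the "saturation" is unspecified at the source; the clip is the simplest
choice, and the fitted regime rarely activates it — the clip rate is
reported). Stationarity gives \(\alpha = \rho\) (lag-1 autocorrelation of
the observed instantaneous posteriors) and mean matching with
\(E[W] = 1/2\) gives \(\beta = 2\mu(1-\alpha)\). The stationary variance is
estimated and reported but unused in fitting. Each Monte-Carlo trial pushes
a surrogate posterior sequence of the session's length through the *same*
averaging and thresholds and scores it against the cues; the empirical
p-value is the fraction of trials whose maximum correlation strictly
exceeds the observed one, with reporting floor `1/n_trials`. Surrogate
trials that never leave idling have no defined correlation and cannot count
as exceedances.

## The synthetic world

`synth_config()` states the conditions the generators emulate:

* protocol shapes straight from the stated world — 20 × 30 s alternating
  training cues (600 s), 10 × 60 s online cues, 256 Hz, 16 channels by
  default (a montage subset; the hardware cap had 64);
* background EEG: 1/f noise (exponent 1) with a 20 % white floor, nominal
  10 µV SD, per-channel lognormal SD spread (σ = 0.25) and a slow
  multiplicative amplitude envelope. The last two are not decoration: with
  a perfectly homogeneous, stationary background, the class-modulated
  channels themselves are the only variance/kurtosis outliers and the
  artifact screen would reject exactly the informative channels;
* class signal: independent 8–12 Hz Gaussian processes on the modulated
  channels whose amplitude is multiplied during walking epochs. The gain is
  calibrated *on the realized noise* (via the windows' band-restricted
  complex spectra, so background/signal cross terms are exact) such that
  the single-window log band-power separation equals the requested
  `effect_size` d′. The default d′ = 2 represents a strong, cleanly
  decodable modulation; d′ = 0 is the chance-level control;
* online sessions apply the gain a configurable reaction delay (default
  1 s) after each cue switch, standing in for user response time;
* artifact channels add ≥ 10× slow sinusoidal drift plus a sparse spike
  train;
* gait traces: a periodic gyroscope pattern (1.1 s stride, the cadence of
  2 km/h treadmill walking) and three EMG channels with broadband bursts
  phase-locked to the cycle, amplitude-scaled per condition (active 1.0 >
  cooperative 0.55 ≫ passive 0.12 ≈ decoded 0.13; passive is deliberately
  nonzero — robot-driven stepping elicits real EMG).

What a green test does **not** establish: the generator has no volume
conduction or channel correlation, no eye/muscle artifact overlap with the
analysis band, no nonstationary drift of the class effect across a session,
and its class signal sits exactly where the seed band looks. Passing
accuracies on this world validate the pipeline's mechanics and
calibrations, not clinical decoding performance.

## Numerical choices and degenerate inputs

* Half-open intervals everywhere (cues, bins, windows) make epoching
  lossless and the clocks unambiguous; the trace clock starts at 0.75 s
  (first full window) and runs at 4 Hz.
* A tone at a 2-Hz bin edge leaks ~13 % of its power into the adjacent
  lower bin under the Hamming taper; this is inherent to the window, not a
  bug (tests pin both the mid-bin and the edge case).
* Constant sequences make Pearson correlation and the AR fit undefined;
  both error out naming the degenerate input. Lags whose overlap is
  degenerate are skipped.
* `fit_ar` clips \(\alpha\) into \([0, 1)\) with a warning (an iid-looking
  posterior stream can have slightly negative sample autocorrelation).
* Greedy band search on pure noise may random-walk a bin or two: 10-fold CV
  accuracy has sampling noise comparable to the 0.5-pp stopping tolerance.
* The EMG band-pass is a zero-phase FFT mask with raised-cosine edges;
  rectification follows filtering, so the full preprocesor is not literally
  idempotent (rectified-positive signals have DC the filter removes) — the
  filter stage is.
* Onset-ordering checks require the envelope to stay above the
  baseline-mean + 3 SD threshold for 100 ms, guarding against single noise
  excursions.

## Known limitations

Two-class decoding only; no adaptation to nonstationarity across sessions;
no spatially informed filtering (CSP, Laplacian); EDF support is a minimal
single-record reader/writer for interchange of synthetic sessions; the
published per-subject accuracies and real-session null maxima depend on
recordings that are not deposited, so they are inputs to aggregation
targets rather than reproduction targets here.
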