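---
title: "Decomposing decision RTs into sequential EEG events: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decomposing decision RTs into sequential EEG events: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`chronodecomp` models the multichannel EEG recorded between a stimulus and
the response on each trial as a sequence of short, trial-recurrent
multivariate events, and relates the recovered inter-event durations to two
classical psychophysical laws. This vignette explains the generative model,
the estimation machinery, the synthetic-data generator that defines the
package's reference conditions, and the design decisions behind the
numerical choices — in the spirit of a methods section a practitioner can
audit.

## The sequential-event model

Each trial's signal (channels x samples, truncated at the response) is
assumed to contain $N$ ordered events. Event $i$ is a 25 ms half-sine
deflection with a fixed spatial pattern; its single-trial peak time $t_i$
is unknown. The durations of the $N+1$ stages delimited by the stimulus,
the event peaks, and the response are gamma distributed with a fixed shape
of 2 and a free scale per stage, so the model is a hidden semi-Markov chain
over event placements:

$$p(t_1,\dots,t_N) \propto \prod_{i=0}^{N} P_i(t_{i+1}-t_i)\,
  \prod_{i=1}^{N} f_i(t_i),$$

with $t_0 = 0$, $t_{N+1} = T$ (the trial length in samples). $P_i$ is the
discretized gamma mass of stage $i$ (mass at integer duration $d$ equal to
$\mathrm{CDF}(d+0.5)-\mathrm{CDF}(d-0.5)$, renormalized over the trial) and
$f_i$ the event evidence.

**Evidence model.** The data are reduced to principal components of the
participant-averaged channel covariance (components retained up to 99.9%
of variance), z-scored per participant (mean and SD pooled over all of a
participant's trials, samples, and components — the pooled reading of the
ambiguous per-trial phrasing, chosen because per-trial z-scoring would
erase amplitude differences between trials), and cross-correlated with the
unit-energy half-sine template. Event evidence is a unit-variance Gaussian
model on these match scores, $\log f_i(t) = \sum_k (m_{ik} x_k(t) -
m_{ik}^2/2)$, the standard form in this model family.

**Estimation.** An exact forward–backward pass (implemented in C++; the
recursion is $O(N\,T^2)$ per trial) yields each event's posterior over peak
samples and the trial log-likelihood; EM alternates it with closed-form
updates: magnitudes are posterior-weighted means of the match scores, and
each stage scale is the mean posterior-expected duration divided by the
shape. The scale update uses differences of expected times rather than the
full pairwise duration posterior — an approximation that is exact in the
mean and cheap, and that preserved likelihood monotonicity in every dataset
we tested. Iteration stops at a relative log-likelihood gain below 1e-4 or
200 iterations.

**Minimum event separation.** Two model events must not explain the same
half-sine deflection. Without a constraint, EM happily places two events on
adjacent samples of one deflection (we observed exactly this). The fitting
routines therefore give interior stages a hard minimum duration of one
template width minus one sample, implemented as an offset on the
discretized gamma (durations are `location + gamma`). This mirrors the
generator's own constraint that every stage exceeds the template width, and
matches how this model family handles event identifiability. The
`event_model` constructor defaults to `location = 0`, so the unconstrained
model remains available (and is what the brute-force equivalence tests
exercise alongside constrained cases).

**Choosing the number of events.** `cumulative_fit()` grows the model one
event at a time: a zero-magnitude event is inserted into each stage in
turn (scale split in half), candidates are scored by a short EM run, the
best is refined to convergence, and the larger model is accepted if

1. the log-likelihood gain exceeds one unit *per trial*, and
2. no stage is degenerate (its expected duration in excess of the hard
   minimum must reach the template width).

The per-trial bar is the package's stopping rule where the reference
method's exact default is not public knowledge. It is set from measured
behavior: pure-noise data yield self-alignment gains below 0.3 per trial
(EM aligns to noise, so the gain never vanishes, and it scales with the
number of trials — which is why a fixed absolute threshold such as AIC/BIC
cannot work here), while a genuine event at the calibrated SNR gains
roughly 4 units per trial. The degeneracy rule catches duplicated events,
which converge to a stage pinned at the minimum separation. A fitted
dataset with no trial-recurrent events at all is flagged
(`no_reliable_events`) when even the single-event model improves on flat
evidence by less than one unit per trial.

## Psychophysical laws and the diffusion link

Durations (RTs or inter-event intervals) are binned into 10 equal-width
contrast bins per participant (each bin's contrast is the mean contrast of
its trials) and fitted per participant with three models:

* linear: $\alpha + \beta C$;
* Pieron: $\alpha + \beta C^{-\nu}$, $\nu \ge 0$ so the curve decreases
  with contrast (an intercept is included by default; the classical
  intercept-free form is available);
* Fechner diffusion: the perceived difference between two patches at
  contrasts $C \pm \delta/2$ is $p = \beta \log\frac{C+\delta/2}{C-\delta/2}$,
  and a proportional-rate diffusion with drift proportional to $p$ gives
  $\mathrm{RT} = \frac{A}{\beta p}\tanh(A p) + T_0$ and
  $P_c = (1+e^{-2Ap})^{-1}$. As $p \to 0$, RT tends to $A^2/\beta + T_0$
  and accuracy to 1/2; the implementation uses the analytic limit. A single
  sensitivity $\beta$ serves both the perceived difference and the drift
  (the notation is ambiguous on whether these are one or two parameters;
  one parameter keeps the model identifiable from mean RTs).

Fitting is bounded nonlinear least squares (Levenberg–Marquardt with box
constraints, five jittered starts with a fixed seed, to tame the `tanh`
nonconvexity): $\beta \in (0, 50]$, $A \in (0, 10]$, $T_0$ between 0 and
the smallest bin mean; the diffusion term is treated as seconds and $T_0$
as milliseconds. Model comparison is leave-one-contrast-bin-out: refit on
the remaining bins, predict the held-out bin, pool squared prediction
errors across bins and participants, and report the RMSE (ms) and the
$R^2$ of predicted versus observed bin means; the winner is the smallest
RMSE. Contrast "levels" are realized as the 10 bins — the natural reading
when contrast is sampled continuously.

Because accuracy is governed by the same two parameters $A$ and $\beta$
that shape the RT curve, a fit on durations alone predicts the proportion
of correct responses per bin; `predict_accuracy()` reports that prediction
and its $R^2$ (flagged undefined when observed accuracy has no variance).

## The synthetic-data generator

The generator is first-class, tested code: it produces the exact
statistical structure the estimator assumes, plus the ground truth needed
for recovery tests.

* **Stimuli.** Contrast uniform on [0.035, 0.955]; the correct side
  carries $+\delta/2$ and the incorrect side $-\delta/2$ with
  $\delta = 0.05$.
* **Stages.** Six stages around five events, emulating the cascade
  identified in visual decision making: a constant 70 ms early-visual
  stage; two Pieron stages (35 + 25$C^{-1/2}$ and 45 + 30$C^{-1/2}$ ms)
  for encoding; a Fechner-diffusion decision stage ($\beta = 8$,
  $A = 1.5$, $T_0 = 60$ ms) and a shorter diffusion tail ($\beta = 15$,
  $A = 0.8$, $T_0 = 35$ ms); and a constant 55 ms motor stage. Mean RT is
  ~550 ms, the first event peaks ~70 ms after stimulus and the last
  shortly before the response. Every stage duration is gamma(shape 2,
  scale mean/2); correctness is Bernoulli with the decision stage's
  $P_c$. Under speed instructions the decision criterion drops to
  $0.8A$ and the remaining stages (except stimulus-to-first-event)
  shrink by 10% — boundary lowering is how diffusion models express
  speed stress, and it couples faster decisions with more errors, as
  observed empirically.
* **Epochs.** 32 channels (standard montage names) at 200 Hz; each event
  contributes amplitude x unit-norm topography x half-sine (or a ramp
  ending at the peak, the shape expected of an accumulation signal);
  noise is AR(1) Gaussian per channel (coefficient 0.9, marginal SD
  2.5 uV), giving EEG-like temporal smoothness. The fourth event carries
  a lateralized central component (C3/C4) so asymmetry statistics have
  signal. Trials in which any stage falls below the 25 ms template width
  are regenerated, keeping events separable — the same constraint the
  estimator encodes.
* **Calibration.** The event amplitude default (20 uV against the 2.5 uV
  noise) was set once by a sweep so that single-trial peak-time recovery
  correlation comfortably exceeds 0.9 for every event; this "default SNR"
  is the reference condition for all recovery claims. Real EEG does not
  announce its event SNR, so this is a calibration choice, not an
  empirical value.

What the generator deliberately omits: volume-conducted spatially
correlated noise, eye/muscle artifacts, overlapping or optional events,
and between-participant topography variability. Passing recovery tests
therefore shows the estimator works when its assumptions hold — it does
not certify performance on real recordings, where misspecification (e.g.,
events absent on some trials, C1/P100-style overlap) is the norm.

## Event-level statistics

* **Trial rejection** uses the standard rules (RT outside [100, 3000] ms,
  any channel exceeding 100 uV inside the stimulus–response window), and
  analysis windows are extended by 10 ms past the response so events
  peaking at the response survive the cross-correlation edge mask.
* **Asymmetry.** Channel values at the single-trial most-likely event
  times, averaged per participant and event, are compared left minus
  right over the 14 lateral pairs with one-sample t-tests, Bonferroni
  corrected over pairs x events (70 tests at base alpha 0.05, corrected
  threshold 0.00071). Zero-variance differences get p = 1 and a flag.
* **Match series and event-locked averages.** An event's average
  topography serves as a spatial filter (dot product per sample) from
  stimulus onset to 100 ms past the event peak; averaging after
  re-centering each trial at its peak undoes latency smearing (the
  realigned average recovers the template where the stimulus-locked
  average is wider and lower).
* **Cluster permutation test.** Per-sample paired t statistics are
  thresholded at the two-sided p = 0.05 t quantile (the conventional
  default; the reference implementations do the same), clusters are
  contiguous same-sign suprathreshold runs, mass is the summed t, and the
  null is the maximum absolute mass under random within-participant sign
  flips (1024 by default, identity included so p is never below
  1/n_perm); the test suite checks its type-I rate against the nominal
  level on null simulations.
* **Build-up regression.** Per trial, the match series over the 250 ms up
  to the event peak is regressed on time with the origin at the peak, so
  the intercept is the fitted evidence at commitment and the slope the
  build-up rate per second; trials with fewer than 3 samples are dropped.
  Per-contrast-bin averages of intercepts and slopes are rank-correlated
  (Spearman) with bin accuracy.

## Problem sizes and numerical notes

The reference recovery condition is 5 participants x 100 trials at 200 Hz
(a full ten-replicate recovery study runs in a few minutes on one CPU).
Law-selection simulations use single sessions of 1000 trials — the order
of trials a participant contributes in such an experiment — because
trial-level gamma noise (CV 0.71) at 10-bin resolution needs that much
data to separate logarithmic from linear curvature. Cluster-test
calibration uses 200 null replicates of 20 participants. Ties in
posterior argmax break to the earliest sample; rank ties in Spearman
correlations use average ranks; degenerate gamma scales are floored at a
quarter sample; posterior recursions are rescaled per stage, so trials up
to 10^4 samples run without underflow.

## Known limitations

The estimator fits one model across participants and conditions, assumes
every event occurs on every trial, and cannot separate events closer than
the template width. The cumulative fit's stopping rule is a calibrated
package choice, not a reimplementation of any particular tool's default.
The diffusion link predicts mean RT only (no full RT distributions), and
the LOO comparison operates on bin means, so it inherits the binning
resolution.
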