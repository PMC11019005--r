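---
title: "Modeling proactive inhibitory control: belief dynamics, ERP features, and the motivated stop-signal task"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling proactive inhibitory control}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sstdbm)
```

## The scientific problem

In the stop-signal task (SST), participants respond to a go stimulus as
fast as possible, but on a minority of trials (here 25%) an auditory stop
signal instructs them to withhold the response. Performance on such tasks
is not purely reactive: people track the local history of trial types,
form an expectation of whether the next trial will require stopping, and
slow down proactively when that expectation is high. `sstdbm` implements a
complete, testable pipeline for quantifying this proactive control and its
interaction with motivational incentives (reward vs punishment feedback at
low/high monetary stakes) and with early visual attention, indexed by the
single-trial P1 and N1 event-related potentials at posterior electrodes
(PO7/PO8).

Because no human dataset ships with the package, a first-class synthetic
module simulates the full task — trial sequences, the adaptive
stop-signal-delay staircase, a race-model agent whose go process slows
with its own stop expectation, and single-trial ERP waveforms — so that
every analysis stage can be validated by parameter- and effect-recovery
studies.

## The Dynamic Belief Model

The core inferential object is a Dynamic Belief Model (DBM): a leaky
beta-Bernoulli filter over the latent stop-trial rate $r_k$. The observer
believes that on each trial the rate stays what it was with probability
$\alpha$ and is re-drawn from a fixed prior $\mathrm{Beta}(a, b)$ with
probability $1 - \alpha$, where the prior is parameterized by its mean
$m = a/(a+b)$ and scale $s = a+b$. Writing $S_{k-1}$ for the outcome
history, the predictive belief for trial $k$ is

$$p(r_k \mid S_{k-1}) = \alpha\, p(r_{k-1} \mid S_{k-1}) +
  (1-\alpha)\, p_0(r_k),$$

the posterior follows Bayes' rule with the Bernoulli likelihood
($P(\text{go}) = 1 - r_k$), and the trial-wise stop expectation is the
predictive mean

$$P(\text{stop})_k = \langle r_k \mid S_{k-1} \rangle .$$

`dbm_pstop()` emits this quantity for every trial, always *before* the
trial's outcome is observed; the first prediction therefore equals $m$.
At $\alpha = 1$ the filter collapses to conjugate beta-Bernoulli updating
(Laplace's rule for a flat prior), which provides an exact closed-form
oracle used extensively in the test suite. At $\alpha = 0$ it is
memoryless and predicts $m$ forever.

### Numerical representation

The belief is carried on a grid of 200 bin midpoints of $(0,1)$ by
default. Midpoints (rather than endpoints) keep the beta density finite
when $a < 1$ or $b < 1$, and the midpoint rule is superconvergent for the
ratio-of-sums that defines the predictive mean: against the conjugate
closed form the 1000-point grid is accurate to ~3e-7 over 1000 trials, and
the default 200-point grid agrees with a 5000-point quadrature reference
to better than 1e-3 per trial. Mass is renormalized after every
multiplication (in the batched C++ sweep the normalizer is carried as a
scalar folded into the leak coefficient, which is algebraically identical),
so 288-trial blocks sit far from underflow. Doubling the grid at 200
points changes no prediction by more than 1e-3.

## Fitting the DBM to behavior

The model assumes a positive linear relationship between the stop
expectation and go RT. Parameters are estimated per subject and condition
block by exhaustive grid search: for every triple in
$\alpha \in \{0.25, 0.26, \ldots, 1.00\}$,
$m \in \{0.01, \ldots, 0.99\}$, $s \in \{2, 4, \ldots, 20\}$ (75,240
candidates), the P(stop) sequence is computed from the trial-type history
alone and the eligible go RTs are regressed on it; the triple maximizing
the regression fit $R^2$ wins. Three choices deserve comment:

- **Eligible RTs** are responses on trials *without* a stop signal.
  RTs on failed stop trials are censored by the stop process (only fast
  go finishes survive) and would bias the slope, so they are excluded;
  `dbm_grid_fit()` documents this and the trial table keeps enough
  information to revisit the choice.
- **Robust regression.** `robust_fit()` is a Huber M-estimator
  (tuning constant 1.345, IRLS with MAD scale re-estimated per iteration),
  cross-checked against `MASS::rlm`. The reported $R^2$ is the squared
  Pearson correlation between fitted and observed RT. Because fitted
  values of a straight-line fit are affine in the predictor, this equals
  $\mathrm{cor}(x, y)^2$ whenever the slope is nonzero — so the grid
  ranking is computed directly from the correlation (exactly equivalent
  and orders of magnitude faster), and the Huber fit is evaluated once
  for the winning triple to report its slope and intercept.
- **Determinism.** Candidates are scanned in smallest-$(\alpha, m, s)$
  lexicographic order and ties within 1e-12 keep the first candidate, so
  refits are bit-identical.

The hot loop (belief filtering across all candidates) is C++ (Rcpp); the
full default grid takes well under a minute per 288-trial block on one
CPU, and simulation studies use a documented coarse grid
(`dbm_search_space_coarse()`, steps 0.05/0.05 and $s \in \{2,6,10,14,18\}$,
1,520 triples).

## The synthetic task and agent

`task_config()` fixes the design constants: 4 incentive blocks
(low/high reward, low/high punishment; $0.05 / $0.25 stakes) of 288
trials, exactly 72 stop trials per block, go window 1200 ms, SSD
staircase initialized at 500 ms moving ±50 ms within [50, 1200] ms
(success → harder, the standard tracking rule targeting 50% stop
accuracy).

The agent (`agent_config()`) is an independent-race model. Its go finish
time is ex-Gaussian — positively skewed like empirical RT distributions —
with mean $\text{base} + \text{slope} \cdot P(\text{stop})$ plus a
high-stake slowing offset; on stop trials an independent stop process of
latency SSRT races it, and a response is emitted iff the go process wins.
The agent's expectation comes from the *same* DBM code that the fitting
side uses, enabling exact parameter-recovery experiments.

Default calibration (chosen once, as the package's study conditions):
$\alpha = 0.95$, $m = 0.30$, $s = 14$ (typical group-level best-fit
values for this task), base 680 ms, slope 1000 ms per unit P(stop),
Gaussian SD 50 ms, exponential tail 50 ms, stake offset 10 ms, SSRT
300 ± 30 ms, 2% go lapses. These put mean go RT near 950 ms and the
RT-on-P(stop) regression in the $R^2 \approx 0.25$ regime the fitting
self-consistency checks assume. Real data are noisier: empirical
trial-level RT models report standardized P(stop) effects an order of
magnitude smaller, so passing recovery tests here demonstrates
correctness of the machinery, not that human parameters are recoverable
with this precision.

### Synthetic ERP amplitudes and waveforms

Per-trial P1/N1 mean amplitudes follow a linear model over effect-coded
valence (punishment = +1), stake (high = +1) and continuous P(stop),
including all interactions, plus N(0, 3 µV) trial noise
(`erp_effect_config()`). The default coefficients encode the qualitative
pattern the pipeline is designed to detect: a positive P(stop) slope of
P1 in punishment blocks only, and a stake-dependent N1 sign flip
(positive slope in high punishment, negative in high reward, null at low
stake). A per-trial latent attentional state links the N1 to stopping:
it loads on the synthetic N1 (+1.5 µV/SD) and shifts the agent's stop
latency on stop trials with a condition-specific gain, producing the
"more negative N1 × higher P(stop) → better stopping in high reward"
coupling as an emergent property of the race.

`render_epochs()` turns amplitudes into two-channel epochs (−200..800 ms
at 500 Hz): Gaussian-shaped components centered at 104 ms (SD 12 ms,
positive) and 154 ms (SD 15 ms, negative), with per-trial latency jitter
in whole samples (±8 ms) and optional waveform noise. The centers sit on
the 2 ms sample grid so that noiseless rendering round-trips *exactly*
through the extractor. What the renderer does **not** emulate: overlapping
activity from other components, 1/f background EEG, ocular artifacts,
channel-specific noise covariance — so extraction tests validate the
feature machinery, not robustness to real EEG nuisance structure.

## ERP feature extraction

`extract_erp_features()` chains: baseline correction (mean over
[−200, 0) ms per channel), artifact screening per channel (reject if any
adjacent-sample step exceeds 50 µV/ms or the epoch range exceeds 80 µV on
either channel), peak detection as the extreme sample in the 90–120 ms
(P1, positive) and 130–180 ms (N1, negative) windows with ties going to
the earliest sample, the ±24 ms mean amplitude around each peak
(truncated at epoch edges, which the default windows never reach), and
averaging of the two channels' amplitudes into a combined posterior
feature. The search windows are fixed constants of the analysis (the
window-discovery step that produced them is not re-run) but are
arguments, not magic numbers.

Amplitudes are z-scored within subject, pooled across blocks
(`standardize_amplitudes()`): the downstream models compare blocks, so
per-block scaling would erase exactly the condition effects of interest.
Stop trials with SSD ≤ 150 ms (boundary inclusive) are removed before any
trial-level ERP model, so early stop-signal processing cannot leak into
go-locked windows.

One measured property worth knowing: with waveform noise, picking the
extreme sample induces a small off-center averaging loss (about −1% of
the component amplitude at 1 µV noise), because the ±24 ms window is
centered on a noisy latency. The acceptance suite bounds this bias at 2%
of the amplitude; it is a property of single-trial peak extraction
generally, not of this implementation.

## SSRT and behavioral summaries

`compute_ssrt()` implements the consensus integration method with
omission replacement: go omissions are replaced by the maximum observed
go RT, and SSRT is the $\lceil p \cdot n_{go} \rceil$-th ascending go RT
minus the mean SSD, where $p$ is the probability of responding on a stop
trial. The ceiling rank convention shifts the estimate by at most one RT
quantile step; estimates with $p$ outside [0.1, 0.9] are flagged
unreliable. Simulation shows the estimator recovers a true 300 ms SSRT
within ±15 ms at 1,000 stop trials.

## Trial-level mixed models

`fit_trial_model()` fits
`outcome ~ valence_c * stake_c * pstop [* amplitude] + (1 | subject)`
with ±0.5 effect coding, Gaussian for RT and z-amplitudes and a logit
link for stop errors. Estimation is (restricted) maximum likelihood via
`lme4`/`lmerTest` with Wald 95% intervals. The study this package grew
from estimated these models in a Bayesian framework; we default to ML
because the published prior specification — uniform Beta(1,1) on model
coefficients — would confine signed effects to [0, 1] and cannot have
been meant literally, and because ML makes the recovery and calibration
suites fast and deterministic. The random-effects structure is
intercept-only per subject, matching the published description; P(stop)
enters uncentered by default with a centering switch.

`simple_slopes()` decomposes interactions into per-condition slopes of
P(stop) (or of an amplitude × P(stop) product) as linear combinations of
the fixed effects with propagated intervals. `bin_tertiles()` cuts the
pooled P(stop) distribution at its empirical thirds (lower-inclusive
labeling) for visualization-style summaries; with the concentrated
P(stop) distributions this task produces, the cutpoints sit close
together (around 0.2–0.3), as expected.

## The pipeline and its validation

`run_pipeline()` chains simulate → fit → features → merge → models and
writes CSV tables plus a JSON manifest (seed, counts, missing cells,
versions); identical seeds give identical tables. The acceptance-level
checks it must pass, at the problem sizes the package uses for them:

- exact stop-trial counts (72/288), and staircase convergence of a
  stationary agent's stop-response rate to 50% ± 3 points over ≥ 2,000
  stop trials;
- conjugacy and dense-quadrature oracles for the belief filter;
- DBM parameter recovery: 20 subjects, one 288-trial block each, coarse
  grid — median recovered $\alpha$ within ±0.05 and $m$ within ±0.15 of
  (0.95, 0.30), with recovery degrading monotonically when RT noise is
  quadrupled;
- SSRT recovery within ±15 ms at 1,000 stop trials;
- exact noiseless ERP round-trips and bounded noisy-extraction bias;
- end-to-end effect-pattern recovery (P1 punishment-positive slopes, N1
  HR-negative/HP-positive, stop-error N1 × P(stop) benefit in high
  reward) in at least 80% of 20 seeded runs at 20 subjects;
- ~95% coverage of zero by the 95% intervals across fixed effects in
  zero-effect simulations (20 runs, 10 subjects).

## Known limitations

- The fitted $R^2$ surface over $(\alpha, m, s)$ is flat near $\alpha=1$
  when sequences are short; prior-scale $s$ is only weakly identified by
  design (the paper-level analyses use it descriptively), and no
  uncertainty is attached to the grid point estimates.
- The generator's effect sizes are deliberately comfortable; null
  behavior is calibrated, but power at *empirical* effect sizes is out
  of scope.
- Waveform realism is limited to what the extraction chain consumes;
  anyone ingesting real epoched EEG should enter at
  `extract_erp_features()` with a conforming `sst_epochs` container.
- Bayesian estimation of the mixed models (and hence posterior-fraction
  summaries) is not implemented; the ML path covers the package's
  inferential claims.
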