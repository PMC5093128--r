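---
title: "Modelling stop-signal anticipation: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling stop-signal anticipation: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stopbayes)
```

`stopbayes` implements a complete analysis chain for proactive control in
the stop-signal task (SST): trial-by-trial Bayesian estimation of the
probability of an impending stop signal, race-model behavioral estimators,
a first-level GLM for region-of-interest BOLD with parametric modulators,
second-level trait regressions, and a synthetic cohort generator that makes
the whole chain testable end to end. This vignette explains the models, the
tunable parameters, and the design decisions taken where the methodology
left genuine freedom.

## The dynamic belief model

Participants in the SST behave as if they continuously re-estimate how
likely the next trial is to contain a stop signal. The dynamic belief model
(DBM) formalizes this: the latent stop rate $r_k$ on trial $k$ persists
from the previous trial with probability $\alpha$ and is otherwise redrawn
from a generic beta prior $\pi(r)$ with mean $pm$ and concentration
$scale$ (shape parameters $a = pm \cdot scale$, $b = (1-pm) \cdot scale$):

$$p(r_k \mid s_{k-1}) = \alpha\, p(r_{k-1} \mid s_{k-1}) +
  (1-\alpha)\, \pi(r_k).$$

Each trial contributes a Bernoulli likelihood ($r$ for stop, $1-r$ for go)
through Bayes' rule, and the reported anticipation

$$p(\mathrm{Stop})_k = E\big[r_k \mid s_{k-1}\big]$$

is the mean of the *predictive* distribution, computed strictly before
trial $k$ is observed. Two limits anchor intuition and testing: $\alpha=1$
reduces to conjugate beta-Bernoulli updating with the closed form
$p(\mathrm{Stop})_k = (pm \cdot scale + \#\text{stops before } k) /
(scale + k - 1)$, and $\alpha=0$ pins $p(\mathrm{Stop})$ at $pm$. For
intermediate $\alpha$ the filter is well approximated by a causal
exponential filter on the stop history (`exp_filter()`), which the test
suite uses as a comparison oracle (best-decay correlation above 0.95).

**Numerical choices.** Beliefs are discretized on the midpoints of
`grid_size` equal-width bins of $(0,1)$ (default 100) and renormalized
after every step; midpoints avoid the endpoint singularities of beta
densities with shape below one, and the representation is closed under
both the Bayes and the mixture update. All arithmetic is in linear space —
at task lengths of a few hundred trials the masses stay far from
underflow, and each step renormalizes explicitly (tested to $10^{-10}$).
Doubling the grid moves no $p(\mathrm{Stop})$ value by more than 0.002.
The first trial needs no special casing: its predictive distribution *is*
the prior, so $p(\mathrm{Stop})_1 = pm$ up to discretization.

**Parameter reading.** "Mean `pm` and shape `scale`" is interpreted in the
standard mean/concentration form, $scale = a + b$; the alternative reading
(`scale` as the second shape parameter alone) was considered and rejected
because the mean/concentration form keeps `pm` meaningful independently of
`scale`. Default analysis-side parameters are $\alpha = 0.8$, $pm = 0.25$
(the task's stop fraction), $scale = 4$ — values in the range used across
the sequential-effects modelling literature. Because the originating
methodology does not fix these, `dbm_grid_fit()` also offers a principled
data-driven selection: it picks, over a candidate grid, the parameter set
whose $p(\mathrm{Stop})$ series correlates most strongly with go RT, with
a deterministic first-in-grid tie-break, and flags fits whose best
correlation is not significantly positive.

## Task simulation

`sst_schedule()` draws each trial independently as stop with probability
0.25, a uniform 1–5 s foreperiod between fixation and go signal, a 1 s
response window, and a 2 s inter-trial interval; onsets accumulate these
durations so the schedule doubles as the fMRI event timeline. Sessions
default to 4 × 100 trials (about ten minutes each).

Subjects are simulated by an independent race (`simulate_subject()`): the
go process finishes at

$$\mu_{go} + \beta_{slow}\,(p(\mathrm{Stop})_k - 0.25) +
  \delta\,\frac{k}{100} + \varepsilon_k,$$

floored at 80 ms, with Gaussian noise $\varepsilon_k$ (SD 100 ms). The
anticipatory slowing term $\beta_{slow}$ produces the sequential effect;
the drift term $\delta$ a slow within-session RT increase. On stop trials
a response escapes iff the finishing time beats $SSD + SSRT$ (and falls
inside the window); the stop-signal delay follows the 1-up/1-down
staircase (start 200 ms, step 67 ms), which drives stop success toward
50%.

Design decisions where the task description is silent:

- **Finishing-time distribution**: Gaussian with an 80 ms floor. An
  ex-Gaussian would be more realistic in the RT tails but changes none of
  the estimator properties validated here; it is a documented extension
  point.
- **SSD bounds**: clamped to [0, 900] ms (the response window is 1 s).
- **Go errors**: pooled at `go_fail_prob`, split 50/50 between premature
  presses (flagged) and omissions; finishing times beyond the window are
  also omissions. Neither carries a scored RT.
- **Staircase continuity**: the tracker carries over from session to
  session rather than restarting at 200 ms, so only the first session
  shows the initial climb. Restarting per session would inject four
  transients, biasing the critical-SSD estimate downward; a continuously
  tracked delay matches how such experiments are typically run. The belief
  model and the drift term do restart per session (each scanner run begins
  with the generic prior).
- **Seeds**: every stochastic operation takes an explicit seed; cohort and
  session seeds derive deterministically from the master seed, making
  every bundle a pure function of `(config, seed)`.

## Behavioral estimators

The critical SSD — the delay at which stopping succeeds half the time — is
estimated as the mean SSD over stop trials after discarding the initial
staircase transient: all stop trials before the first reversal (change of
step direction), with at least 5 discarded. A reversal-based burn-in suits
the 1-up/1-down tracker, whose post-convergence path oscillates around the
50% point; alternatives (last-*N* mean, interpolated psychometric fit)
were rejected as either wasteful or over-parameterized for a tracked
delay. The estimator recovers median finishing time minus true SSRT within
25 ms at 100 stop trials in simulation, which is how it is validated —
the cited estimator of the original behavioral protocol is not restated
there, so simulation recovery stands in for code-level equivalence.

SSRT follows the race model: median go RT (successful go trials; even
counts take the mean of the central pair) minus critical SSD — the
identity `ssrt + critical_ssd = median GoRT` holds exactly by
construction. The sequential effect is the Pearson correlation between
$p(\mathrm{Stop})$ and RT over successful go trials only (errors carry no
usable RT), tested with the $t$ transform on $n-2$ degrees of freedom.

## First-level GLM

The design convolves unit impulses at every trial's fixation onset (the
trial beginning, duration 0) with the canonical double-gamma HRF — peak
delay 6 s, undershoot delay 16 s, unit dispersions, peak:undershoot ratio
6, sampled at TR/16 over 32 s — plus its finite-difference temporal
derivative. Five parametric modulators follow in a fixed order: p(Stop) on
go-success trials, SSD on successful stops, p(Stop) on successful stops,
SSD on failed stops, p(Stop) on failed stops. Modulators are mean-centered
per session and stratum before convolution; a stratum with fewer than
three trials or no variation is dropped with a warning (its centered
column would be identically zero, or collinear with its sibling when only
two trials remain). Sessions concatenate block-diagonally with per-session
constants.

Two deliberate choices:

- **No serial orthogonalization by default.** Legacy analysis packages
  orthogonalize each modulator against its predecessors in order, which
  makes estimates order-dependent. The default here keeps the columns as
  built (order-independent interpretation); `orthogonalize = TRUE`
  reproduces the legacy behavior for comparison.
- **The temporal derivative does not enter reported contrasts**; it only
  absorbs onset-timing misfit.

High-pass filtering uses the discrete-cosine basis with a 1/128 Hz cutoff.
The basis enters the regression as nuisance columns, which is numerically
identical to filtering data and regressors, and keeps the degrees of
freedom explicit. Serial autocorrelation is corrected with an AR(1) model
estimated per ROI time series: starting from the OLS residual lag-1
autocorrelation, the coefficient is refined (a short secant iteration) so
that the *whitened* residual autocorrelation matches its expected value
under white noise, $-\mathrm{tr}(LP)/(n-p)$, where $P$ is the projection
onto the whitened design space. The naive residual autocorrelation is
biased low by roughly $p/n$ — the high-pass basis absorbs precisely the
low-frequency power where an AR(1) process lives — and the corrected
two-pass recovers $\rho = 0.3$ within 0.05 at ~1000 volumes. Whitening
scales each session's first retained volume by $\sqrt{1-\rho^2}$ and
differences the rest; with $\rho = 0$ the fit is exactly OLS. Contrasts
(`roi_contrast`) average a named regressor across sessions; the +1 and −1
contrasts are exact negations.

## Group statistics

Gender enters the second-level regression as two indicator columns (male,
female) with no separate intercept; the indicators span the intercept, so
trait coefficients are identical to the single-indicator parameterization
while group means remain directly readable. Trait tests across regions can
be Bonferroni-guarded (`bonferroni_traits`), mirroring the $0.05/3$
convention for trait inter-correlations; no further family-wise machinery
is provided (whole-brain voxelwise inference is out of scope — the GLM
here operates on simulated ROI series, not images; spatial preprocessing
likewise does not apply). The gender comparison of regression slopes uses
the classical pooled-residual-variance two-slope $t$ test on
$n_1+n_2-4$ degrees of freedom, the standard textbook statistic for
comparing two independent simple regressions.

## The synthetic cohort: what it emulates, and what it does not

`cohort_config()` encodes the study conditions: 78 subjects (48 women),
4 × 100 trials at 25% stop. Trait scores are truncated, rounded normals —
NS 4.1 ± 2.5 on 0–13, HA with the gender difference (women 7.44 ± 4.40,
men 5.07 ± 4.12) on 0–22, RD 6.4 ± 2.4 on 0–9; truncation at zero
reproduces the right skew of NS qualitatively. Ages are 30.2 ± 10.2 years.
Behavioral parameters are population draws: subject mean go finishing time
620 ± 90 ms, true SSRT 204 ± 42 ms, anticipatory slowing 500 ± 150 ms per
unit p(Stop), within-subject RT noise 100 ms, go-error probability 0.022,
drift 6 ms per 100 trials.

**Calibration.** Two generator parameters are calibrated rather than
assumed, via `calibrate_cohort()`: the go-error probability maps directly
onto the 97.8% go response rate ($1 - 0.978 = 0.022$), and the mean
slowing coefficient was solved so the simulated cohort's mean sequential
effect is 0.33 (secant search over full-size cohorts averaged across
seeds, yielding ≈502, rounded to 500). The drift default stays at 6 ms/100
trials: the simulated stop-success rate sits near 51.6% — about 50% from
the staircase fixed point plus the initial 200 → ~420 ms climb — and the
1-up/1-down lag bias from drift is only
$\approx \delta \cdot \bar{g} / (2 \cdot 67)$ per stop trial ($\bar g$ the
mean trial gap between stop trials), so driving the rate to 52.4% by drift
alone would require an implausible ~80 ms/100 trials (over 300 ms of
slowing per session, contradicting the target median go RT). Whether the
empirically observed >50% stop-success rates reflect drift, tracking lag,
or both is left open; the generator exposes drift as the mechanism without
claiming it is the only one.

**ROI linkage.** Each of four ROIs (anterior pre-SMA, MFG/lOFC, IPL,
thalamus) receives BOLD built *from the design operator itself* — signal
equals design columns times generating amplitudes (event regressor
amplitude 1; p(Stop)-on-GS modulator amplitude
$a_0 + \text{slope} \cdot \text{trait} + \text{noise}$) plus AR(1) scanner
noise ($\rho = 0.3$). Model-consistent generation makes GLM recovery exact
in expectation, which is the point: recovery failures then indicate
estimator defects, not generator mismatch. Amplitude units are arbitrary
(contrast values are unitless); the slopes (−0.10 per NS point for the
three NS-linked regions, −0.06 per HA point for the thalamus) and noise
scales (amplitude noise 0.5, BOLD noise SD 0.5) were set so traits explain
roughly 6–12% of between-subject contrast variance and the second-level
regression recovers the negative signs in ≥95% of seeds at n = 78.

What the generator does *not* emulate — and hence what passing tests do
not show about real data: item-level questionnaire structure (traits are
marginal draws, uncorrelated by construction), ex-Gaussian RT tails,
trigger failures and attentional lapses on stop trials, HRF variability
across subjects and regions (a jittered-HRF variant can be built by
passing a non-default `hrf` to the analysis side), spatially correlated
noise, and head motion. The trait–ROI linkage is linear and additive by
design.

## Pipeline and reproducibility

`run_study()` chains the stages — generation, analysis-side p(Stop)
(recomputed per session with parameters that may deliberately differ from
the generating ones; both are recorded in provenance), behavioral
summaries, ROI GLMs with the positive p(Stop) contrast, second-level
trait regressions, Bonferroni summary, and gender slope comparisons — and
is a pure function of `(config, analysis, seed)`. A mismatch between
analysis-side and generating $\alpha$ degrades the measured sequential
effect smoothly, which the test suite asserts at $\alpha_{analysis} \in
\{0.8, 0.4, 0.05\}$ against a generating 0.8.

Problem sizes in the test suite are chosen to keep the default run brief
while retaining statistical power: full-size cohorts (n = 78) are used
where cohort-level statistics are asserted (behavioral acceptance run,
trait marginals, sign recovery across 10 seeds at one session per
subject), and reduced cohorts (8–30 subjects, 1–2 sessions, 120–160
trials) elsewhere. Null calibrations use 300–400 replicates, enough to
bound a 5% false-positive rate between 2% and 9%. The acceptance script
regenerates the full 78 × 400 study in a few seconds because the imaging
arm is skipped — none of the reported quantities need it.

## Known limitations

- The critical-SSD estimator assumes a converged staircase; with very few
  stop trials (< 20) it refuses to estimate rather than guess, and at
  short sessions the initial climb inflates the stop-success rate by a few
  percentage points (visible in the generator's own output).
- AR(1) is estimated globally per ROI series; no spatial pooling or
  higher-order noise models.
- `dbm_grid_fit()` selects parameters by behavioral correlation, which is
  a proxy, not likelihood-based inference over the belief model.
- The two-slope gender test assumes equal residual variance across groups.
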