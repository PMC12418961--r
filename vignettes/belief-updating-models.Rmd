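---
title: "Beta-count models of social belief updating: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Beta-count models of social belief updating: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(socbayes)
```

## The task and the quantity of interest

`socbayes` models a social estimation game. On each trial an agent samples
a noisy cue about the state of the world — here, the percentage of blue
mushrooms in a forest, observed through either 5 (uncertain condition) or
45 (certain condition) mushrooms in nearby fields — and reports a first
estimate $E_1$. They then see a peer's estimate $P$ together with the
peer's reported confidence (low / medium / high) and may revise their
answer to a second estimate $E_2$. The model-free outcome is the weight
placed on the peer,

$$s = \frac{E_2 - E_1}{P - E_1},$$

which is 0 when the peer is ignored and 1 when the peer is copied. $s$ is
undefined when $P = E_1$; such trials are excluded (`no_peer`).

## The observer-model family

Beliefs are beta distributions over the blue proportion, encoded as
pseudo-counts with a unit prior (one blue, one red). The first-estimate
belief adds the reported proportion scaled by a *perceived* observation
count:

$$E1_{blue} = 1 + \tfrac{E_1}{100} N_{perceived}, \qquad
  E1_{red} = 1 + \bigl(1 - \tfrac{E_1}{100}\bigr) N_{perceived}.$$

The peer contributes $N_{peer}$ further pseudo-observations split by $P$,
added to the counts; the posterior beta density is evaluated at the 101
response options $0, 0.01, \dots, 1$ and renormalised to a discrete pmf.
The posterior-mean weight on the peer is then
$N_{peer} / (N_{peer} + N_{perceived} + 2)$ — precision weighting falls
out of counting.

The family's structural switches, with box bounds used in fitting:

| model | $N_{perceived}$ | $N_{peer}$ | stay bias | free parameters |
|---|---|---|---|---|
| M0 | $N$ | 25 | — | 0 |
| M1a | $N\alpha$ | 25 | — | 1 |
| M1b | $N\alpha_{cond}$ | 25 | — | 2 |
| M2a | $N\alpha_{cond}$ | $\theta$ | — | 3 |
| M2b | $N\alpha_{cond}$ | $\theta_{IC}+\theta_{slope}(c-1)$ | — | 4 |
| M2c | $N\alpha_{cond}$ | $\theta_c$ per level | — | 5 |
| M3a | as M2b | as M2b | $\beta$ | 5 |
| M3b | as M2b | as M2b | $\beta_{cond}$ | 6 |
| M3c | as M2b | as M2b | $\beta/c$ | 5 |
| M3d | as M2b | as M2b | $\beta^{c}$ | 5 |

with $c \in \{1,2,3\}$ the peer's confidence level, $\alpha \in [0.1,
100]$, $\theta \in [0.1, 1000]$, $\theta_{IC}, \theta_{slope} \in [0.1,
500]$ and $\beta \in [0.01, 0.99]$.

The stay bias is a non-Bayesian mixture component: with weight $w$ the
agent repeats $E_1$ outright, with weight $1-w$ they respond from the
posterior pmf. A stay response therefore has probability
$w + (1-w)\,q[E_1]$ and any other response $(1-w)\,q[E_2]$. Normalising
the density on the response grid is what makes this mixture a proper
distribution — each trial's 101 response probabilities sum to one, which
the test suite checks by enumeration.

## Numerical choices

* **Response grid.** Estimates are integers 0–100 (slider resolution).
  Real-data ingestion rounds non-integer estimates onto the grid and
  reports how many were affected.
* **Likelihood floor.** Trial likelihoods are floored at $10^{-12}$
  before taking logs, so an outlying response cannot produce an infinite
  objective; the number of floored trials is attached to the result.
* **Fitting.** Per participant, a log-spaced lattice (default 5 points
  per parameter, capped at 10 000 evaluations by coarsening) seeds
  bounded L-BFGS-B refinement from the best 3 points. Optimisation runs
  on the log-parameter scale: all bounds are positive and the likelihood
  is far better conditioned in $\log\alpha$, $\log\theta$ than on the raw
  count scale. If refinement ever ends above its grid start, the start is
  returned instead, so the reported optimum is never worse than the grid.
* **Model comparison.** $BIC = k\ln n + 2\,\mathrm{NLL}$ per participant
  ($n$ = that participant's included non-filler trials), summed over the
  cohort. Summing per-participant BICs keeps the comparison invariant to
  cohort imbalance and matches per-participant fitting. The conditional
  model-building path (`model_building_path`) accepts a model only if it
  lowers the running-best total BIC.
* **Near-nesting.** Because $\beta$ is bounded below at 0.01, the stay
  models cannot exactly reproduce their stay-free parents; on stay-free
  data the gap is at most $-n\log(1-0.01) \approx 0.01\,n$ nats, which is
  the tolerance the nesting tests use.

## The synthetic-data generator

Every analysis stage is testable without real data because the generator
emulates the task end to end:

* **Designs.** Experiment 1: 42 main trials (2 conditions × 3 confidence
  levels × 7 true percentages) plus 12 fillers over 3 rounds. Experiment
  2: 60 main trials (5 percentages, each cell twice) plus 15 fillers over
  3 runs. Runs are balanced on condition; order is seeded.
* **Fields.** The blue count is one binomial draw with $N$ trials and
  success probability `true_pct`/100. (The task screen shows five small
  fields, but five sub-binomials summing to $N$ are statistically
  identical to one draw — only the total enters the model.) $E_1$
  faithfully reports the seen proportion, rounded to the grid.
* **Peers.** Main trials: $|P - E_1| \in [15, 18]$, toward the true
  percentage whenever a value in 0–100 exists in that direction,
  otherwise away from it. Fillers: distance $\in \{1, 2\}$ or $> 40$
  (distance 0 is skipped so $P \ne E_1$ even on fillers, which are
  excluded from analysis regardless). Peer confidence is assigned by the
  design, independent of $P$ — the original peers came from a database of
  earlier players whose confidence–accuracy coupling is unknowable here;
  this is the main feature of real data the generator does not emulate.
* **Responses.** $E_2$ is drawn from the full mixture distribution of the
  generating model, so simulated data exhibit exactly the stay-bias and
  precision-weighting structure the fitted models assume.
* **Timing.** Simulated cohorts have no measured event onsets, so the
  regressor builder lays trials out deterministically (24 s spacing, the
  first-estimate prompt at +8 s, social information at +14 s). Real data
  with onset columns pass straight through.

Passing tests on these cohorts show that the estimation machinery is
correct and self-consistent; they do not show that real participants obey
the model — misspecification, response noise unrelated to the beta
posterior, and peer-confidence couplings are absent by construction.

## Recovery studies

Observed parameter ranges from the original cohorts are not published, so
recovery simulations draw uniformly from ranges chosen to bracket the
reported median estimates (distortion medians 4–29, implied peer counts
55–241) while staying inside the fitting bounds: $\alpha \in [1, 50]$,
$\theta_{IC}, \theta_{slope} \in [1, 150]$, other $\theta$s $\in [1,
300]$, $\beta \in [0.05, 0.9]$. Model recovery simulates a cohort per
generator model, fits all nine parameterised models to each cohort, and
assigns the winner by total BIC — 81 fitting procedures at the default
nine-model setting. The winner is assigned at cohort level (matching how
the comparison is used), so confusion rows are one-hot; the full
total-BIC matrix is returned alongside for graded inspection. The linear
(`M3c`) and exponential (`M3d`) confidence-dependent stay biases are
structurally close and are the documented overlap case.

Parameter recovery refits the generating model to each simulated
participant on the experiment-2 design (60 non-filler trials) and
reports per-parameter Pearson correlations between generating and
recovered values. At the package defaults (50 participants, full fit
settings) every M3d parameter recovers with $r \ge 0.62$; the acceptance
script recomputes this from scratch. Problem sizes used by the checked
examples — 10 participants per generator cohort with a 3-point grid for
the confusion matrix, 50 participants with the 5-point grid for parameter
recovery — are the package's default reduced-scale settings for routine
quality control.

## Exclusion rules

Trial level, with fixed precedence (filler > missed > no_peer >
outlier_3sd > s_out_of_range): fillers; missed responses; $P = E_1$;
first or second estimates more than 3 SD from the cohort mean of their
(condition × true percentage) cell, computed over non-filler non-missed
trials; and $s \notin [0, 1]$. "Ratio" in the original 3-SD rule is read
as the true-percentage cell — the only trial-level ratio variable.
Participant level: anyone with $s = 0$ on more than 70% of evaluable
non-filler trials (strict inequality; a participant at exactly 70% is
retained), plus manual flags for participants who misunderstood the task
— a qualitative screen that is an input, not an algorithm. Filters are
idempotent and conserve counts (included + excluded-by-reason = total).

## The condition-effects regression

`fit_condition_regression` fits `s ~ certainty * confidence` with
by-participant random intercepts and slopes, on included trials.
Confidence is coded −1/0/+1; certainty −0.5/+0.5 (uncertain/certain) —
the original analysis states only the confidence coding, and the centred
unit contrast makes the certainty coefficient directly interpretable as
the condition difference; pass `certainty_coding = c(-1, 1)` to switch.
Singular or non-convergent maximal fits fall back to uncorrelated
slopes, then to a random intercept, logging each step rather than
failing silently.

## Model-based regressors

For event-related fMRI designs the package constructs, per trial:
own certainty $N \times \alpha_{cond}$ (at the first-estimate prompt,
0.5 s); peer confidence $\theta_{IC} + \theta_{slope}(c-1)$ and the
Kullback–Leibler belief update (at social-information onset, 4 s,
non-filler trials only); and the $\beta^c$ stay-bias modulator. Values
are mean-centred within run over the trials entering each regressor and
exported as 3-column (onset, duration, amplitude) files, one per run per
regressor.

The KL update measures how much the belief changed, capturing both the
shift of the point estimate and the narrowing of the distribution. Two
design choices were genuinely open and are fixed as follows:

* **Direction.** $KL(\text{posterior} \,\|\, \text{prior})$ — the
  Bayesian-surprise convention.
* **Posterior-belief construction.** The updated belief takes its point
  estimate from the *observed* $E_2$ and its precision from the
  model-based total count $N_{perceived} + N_{peer}$ (plus the unit
  prior), so the regressor reflects the participant's actual revision at
  the model-implied precision.

Both distributions are discretised on the response grid, clipped at
$10^{-10}$ and renormalised, guaranteeing finite KL at the grid
endpoints. Consequences worth knowing: KL is strictly positive even for
stay responses (the posterior is narrower whenever $N_{peer} > 0$), and
the discrete KL agrees with the continuous beta–beta closed form to
within 2% for moderate pseudo-counts, which the tests verify against the
digamma expression.

## Known limitations

* The generator's peers have confidence assigned by design, uncorrelated
  with their accuracy — real advice quality covaries with confidence.
* Missed trials and response timeouts are not simulated; the `missed`
  flag exists for real-data ingestion.
* The mixed regression of a heavily stay-biased cohort routinely needs
  the random-effects fallbacks; this is logged, not hidden.
* Reported headline statistics of the original cohorts (mean $s$,
  regression coefficients, total-BIC differences) depend on the
  unpackaged real data and are out of scope; the package reproduces the
  arithmetic anchors and the recovery properties instead.
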