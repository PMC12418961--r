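# socbayes

Bayesian models of social information use under uncertainty.

`socbayes` is an analysis package for a social estimation task in which a
person first estimates a quantity from noisy evidence (the percentage of
blue mushrooms in a forest, sampled through either 5 or 45 mushrooms),
then sees a peer's estimate together with the peer's confidence rating
(low / medium / high), and may revise their answer. It is written for
computational cognitive scientists who want to simulate this task, fit
observer models to it, and derive trial-level regressors for neuroimaging
analyses.

The model-free outcome is the weight placed on the peer,

```
s = (E2 - E1) / (P - E1)
```

(0 = peer ignored, 1 = peer copied). The model-based core is a family of
ten beta-count Bayesian observers: beliefs are beta distributions encoded
as pseudo-counts with a unit prior,

```
E1_blue = 1 + (E1/100) * N_perceived
E1_red  = 1 + (1 - E1/100) * N_perceived
```

to which the peer adds `N_peer` pseudo-observations split by `P`. The
family varies (i) how the objective count maps onto `N_perceived`
(identity, one distortion `alpha`, or condition-specific
`alpha_uncertain` / `alpha_certain`), (ii) how confidence sets `N_peer`
(fixed at 25, free `theta`, linear `theta_ic + theta_slope * (conf - 1)`,
or one `theta` per level), and (iii) a non-Bayesian stay bias — mixture
mass on repeating `E1` — that is constant, condition-specific, or decays
linearly (`beta/conf`) or exponentially (`beta^conf`) with peer
confidence. Responses are scored on the 101-point percentage grid, so
each trial's likelihood is a proper discrete mixture distribution.

On top of the model family the package provides per-participant maximum
likelihood fitting (log-spaced grid search + bounded L-BFGS-B), BIC model
comparison, model- and parameter-recovery diagnostics, the trial- and
participant-level exclusion rules, a mixed-effects regression of `s` on
the two task factors, and model-based fMRI regressors (perceived
certainty, peer weight, Kullback–Leibler belief update) exported as
3-column event files. A seeded synthetic-data generator emulates the full
task, so everything is testable without real data.

## Worked example

```r
library(socbayes)

# simulate a scanner-design cohort of exponential-stay Bayesian agents
pars <- sample_parameters("M3d", 12, seed = 31)
cohort <- simulate_cohort(12, "M3d", pars, experiment = 2, seed = 32)

# exclusion rules, then the condition-effects regression
cohort <- apply_trial_filters(cohort)
cohort <- apply_participant_filters(cohort)$records
fit_condition_regression(cohort)
#> Mixed regression of social information use (11 participants, 614 trials)
#> Random-effects structure: uncorrelated
#> Fallbacks: maximal: singular fit
#>                       term estimate     se    df     t        p
#> 1              (Intercept)    0.268 0.0398  9.98  6.74 5.18e-05
#> 2              certainty_c   -0.310 0.0310  9.79 -9.99 1.89e-06
#> 3             confidence_c    0.101 0.0163 10.15  6.21 9.36e-05
#> 4 certainty_c:confidence_c   -0.102 0.0240  9.97 -4.25 1.71e-03
```

The signs are the task's signature: people lean on the peer more when
their own evidence is thin (negative certainty coefficient, coded
uncertain = −0.5, certain = +0.5) and when the peer claims confidence
(positive confidence coefficient, coded −1/0/+1), with the confidence
effect strongest under uncertainty (negative interaction). One simulated
participant was dropped by the "stayed on more than 70% of trials" rule.

Fitting and comparing models on the same cohort:

```r
fits <- fit_cohort(cohort, models = c("M1b", "M2b", "M3d"))
compare_models(fits)
#>   model k total_bic delta_bic winner
#> 1   M1b 2  4185.808  1916.544  FALSE
#> 2   M2b 4  3976.275  1707.010  FALSE
#> 3   M3d 5  2269.265     0.000   TRUE
```

Lower BIC is better; the generating model wins. `build_regressors()` and
`export_events()` then turn any participant's fitted parameters into
mean-centred parametric regressors.

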