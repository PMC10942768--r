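---
title: "Modelling effortful prosocial choice: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling effortful prosocial choice: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(effortdisc)
```

## The task and the choice model

`effortdisc` models a binary *work vs. rest* effort task with two reward
recipients. On every trial a participant chooses between a fixed rest
option (1 credit for no effort) and a work offer of R ∈ {2, 4, 6, 8, 10}
credits at effort level E ∈ {1, …, 5} (30–70% of the participant's maximum
voluntary contraction, MVC). Half the trials benefit the participant
(*self*), half another person (*other*). The full factorial — 5 rewards ×
5 efforts × 3 repetitions × 2 recipients — gives 150 trials in 6 runs of
25.

Effort devalues reward. We consider three discount forms,

* linear: SV = R − K·E
* hyperbolic: SV = R / (1 + K·E)
* parabolic: SV = R − K·E²,

each crossed with a shared vs. recipient-specific discount rate K and a
shared vs. recipient-specific softmax temperature β, yielding the
twelve-model family of `enumerate_models()`. Choice follows the binary
softmax rule P(work) = 1 / (1 + exp(−β·(SV_work − 1))). The temperature's
functional form is the standard logistic-in-β·ΔSV rule of this task
lineage; models in the family differ only in discounting and parameter
sharing.

### Effort coding

Effort enters the discount equations as the integer level 1–5 (rest = 0),
not as the fraction of MVC. With the conventional K bound of [0, 1.5],
level coding is the only scaling under which the bound brackets
behaviourally meaningful indifference points: under fraction-of-MVC coding
(E ≤ 0.7) even K = 1.5 could never make rest preferable to the smallest
work offer under parabolic discounting. The scaling is nevertheless a
property of the data columns, not of the fitter, so results can be
re-expressed by transforming `effort_level` before fitting.

## Fitting, bounds and model comparison

`fit_effort_model()` minimises the negative log-likelihood over a bounded
box — K ∈ [0, 1.5], β ∈ [0, 30] — with L-BFGS-B and an analytic gradient,
restarted from seeded uniform initialisations (default 20; the studies in
this package use 3–8 where thousands of fits are needed, which we found
ample for these 2–4 parameter likelihoods). The β upper bound of 30
covers effectively deterministic choice at the task's SV scale (at ΔSV =
1 credit, β = 30 gives P(work) > 0.9999) while keeping the optimisation
well-conditioned; it is configurable. Probabilities are floored at 1e−12
before logs so the objective stays finite at extreme temperatures.

Missed trials (no response) are excluded from the likelihood *and* from
the n used in the BIC, k·ln(n) − 2·logL, mirroring their treatment as a
separate nuisance regressor downstream. Models are compared by BIC summed
over participants (rank-equivalent to the mean at equal n); ties break
toward fewer parameters. `sv_regressor()` emits the per-trial signed SV
difference (chosen − unchosen) under the winning model, the quantity used
as a trial-level parametric modulator in neuroimaging analyses.

## The synthetic cohort

`simulate_population()` generates the structure the downstream analyses
assume: two groups (stress induction vs. control; default 45 + 46
participants, the analysed-sample sizes of the study design this package
emulates), each agent with ground-truth parameters recorded losslessly.
The published work reports no generative magnitudes, so all synthetic
effect sizes are this package's own choices and must never be read as
estimates of any study's effects:

* K_self ~ N(0.30, 0.15²) and K_other ~ N(0.35, 0.15²), truncated to
  [0, 1.5] — mid-range discounting with realistic heterogeneity.
* β ~ N(5, 2²), truncated to [0.2, 30]: choices informative but noisy.
* Stress effect: +0.15 on K_other in the stress group, none on K_self,
  chosen to produce the qualitative low-effort self/other asymmetry such
  studies report. Setting it to 0 yields a null population.
* SVO angle ~ N(19.3°, 8.4²) (matching the published sample means/SDs),
  coupled to behaviour by K_other decreasing 0.08 per SD of SVO, which
  reproduces a positive SVO–prosociality correlation of roughly the
  reported size (r ≈ 0.2).
* 1% of trials are missed; work attempts succeed with probability 0.98
  (the reported success-rate range), judged from a simulated 3-s force
  trace that must stay above the required level for one contiguous
  second.

Perceived-stress ratings are generated at 8 timepoints (minutes −42, 0,
11, 38, 51, 64, 94, 119 relative to induction onset) and cortisol at the
6 saliva-sample timepoints (−42, 0, 38, 64, 94, 119). Trajectories are
piecewise linear — flat baseline, rise to a peak at minute 51, linear
decay — because the emulated design specifies timepoints and group
differences but no functional form; the control group receives 15% of the
stress group's peak amplitude (scanning itself is mildly stressful).
Ratings are clipped to [1, 7] and cortisol to ≥ 0.

What the generator does *not* emulate: cortisol pharmacokinetics,
diurnal drift, rating anchoring effects, fatigue across runs, and any
dependence of choice noise on stress. Tests passing on this cohort
therefore validate the pipeline's correctness and calibration, not any
empirical claim about real stressed humans.

## Stress summaries

`auc_ground()` computes the trapezoidal area between the series and zero
over the observed span — for the default schedules, 161 minutes from
first to last sample; we integrate over actual clock minutes rather than
re-origining at the arrival sample, which only shifts all participants'
AUCs by a common factor of the baseline. A single interior missing sample
is linearly interpolated in clock time between its flanking samples
(`interpolate_missing()`); an index-midpoint variant is available as a
sensitivity check, and missing edge samples are an error rather than an
extrapolation. Z-scoring across participants uses the sample (n − 1) SD.

## Behavioural statistics

`proportion_prosocial()` is other-benefitting work choices over all work
choices, across all reward and effort levels; participants with no work
choices are flagged undefined rather than dropped silently.
`choice_regression()` delegates the mixed-effects logistic numerics to
`lme4::glmer` (work ~ Group × Recipient × Effort × Reward up to
three-way interactions, random intercept plus Recipient slope per
participant) with sum-to-zero contrasts so the type-III Wald chi-square
tests from `car::Anova` are interpretable. Effort and Reward enter as
five-level factors, which is what per-level follow-up contrasts require;
`group_recipient_by_effort()` tests the Group × Recipient interaction
within each effort level at the factor-average of Reward, Bonferroni-
corrected over the five levels. These follow-up contrasts are computed on
the fixed-effect (logit) scale from the coefficient covariance; their SE
convention may differ slightly from reference-grid marginal-means
implementations, which we deliberately do not reimplement.

`moderation_simple_slopes()` is OLS with an interaction; the simple slope
at moderator value m₀ is b_x + b_xm·m₀ with SE from the linear-combination
quadratic form, probed by default at the moderator's sample mean ± 1
sample SD.

## Numerical and design choices

* Pseudorandomisation: the published task description says only
  "pseudorandomised order", so the constraint is ours: no more than 4
  consecutive trials (configurable) may share a recipient. The sequence
  is drawn by sequential urn sampling with retry on dead-ends, which
  guarantees exact cell balance and the streak bound.
* Determinism: every stochastic function takes a seed and restores the
  caller's RNG state; identical (config, seed) gives byte-identical
  output.
* Degenerate inputs fail loudly: all-missed choice tables, zero-variance
  z-scores, single-participant mixed models, collinear moderators and
  edge-missing series are errors, not silent NAs.

## Problem sizes of the validation studies

The package's own validation studies (run by the test suite and the
acceptance script) use: 60 agents for parameter recovery at β = 5
(Pearson r(true, recovered) ≈ 0.99 for both K parameters); 40 agents for
the deterministic-choice limit; 20 replicate populations of 40 agents for
model identification; 84 agents × 12 models (1008 fits) for bound
compliance; and 200 replicate null populations for type-I-error
calibration. The calibration study runs on a reduced factorial (3 reward
× 3 effort levels, 2 repetitions, 2 runs of 18 trials, 20 participants
per group) and fits the logistic models with `nAGQ = 0`; at these sizes
the Wald test's null rejection rate is indistinguishable from the nominal
5% while hundreds of mixed-model fits remain cheap. Elsewhere the
package defaults to the Laplace approximation (`nAGQ = 1`).

## Known limitations

* **Set-identification at extreme temperatures.** With effectively
  deterministic choices, the data only constrain K to the interval
  between adjacent indifference thresholds (R − 1)/E² of the design grid;
  within such an interval the likelihood is flat and the returned
  estimate is an arbitrary interior point. Threshold gaps in [0, 1]
  reach ≈ 0.19, so point-estimate errors up to ≈ 0.1 in the β → ∞ limit
  are a property of the 5 × 5 design, not of the optimiser. At realistic
  temperatures (β ≈ 5) choice stochasticity smooths the likelihood and
  recovery is excellent.
* β recovers poorly compared to K when true β is large (the likelihood
  flattens in β once choices are near-deterministic); recovery reports
  therefore focus on K.
* The regression machinery covers the contrasts implemented here, not a
  general marginal-means framework.
* Hierarchical (partial-pooling) estimation is out of scope; fits are
  per participant.
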