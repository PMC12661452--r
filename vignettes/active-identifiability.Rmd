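---
title: "Active selection of measurement times for practical identifiability"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Active selection of measurement times for practical identifiability}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(alpipe)
```

## The problem

A mechanistic ODE model is *practically identifiable* from a dataset when
every parameter can be given finite confidence bounds — not merely a point
estimate. In bioengineering practice each measurement costs time and
resources, so the question this package addresses is: **given the model, a
noise model and the data so far, at which time should the next measurement
be taken so that practical identifiability is reached with as few
observations as possible?**

Identifiability is judged by profile likelihood. For a parameter
$\theta_i$, the profile is the negative log-likelihood re-optimised over
all other parameters while $\theta_i$ is held fixed. With
$\mathrm{nLL}(\hat\theta)$ the negative log-likelihood at the maximum
likelihood estimate (MLE), the pointwise 95% threshold is

$$\mathrm{threshold} = \mathrm{nLL}(\hat\theta) + \tfrac12\,\chi^2_{0.95,1}
 = \mathrm{nLL}(\hat\theta) + 1.9207 .$$

A parameter is practically identifiable when its profile exceeds the
threshold on *both* sides of the MLE; the two crossings bound the 95%
confidence interval (CI). `likelihood_threshold()`, `check_identifiability()`
and `bisection_ci()` implement this machinery.

## The acquisition criterion

Instead of scanning full profiles, the sequential design works with a
*candidate set* of $m = 2N + 1$ models for $N$ free parameters: the MLE
model plus, per parameter, the two *boundary models* obtained by pinning
the parameter at its lower / upper search bound and re-fitting the rest
(`build_candidate_set()`). Candidates are weighted by normalised
likelihood, $w_i \propto e^{-\mathrm{nLL}_i}$ (computed in the log domain;
`candidate_weights()`).

The next measurement time maximises the noise-scaled, likelihood-weighted
disagreement between the candidates and the MLE model
(`ealpipe_scores()`), summed over the $M$ observed outputs:

$$S(x) \;=\; \sum_{j=1}^{M} \frac{1}{\hat\sigma_j^2(x)}
  \sum_{i=1}^{m} w_i \bigl(f_j(x \mid \theta_i) - f_j(x \mid
  \hat\theta)\bigr)^2 ,$$

where $\hat\sigma_j^2(x)$ is the observation-noise variance predicted at
the MLE trajectory under the truncated-normal noise model. Intuitively, a
time point is informative exactly when models that are still plausible
under the data disagree there by more than measurement noise can explain.

Two ensemble *benchmark* criteria are included for comparison
(`benchmark_ensemble()`, `benchmark_scores()`): 10 evenly spaced pin
values per parameter (restricted to the current CI once a parameter is
identifiable, falling back to the CI midpoint) yield up to $10N$ profile
models; the score is the across-ensemble variance of the predictions
(single output) or the determinant of their covariance (generalised
variance, multiple outputs), optionally divided by the predicted noise
variance(s) — the *relative variance*. Random sampling completes the set
of strategies.

## Noise model

Observations are non-negative concentrations, so additive Gaussian errors
are truncated below: $y = f + e$ with $e \sim N(0, \sigma^2)$ conditioned
on $e \ge -f$. The log-density subtracts $\log \Phi(f/\sigma)$, evaluated
with `pnorm(log.p = TRUE)` so signal-to-noise ratios in the hundreds stay
accurate, and its predicted variance
$\sigma^2(1 + \alpha\lambda(\alpha) - \lambda(\alpha)^2)$,
$\alpha = -f/\sigma$, is the $\hat\sigma_j^2$ used in the scores. Two
consequences worth knowing:

* the likelihood is a proper density on $y \ge 0$ for *every* candidate
  parameter vector (the truncation point moves with the candidate's own
  trajectory — the simulator, by contrast, truncates at the true
  trajectory, which is what a real instrument would do);
* when a trajectory spends time near zero relative to $\sigma$, the
  normalising term rewards parameters that lift it above the noise floor,
  so the MLE on such data is *not* the zero-residual point. This is
  visible in the first case study, where most of the candidate grid has
  $f \ll \sigma$.

Sampling uses the inverse-CDF construction — exactly one uniform variate
per observation — so the noise streams of two strategies remain aligned
wherever their designs coincide, which is what makes paired signed-rank
comparisons meaningful.

## The loop

`run_replication()` starts from one user-chosen observation, then
alternates estimation (candidate set) and exploration (score + argmax;
ties break to the earliest time; previously sampled times remain
selectable — replicates are informative under noise). Identifiability is
assessed from the second observation onwards, and a run counts as
*reliably identifiable* at the second of two consecutive assessments with
every parameter identifiable; stop-on-identifiability mode then computes
bisection CIs and stops, otherwise the run caps at `max_points` (default
50). The separate fixed-budget mode never stops early, always collects
exactly `budget` (default 20) observations, and ends with a fresh
multi-start MLE plus CIs for whatever is identifiable at the budget —
the basis of the CI-width and trajectory-error comparisons, which would
otherwise be confounded by different dataset sizes across strategies.

## Case studies and the synthetic generator

Three built-in configurations (`experiment_preset()`):

1. **Sum of two exponential decays**, $y(t) = e^{-\beta_1 t} + e^{-\beta_2
   t}$, bounds $\beta_1 \in [0,3]$, $\beta_2 \in [3,6]$ 1/h
   (non-overlapping, because the output is symmetric under swapping the
   rates), truth $(2, 4)$, $\sigma = 0.005$, grid $1\!-\!10$ h step 0.1,
   first observation at $t = 3$ h.
2. **Monod bioreactor, biomass observed** ($\mathrm{BG}$ only):
   $\mu_{\max} \in [0.1, 50]$ 1/h, $K_D \in [10^{-4}, 1]$ 1/h,
   $Y \in [0.01, 10]$, $K_S$ fixed at 30 g/L, truth $(1, 0.1, 0.5)$,
   $\sigma_{BG} = 2$ g/L (deliberately harsh), grid $1\!-\!60$ h step
   0.5, first observation at $t = 10$ h.
3. **Monod bioreactor, biomass and substrate observed**, all four
   parameters free ($K_S \in [0.1, 50]$ g/L), truth
   $(0.5, 30, 0.05, 0.6)$, $\sigma_{BG} = 0.5$, $\sigma_{SC} = 1.6$ g/L.

The generator draws truncated-normal observations from the true
trajectory at the chosen times; replication $r$ of every strategy derives
its noise / optimiser / random-selection streams from `child_seed(seed,
r, ...)`. What the generator does *not* emulate: instrument drift, batch
effects, missing measurements, or correlated errors across times and
outputs — passing tests therefore demonstrate correctness of the method
under its stated noise assumptions, not robustness to real-laboratory
artefacts.

## Numerical choices

* **Integration.** The bioreactor trajectories are integrated with an
  adaptive embedded Dormand–Prince 5(4) pair compiled in `src/`, relative
  tolerance $10^{-8}$, absolute $10^{-10}$: the bounds admit growth rates
  up to 50/h, and the design loop needs on the order of $10^6$ forward
  solves per experiment, which rules out interpreted right-hand sides.
  Tiny negative substrate excursions from solver overshoot are clipped to
  zero inside the Monod term only; step-size collapse is reported as an
  all-`NA` trajectory that the likelihood maps to $+\infty$ (an
  infinitely bad fit). Tests verify agreement with an independent
  `lsoda` integration at $10^{-12}$ tolerances.
* **Optimisation.** Box-constrained L-BFGS-B with finite-difference
  gradients (the objective involves ODE solves; analytic sensitivities
  are out of scope), objective scaled by the box widths, multi-start with
  Latin-hypercube draws: 10 starts for a cold fit, and warm starts from
  the previous iteration's optimum (plus LHS top-ups) for sequential
  re-fits, since the dataset changes by one observation per iteration.
  Non-finite objective values are replaced by a large finite penalty so
  the optimiser can leave infeasible regions.
* **Profile-fit depth — a genuine sensitivity.** Boundary (profile) fits
  start from the MLE projected into the constrained space plus
  Latin-hypercube top-ups. We deliberately do *not* chain them across
  iterations: chained warm starts converge the profiles substantially
  deeper along the curved $\mu_{\max}$–$K_S$ ridge, and since the verdict
  compares $\mathrm{pl} - \mathrm{nLL}(\hat\theta)$ against 1.92 nats,
  deeper profile convergence systematically *delays* certification. The
  two-output bioreactor makes the stakes concrete: against the entire
  noise-free candidate grid, the best attainable evidence against
  $K_S = 50$ is only ≈ 3.6 nats (≈ 1.4 nats from the 10 best single
  points), so certification of $K_S$ at realistic sample sizes rides on
  the interplay of noise excursions and ordinary multi-start profile
  depth. Users comparing absolute certification speeds across
  implementations should fix this setting first
  (`n_starts_profile`).
* **Bisection.** CI crossings are bracketed between the box bound
  (profile above threshold — the parameter was already certified) and the
  MLE, to a tolerance of $10^{-3}$ of the box width per parameter
  (`epsilon_frac`); a relative tolerance keeps the 49.9-wide and 3-wide
  boxes comparable. Probes warm-start from the nearest accepted profile
  point; a failed probe counts as above-threshold, widening the interval
  conservatively. Profiles are assumed unimodal — multimodal profiles
  would need a grid/multi-interval scan and are out of scope.
* **Weights.** Likelihood weights are normalised after subtracting the
  minimum negative log-likelihood; raw likelihoods underflow beyond a few
  dozen observations. Ensemble variance uses the population convention
  (denominator $m$): the ensemble is an exhaustive model set, not a
  sample. Near-singular ensemble covariances get a $10^{-12} \times
  \mathrm{trace}$ diagonal ridge before the determinant.

## Evaluation protocol

Three metrics over replications (`summarise_method()`, `write_report()`):

1. **Speed**: the observation count at reliable identifiability,
   averaged with failures scored at the 50-point cap
   (`mean_iterations_to_identifiability()`), and the cumulative
   probability curve (`identifiability_probability()`).
2. **Precision**: per-parameter CI width after exactly 20 observations,
   with the full box width assigned to parameters not identifiable at the
   budget (`ci_width_at_budget()`; widths are capped at the box width).
3. **Accuracy**: mean absolute deviation between the budget-time MLE
   trajectory and the truth over the candidate grid (`diff_metric()`).

Methods are compared pairwise with the Wilcoxon signed-rank test
(`paired_rank_test()`), paired by replication through the shared noise
streams; no multiplicity correction is applied across the pairwise
comparisons.

Problem sizes used by the bundled acceptance script: 100 sequential and
50 fixed-budget replications for the analytic first case study, 24 of
each for the single-output bioreactor, and 14 sequential replications
for the two-output bioreactor — sizes at which the Monte-Carlo standard
errors of the reported means are small relative to the between-method
differences of interest.

## Known limitations

* The *scaled* benchmark has a degenerate attractor on models whose
  output decays into the noise floor: across the first case study's grid
  the ensemble's generalized variance is nearly flat (the $\beta_1 = 0$
  pin model dominates it everywhere), so dividing by the predicted noise
  variance — smallest where the trajectory is near zero — steers every
  selection into the uninformative tail, and the strategy stalls at the
  observation cap. The weighted-disagreement criterion does not share
  the attractor because implausible pin models carry (essentially) zero
  likelihood weight there.
* Verdicts inherit the profile-likelihood machinery's assumptions:
  unimodal profiles, pointwise (df = 1) intervals, a pre-verified
  structurally identifiable model.
* Certification speed depends on profile-fit convergence depth (above);
  absolute speeds are comparable only at matched optimiser settings.
* Single-point (greedy) acquisition only; no batch designs, no
  continuous-time protocols, no selection of *new observables*.
* Homoscedastic, independent truncated-normal errors; no correlated or
  heteroscedastic noise models.

## A worked five-minute example

```{r example, eval = FALSE}
cfg <- experiment_preset(1, seed = 1)
tr <- run_replication(cfg, replication = 1)
tr
tr$reliable_iteration          # observations needed
sapply(tr$final$cis, `[[`, "width")
```

See the README for the output this prints and for how to reproduce the
full comparison tables with `scripts/acceptance.R`.
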