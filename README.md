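# alpipe

Sequential choice of measurement time points that establishes **practical
identifiability** of ODE model parameters with as few experiments as
possible.

## The problem

Fitting a mechanistic model to data is only half the job: a parameter
estimate is trustworthy when the data give it *finite* confidence bounds.
Practical identifiability analysis judges this through the profile
likelihood — for each parameter, the negative log-likelihood re-optimised
over all other parameters while the parameter of interest is held fixed.
With `nLL(θ̂)` the value at the maximum-likelihood estimate, the pointwise
95 % threshold is

    threshold = nLL(θ̂) + χ²(0.95, 1) / 2 = nLL(θ̂) + 1.9207

and a parameter is practically identifiable when its profile exceeds the
threshold on both sides of the MLE; the crossings bound its 95 %
confidence interval. In the laboratory every additional measurement costs
time and material, so the practical question is *where to measure next*
so that this certification arrives earliest.

## The algorithm

`alpipe` implements the E-ALPIPE acquisition rule. At each iteration it
builds a candidate set of `m = 2N + 1` models — the MLE plus, for each of
the `N` free parameters, the two *boundary models* obtained by pinning
the parameter at its lower/upper search bound and re-fitting the rest —
weighted by normalised likelihood `w_i ∝ exp(−nLL_i)`. The next
measurement time `x` maximises the noise-scaled weighted disagreement

    S(x) = Σ_j (1/σ̂_j²(x)) Σ_i w_i (f_j(x|θ_i) − f_j(x|θ̂))²

summed over the observed outputs `j`, where `σ̂_j²(x)` is the observation
variance predicted at the MLE trajectory under a lower-truncated normal
noise model (observations are non-negative concentrations). The loop
stops once every parameter is identifiable in two consecutive
iterations, then computes profile-likelihood confidence intervals by
bisection. Two literature benchmark criteria (profile-ensemble
generalized variance and its noise-scaled *relative variance* variant)
and random sampling are included for comparison, plus a replicated
simulation harness with three built-in case studies (a sum of two
exponential decays; single- and two-output Monod bioreactor models) and
evaluation utilities (identifiability-probability curves, CI widths and
trajectory errors at a fixed budget, Wilcoxon signed-rank comparisons).

## A worked example

```r
library(alpipe)

cfg <- experiment_preset(1, seed = 1)   # sum of two exponential decays
tr  <- run_replication(cfg, replication = 1)
tr
#> <al_trace> ealpipe rep 1 (stop_on_id): 14 observations, reliably
#> identifiable at n = 14, terminated: identifiable

round(tr$final$mle$theta, 3)
#> beta1 beta2
#> 2.024 3.644

sapply(tr$final$cis, `[[`, "width")
#>     beta1     beta2
#> 0.1837197 1.1037787
```

Reading the output: starting from a single observation at t = 3 h, the
design needed 14 measurements (the reference protocol averages ≈ 9–10
over 100 replications) before both decay rates were certified — every
profile crossed the 1.92-nat threshold on both sides — in two
consecutive iterations. The fitted rates are close to the simulation
truth (2, 4) h⁻¹; the first rate is pinned to a width-0.18 interval while
the second, whose component decays into the noise floor almost
immediately, keeps a much wider interval — collecting data that narrows
exactly this kind of gap is what the acquisition rule is for.

The same harness runs method comparisons:

```r
traces <- run_experiment(experiment_preset(1, seed = 1),
                         methods = c("ealpipe", "random"), reps = 20)
sapply(traces, mean_iterations_to_identifiability)
#> ealpipe  random
#>     9.9    49.6
```

Random sampling almost never certifies within the 50-point cap (failures
score 50), while the active design needs about ten points.

A thin command-line wrapper is included:

```sh
Rscript inst/scripts/alpipe-run.R --experiment 1 --method ealpipe,random \
    --reps 5 --seed 1 --mode stop_on_id --out results/
```

## Learning more

The methods vignette (`vignettes/active-identifiability.Rmd`) documents
the model and noise assumptions, every tunable parameter with its
default and rationale, the numerical choices (integrator, optimiser,
bisection tolerances, weight normalisation), what the synthetic
generator does and does not emulate, and known limitations — including a
genuine sensitivity of certification speed to profile-fit convergence
depth that anyone comparing identifiability pipelines should read first.
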