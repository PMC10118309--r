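---
title: "Fixed versus flexible decision criteria: models, degeneracy, and identification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Fixed versus flexible decision criteria: models, degeneracy, and identification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(flexcrit)
```

## The problem

In a detection experiment an observer decides, trial by trial, whether a weak
stimulus was present. Signal detection theory models the observer's internal
evidence as a one-dimensional measurement `x`: Gaussian with mean 0 when the
stimulus is absent and mean `mu` when present, with common SD `sigma`, and the
observer responds "present" when `x` exceeds an absolute criterion `k`
(expressed in the same physical units as the measurement). Two relative,
unit-free quantities are observable from the hit rate H and false-alarm rate F:

* discriminability `d' = z(H) - z(F) = mu / sigma`, and
* the relative criterion `c = -(z(H) + z(F)) / 2 = (k - mu/2) / sigma`.

Inattention is modelled as an increase of `sigma` from an attended ("valid")
to an unattended ("invalid") condition. The empirical pattern known as
*subjective inflation* is: with d' matched across conditions, the invalid
condition shows a lower (more liberal) relative criterion, `c_inv < c_val` —
observers report "seen" more readily exactly where their sensory evidence is
noisier. A popular explanation posits a *fixed* absolute criterion:
`k_inv = k_val`.

This package implements the quantitative case that the inflation signature
cannot establish a fixed criterion, and the task design under which the
absolute criterion does become measurable.

## The solution family

Writing the matched-d' constraint `mu = d' sigma` per condition into
`c_inv < c_val` gives a single inequality on absolute quantities,

```
k_inv < (sigma_inv / sigma_val) * k_val,     with k_val > 0,
```

so *every* criterion pair below the linear-scaling line accounts for the
signature. `iarf_satisfied()` classifies a condition pair against this bound
(with a 1e-9 tolerance band in ratio units around the boundary, since the
inequality itself is strict and floating point needs a convention), and
`iarf_region()` maps it over a grid of noise and criterion ratios. The
criterion-setting rules themselves are represented by `criterion_policy()`
objects: power laws `k = k_ref (sigma/sigma_ref)^gamma` with `gamma = 0`
(fixed), `gamma = 0.5` (square root), `gamma = 1` (the Bayes-optimal rule
under d'-matching and equal priors, since `k_Bayes = mu/2` there), plus a
"misbelief" observer who applies Bayes' rule under a wrong belief about how
much the noise changed. Two reductions pin the misbelief construction down:
believing the noise never changes reproduces the fixed policy, and believing
the true ratio reproduces the optimal one. We deliberately parameterise the
wrong belief by a single believed noise ratio applied to any non-reference
condition — the minimal structure with those endpoints; richer wrong-belief
models would add parameters the data discussed here cannot constrain.

```{r}
fixed <- criterion_policy("fixed", k_ref = 1, sigma_ref = 1)
signature_under_policy(fixed, sigma_val = 1, sigma_inv = 2, d_prime = 1)
sqrt_obs <- criterion_policy("power", k_ref = 1, sigma_ref = 1, gamma = 0.5)
signature_under_policy(sqrt_obs, 1, 2, 1)
```

Both show `c_inv < c_val`; only their absolute criteria differ, and those are
exactly what the task does not measure: `params_family_from_summary()` shows
that every choice of `sigma` maps one measured `(d', c)` pair to a
`(mu, sigma, k)` triple with *identical* hit and false-alarm rates. Three
unknowns, two measurements.

## The embedded-category task and identification

In the embedded-category design the stimulus orientation is drawn from one of
two zero-mean Gaussians — narrow (category 1) or broad (category 2) — and the
observer categorises it through measurement noise `sigma_m`, responding
"category 2" when `|x| > k`. Two features matter. First, the decision variable
is pinned to a physical axis (degrees of orientation), so `mu` and the
criterion live in known units. Second, the categories differ in spread, so the
ideal boundary moves outward as `sigma_m` grows: with
`v1 = sigma_narrow^2 + sigma_m^2`, `v2 = sigma_broad^2 + sigma_m^2` and prior
odds `pi`,

```
k*^2 = (log(v2/v1) + 2 log pi) / (1/v1 - 1/v2),
```

the point where the prior-weighted measurement densities cross
(`optimal_embedded_criterion()`). When an extreme category-2 prior makes the
numerator non-positive, no interior boundary exists and the function reports
that condition rather than clamping — a degenerate design, not a fit to rescue.

Because `(s, response)` pairs are observed in physical units, the Bernoulli
likelihood with kernel
`P(resp 2 | s) = pnorm((s-k)/sigma_m) + pnorm((-k-s)/sigma_m)` identifies both
`k` and `sigma_m`. `fit_embedded_observer()` maximises it and returns a
standard modelling object:

```{r}
m <- embedded_category_model(3, 12, sigma_m = 4)
trials <- simulate_embedded_category(m, k = 6, n_trials = 5000, seed = 7)
fit <- fit_embedded_observer(trials)
summary(fit)
```

Fitting the same observer at two noise levels then distinguishes fixed from
flexible criterion-setting — the comparison the detection task provably cannot
make.

## Tunable parameters and defaults

* **Detection conditions.** `sigma_val = 1`, `sigma_inv = 2` (measurement
  units) anchor the worked examples and figures; matched discriminability
  defaults to `d' = 1`, a typical near-threshold operating point. d'-matching
  is imposed analytically (`mu = d' sigma`, `match_dprime()`) rather than by
  emulating a psychophysical staircase, whose dynamics are irrelevant to the
  mathematical claims.
* **Criterion anchor.** Figure routines default to
  `k_ref = d' * sigma_val / 2`, i.e. a fixed-criterion observer who happens to
  be optimal in the valid condition; the same anchor is used across panels for
  comparability.
* **Embedded-category defaults.** The task geometry in the literature is
  schematic, so the package's defaults are its own choices, in degrees:
  `sigma_narrow = 3`, `sigma_broad = 12`, `sigma_m = 4` — a narrow category a
  few degrees wide, a broad one about four times wider, and measurement noise
  of the same order as the narrow category, values typical of orientation
  categorisation experiments. Parameter-recovery examples also use the tighter
  geometry (0.8, 2.0, 0.5). Orientation wrap-around is ignored; the
  constructors warn when an SD exceeds 30 degrees, where the unwrapped
  Gaussian approximation starts to strain.
* **Region grid.** `iarf_region()` defaults to noise ratios in [1, 3] and
  criterion ratios in [0, 2.5] on a 251 x 251 grid, wide enough to contain
  the three reference policies; ratios below 1 (less noise without attention)
  are flagged invalid rather than classified.

## Numerical choices

* **Boundary rates.** Empirical H or F of exactly 0 or 1 are corrected by the
  1/(2N) rule in `estimate_summary()`; the analytic `summary_from_rates()`
  refuses boundary rates instead of silently correcting, so corrections are
  always an explicit, counted-data affair.
* **Quantile dialect.** `z` is the standard-normal quantile throughout; no
  log-linear alternative is offered, keeping one dialect.
* **Round-trip precision.** The identity chain parameters → rates → summary
  is exact to 1e-9 for observers whose implied z-scores stay within roughly
  ±5; beyond that, double-precision probabilities near 0/1 cannot carry the
  information back. Randomised tests sample d' in (0.05, 4) and c in
  (-2.5, 2.5) accordingly.
* **Maximum likelihood.** The fit runs bounded quasi-Newton (L-BFGS-B) on
  `(k, log sigma_m)` with analytic gradients; the log parameterisation keeps
  `sigma_m` strictly positive (the `sigma_m = 0` degenerate fit is excluded by
  the open bound) and `k >= 0` is a hard box constraint. Five deterministic
  starts around data-driven anchors (`k0` = median |s| among category-1
  responses, `sigma_m0` = SD of category-1 stimuli) guard against the ridge
  where `k` and `sigma_m` trade off. Standard errors come from the observed
  information at the optimum — a deliberate choice over bootstrap to keep
  desk-scale runtimes; they are Wald-quality and degrade when `k` sits on the
  bound. All-identical responses are refused as non-identifiable.
* **Tie-breaking.** The measurement tie `x = k` (probability zero) is resolved
  as "absent"/"category 1" for determinism.
* **Seeding.** Simulators take one integer seed and derive per-operation
  Mersenne–Twister streams from it; the caller's RNG state is saved and
  restored, and equal seeds give bit-identical trial tables.

## What the generator does and does not emulate

`simulate_detection()` and `simulate_embedded_category()` implement the
generative assumptions exactly: equal-prior (configurable) stimulus
presentation, Gaussian measurement noise, deterministic threshold responses.
They do not simulate the four-quadrant spatial display, cue timing, lapses,
guessing, criterion drift, or sequential effects. Passing tests therefore show
that the package's mathematics is internally consistent and that the
estimators recover the parameters of *this* observer class; they do not show
that human data are free of the omitted processes, and fitted `sigma_m` in
real data would absorb any unmodelled response noise.

## Problem sizes

The shipped tests run detection simulations at 1e5 trials per condition
(standard-error bands of a few thousandths on c), embedded-category fits at
2e4 trials, and the recovery study as 20 seeded replicates of 2e4 trials —
sizes at which median recovery error is comfortably within 5% for `k` and 10%
for `sigma_m` while the whole suite stays desk-scale. Grid-search oracles use
a 1e-3 resolution in criterion units.

## Limitations

Unequal-variance detection (signal SD differing from noise SD), ROC fitting,
confidence ratings, lapse rates, and hierarchical (multi-subject) fitting are
out of scope. The misbelief observer covers only a wrong believed noise
ratio. No human data ship with the package; all quantitative statements are
about simulated observers under the stated generative model.
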