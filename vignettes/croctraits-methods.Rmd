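---
title: "Methods: spatial–social personality and predictability from acoustic telemetry"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: spatial-social personality and predictability from acoustic telemetry}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Estuarine crocodiles (*Crocodylus porosus*) carrying coded acoustic
transmitters are detected by a fixed array of underwater receivers along a
single river channel. From those raw detections, `croctraits` derives three
monthly behaviours per individual — **sociability** (the proportion of the
conspecifics in an individual's monthly social environment that it was
observed co-occurring with), **daily activity** (mean river distance
travelled per day, km/d), and **site fidelity** (overlap of consecutive
monthly home ranges) — and then partitions their variation into among- and
within-individual components with a trivariate double-hierarchical Gaussian
model (DHGLM). The derived quantities are the standard currency of animal
personality research: repeatability, the coefficient of predictability,
realized phenotypes and realized residual intra-individual variation
(rIIV), mean–rIIV correlations, and behavioural syndromes.

## Behavioural metrics

**Centres of activity (COA).** Time is partitioned into half-open bins
(default 60 min, epoch-aligned; the bin width is user-configurable as the
method's source algorithm prescribes). Within each bin, an individual's
position is the detection-count-weighted mean chainage of the receivers
that heard it. Because the study river is effectively a single channel, all
spatial work is one-dimensional on chainage (distance along the
centreline); the least-cost in-river distance between two positions is
then exactly the absolute chainage difference. Planar positions can be
projected to chainage with `project_to_chainage()`; equidistant ties
resolve to the lower chainage.

**Daily activity.** Distances between successive COAs are assigned to the
calendar day of the earlier COA, summed per day, and averaged over the
days of the month that have at least one travel segment. A month with
fewer than two COAs yields a missing value, never a zero — sparse months
carry no information about movement rate, and zero-filling would bias
activity downward.

**Utilization distributions and site fidelity.** The monthly UD is a
Gaussian kernel density of the month's COA positions on a chainage grid
(default 0.5 km step, 1 km bandwidth), truncated and renormalized to the
river extent. The 95% home range is the smallest set of grid bins, taken
in descending density order, whose mass reaches 0.95; its linear extent
(times a nominal 0.1 km channel width for km²) is the home-range size. At
least five *unique* COA positions are required per month; with fewer —
including five detections all at one receiver — the month's UD is absent.
Site fidelity is the volume of intersection `VI = sum(min(d_a, d_b))`
between consecutive monthly UDs, assigned to the later month; a gap month
breaks both of its pairs.

**Sociability.** The monthly social environment of a focal individual is
every tagged conspecific detected, during the same calendar month, at any
receiver the focal visited that month — a monthly, receiver-set based
definition that does not require contemporaneity. Association is stricter:
two individuals co-occurring at the same receiver within a 240 s window.
The default window semantics are a sliding pairwise |Δt| ≤ 240 s, which
avoids the boundary artefacts of fixed bins; a fixed-bin mode
(`association_mode = "binned"`) is retained for comparison with bin-based
implementations. Sociability is |observed| / |potential|; with an empty
environment the ratio is undefined and the value is missing, not zero.

**Calendar conventions.** Timestamps are stored in UTC. Month and day
boundaries are taken in a configurable study timezone (default UTC+10,
the field site's offset), because month assignment — and therefore every
monthly metric — depends on it.

## The model

For behaviour *k* of individual *i* in month *t* (year *y(t)*):

$$y_{ikt} \sim \mathcal{N}(\mu_{ikt},\ \sigma_{ikt})$$
$$\mu_{ikt} = \beta_{0k} + \mathrm{month}_k(t) + \beta_{TL,k}\,TL_i +
  \beta_{det,k}\,D_{it} + a_{ik} + u_{y(t),k}$$
$$\log \sigma_{ikt} = \gamma_{0k} + \gamma\mathrm{month}_k(t) +
  \gamma_{TL,k}\,TL_i + \gamma_{det,k}\,D_{it} + b_{ik} + v_{y(t),k}$$

with crossed random effects
$(a_{i\cdot}, b_{i\cdot}) \sim \mathcal{MVN}(0, \Sigma_{ID})$ and
$(u_{y\cdot}, v_{y\cdot}) \sim \mathcal{MVN}(0, \Sigma_{year})$, each a
full 6×6 covariance parameterized as SDs plus a correlation matrix. The
dispersion model mirrors the mean model, including its covariate coding.
Sociability and activity are cube-root transformed (to de-skew before
modelling residual variation), all responses standardized to mean 0 / SD 1,
total length standardized, and monthly detection counts log-transformed
then standardized. January is the month reference level. Sex is excluded
from the default model. Individuals observed in fewer than a configurable
minimum of months (default 2) are dropped.

**Missingness.** Rather than fitting three per-behaviour subset models, a
single joint model is fitted with per-cell missingness masks: an
unobserved cell simply contributes nothing to the likelihood. The
likelihood contributions are equivalent and the engineering is simpler;
the correlation structure is then informed by whatever cells co-occur.

**Priors.** "Uninformative" is made concrete as Normal(0, 5) on all fixed
effects, half-Normal(0, 1) on all random-effect SDs, and LKJ(1) — uniform
over valid correlation matrices — on both correlation blocks. All are
configurable through `prior_spec()`.

## Sampler

`fit_dhglm()` uses a blocked MCMC scheme written for exactly this
posterior:

* mean-model fixed effects, individual intercepts $a_i$ and year
  intercepts $u_y$ have Gaussian full conditionals and are drawn exactly
  (Gibbs), conditioning on the dispersion side through the cell variances
  and on their partner effects through the conditional MVN prior;
* dispersion-model fixed effects, $b_i$, $v_y$ and both (SD, correlation)
  blocks are updated by coordinate-wise adaptive random-walk Metropolis
  (Roberts–Rosenthal diminishing adaptation toward 0.44 acceptance,
  active during warmup only, frozen afterwards);
* exact interweaving moves resolve the additive confounding that slows
  plain Gibbs: shifting an intercept (or the total-length slope, whose
  covariate is constant within individuals) against the corresponding
  random effects leaves the likelihood invariant, and the conditional of
  the shift is Gaussian, so it is drawn exactly.

Correlation matrices are parameterized by canonical partial correlations
(`tanh` of unconstrained coordinates); the Metropolis target includes the
analytic log-Jacobian of that transform, so the prior over correlation
matrices is exactly LKJ. A non-positive-definite proposal has density zero
rather than raising an error. The centred parameterization is used
throughout: with conjugate blocked updates and interweaving moves the
funnel geometry that motivates non-centring in gradient-based samplers
does not arise, and the Gaussian conditionals that make the sampler fast
exist only in centred form.

The default run configuration is 4 chains × 8000 iterations (6000
warmup, thinning 2). Convergence is reported as split-R̂ and effective
sample size for all fixed effects, SDs and correlations, with a warning
when the contract (R̂ < 1.01, ESS > 1000) is not met; the fit object is
returned either way so the caller can decide. Note the retained-draw count
follows from chains × (iter − warmup) / thin — 4000 under the default
configuration; actual retained counts are always reported rather than
assumed.

Reproducibility: every chain derives its RNG stream from the `seed`
argument, and all randomness (including inside the compiled sampler) goes
through R's RNG, so identical seeds give identical draws.

## Derived statistics

* **Repeatability**: $R_k = \sigma^2_{ID,k} / (\sigma^2_{ID,k} +
  \sigma^2_{year,k} + (\exp \gamma_{0k})^2)$. The residual term uses only
  the dispersion intercept — the population-mean residual SD on the log
  scale, exponentiated then squared — not the month or covariate
  dispersion effects.
* **Coefficient of predictability**: $CV_p = \sqrt{\exp(\omega^2) - 1}$,
  with $\omega$ the among-individual SD of the dispersion intercepts.
  The square root follows the lognormal coefficient-of-variation form;
  `cv_p_point(0.29) = 0.296` and `cv_p_point(0.31) = 0.318` reproduce the
  published 2-dp worked examples (0.30, 0.32), which is what fixes this
  reading of the formula. For the site-fidelity column (ω = 0.26) this
  computation gives 0.2648, which rounds to 0.26 — one 2-dp rounding step
  away from the published 0.27; a rounding artefact of 2-dp table inputs.
* **Realized phenotypes**: per draw, $\beta_{0k} + a_{ik}$,
  destandardized and (for cube-rooted responses) cubed back to original
  units.
* **Realized rIIV**: per draw, $\exp(\gamma_{0k} + b_{ik})$ rescaled by
  the response's standardization SD. For cube-root transformed responses
  there is no exact SD mapping through the cube, so the original-unit
  rIIV is labelled approximate (attribute `approximate`).
* **Correlations**: the mean–rIIV correlation $r(a_k, b_k)$ per behaviour
  and the syndrome correlations $r(a_k, a_{k'})$ per pair, flagged
  significant when the 95% HPD excludes zero.

All derived quantities are computed **per posterior draw** and then
summarized — full uncertainty propagation, the statistically standard
choice. The plug-in computation on posterior means is also reported
(`$plugin`), because worked examples on published tables are plug-in
computations on printed point estimates.

Intervals are highest-posterior-density (narrowest) intervals throughout,
computed by the sliding-window method on sorted draws.

**Associate counts.** To check that an activity–sociability syndrome is
not an artefact of the sociability denominator, a Poisson mixed model
relates the monthly number of potential and observed associates to
standardized home-range size, association type, and their interaction,
with individual and year random intercepts — fitted with the same
adaptive-Metropolis machinery and priors.

## The synthetic-data generator

Two generators make every stage testable without field data.

`simulate_behaviour_panel()` draws monthly panels from exactly the model
above with known truth. Its defaults emulate the study conditions: 118
individuals, a 24-month panel each (about 2830 individual-months —
matching a decade-scale study in which individuals were monitored for
about 25 months on average), fixed effects and variance components at the
published point estimates, and per-behaviour missing-completely-at-random
rates (0.002, 0.003, 0.487) that reproduce the reported per-behaviour
subset sizes, site fidelity being observable in roughly half the months.
Correlations not reported in the main text default to zero; the resulting
6×6 correlation matrix is verified positive semi-definite at
construction. Covariates are generated already standardized, so the panel
is model-ready with identity transforms.

`simulate_detections()` is a mechanistic river-telemetry simulation: a
100 km meandering channel, receivers 3.5 km apart, pings at intervals
uniform on 90–120 s, and a hard 400 m detection cutoff in river distance
(a configuration hook is the natural place for a logistic range curve,
but none is fitted here). Movement is a discrete-time mean-reverting
Gaussian step process on chainage (exact Ornstein–Uhlenbeck
discretization, reflected at the river ends): strong attraction produces
resident phenotypes, weak attraction nomadic ones. Receivers log at 1 s
resolution.

What the generators do **not** emulate — and hence what passing tests do
not show about real data: tidal and diel movement rhythms, temperature
effects, tag loss, receiver outages, detection-probability decay with
distance, non-random (state-dependent) missingness, and any feedback
between social context and movement. Parameter recovery on these panels
demonstrates that the estimation machinery is correct, not that the field
sampling design is unbiased.

## Numerical choices and degenerate inputs

* UD densities are bin masses summing to 1 (tolerance 1e-9); the 95%
  mask is minimal by construction (descending-density threshold).
* Exact duplicate detections (same tag, receiver, instant) are removed at
  load with a logged count; near-duplicates are kept. Dedup is
  idempotent.
* Zero-variance responses, non-PSD covariance truths, negative chainages
  and invalid deployment intervals fail fast with named errors; a non-PSD
  correlation *proposal* inside the sampler is rejected with density
  zero instead.
* A run without a seed draws one and reports it, so it can be replayed.

## Scale of the verification experiments

The test suite fixes its experiment sizes as package choices: oracle
equivalence of the log posterior on 5-individual toys (tolerance 1e-8);
sign recovery of a −0.6 mean–dispersion correlation and a −0.35 syndrome
at 100 individuals × 36 months with 2 chains × 2000 iterations; HPD
calibration of fixed effects and individual-level SDs over 20 seeded
replicates at 30 × 24 (nominal 95% coverage within binomial/Monte-Carlo
noise); and threshold-stability of fixed effects on a fully observed
60 × 24 panel, where chains are run long enough (2 × 4000) that
Monte-Carlo error does not masquerade as a threshold effect.

## Known limitations

* The river is assumed a single channel; branching networks would need a
  graph metric in place of 1D chainage.
* The 1D kernel UD replaces a 2D least-cost kernel; for a river that is
  effectively linear the information lost is the cross-channel
  dimension, which the receiver array cannot resolve anyway.
* Year-level variance components are weakly identified when a panel
  spans few years (their posteriors then lean on the half-Normal prior).
* The associates model treats home-range size as a covariate measured
  without error.
* Original-unit rIIV for cube-rooted responses is approximate (see
  above).
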