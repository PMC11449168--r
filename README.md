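# croctraits

Spatial–social personality and predictability of river-dwelling animals
from passive acoustic telemetry.

## What it does, and for whom

Movement ecologists tracking animals (here: estuarine crocodiles,
*Crocodylus porosus*) with coded acoustic transmitters and a fixed
receiver array face a two-stage problem. First, raw detections must be
turned into monthly behavioural measures: **sociability** (observed over
potential associates within a calendar month), **daily activity** (mean
river distance per day from centre-of-activity positions, km/d) and
**site fidelity** (volume-of-intersection overlap of consecutive monthly
home ranges). Second, the question "do individuals differ, and do they
differ in how *consistent* they are?" requires partitioning variance both
among and within individuals.

`croctraits` implements both stages. The core is a trivariate
**double-hierarchical Gaussian model** (DHGLM): for behaviour *k* of
individual *i* in month *t*,

    y_ikt ~ Normal(mu_ikt, sigma_ikt)
    mu_ikt        = b0_k + month_k(t) + b_TL,k TL_i + b_det,k D_it + a_ik + u_year(t),k
    log sigma_ikt = g0_k + gmonth_k(t) + g_TL,k TL_i + g_det,k D_it + b_ik + v_year(t),k

with crossed individual/year random effects and a full 6×6 correlation
matrix at each level, fitted by a blocked MCMC sampler (Gibbs for the
Gaussian-conditional blocks, adaptive Metropolis for the dispersion side,
exact interweaving moves; written in C++ via RcppArmadillo). From the
posterior it derives:

* repeatability `R = V_ID / (V_ID + V_year + V_res)` with
  `V_res = exp(g0)^2`,
* the coefficient of predictability `CV_p = sqrt(exp(omega^2) - 1)`,
* realized phenotypes and realized rIIV in original units,
* mean–rIIV correlations and behavioural syndromes,
* a Poisson GLMM for monthly associate counts vs home-range size.

A synthetic-data module generates both behavioural panels from the model
(with known truth, for parameter recovery) and raw detection tables from
a mechanistic river-telemetry simulation, so the entire pipeline is
verifiable without any field data.

## Worked example

Simulate a 60-individual, 24-month panel from the generative model and
recover its structure (desk-scale chains; the default configuration is 4
chains × 8000 iterations):

```r
library(croctraits)
truth <- synthetic_truth(n_individuals = 60, n_months = 24)
sim <- simulate_behaviour_panel(truth, seed = 1)
md  <- prepare_model_data(sim$panel, transform = "identity",
                          standardize = FALSE, log_detections = FALSE)
fit <- fit_dhglm(md, control = dhglm_control(chains = 2, iter = 3000,
                                             warmup = 1500, thin = 1),
                 seed = 1)
print(fit)
#> dhglm_fit: 3000 draws x 498 parameters (2 chains)
#>   individuals: 60, years: 2, rows: 1440
#>   converged: FALSE (max rhat 1.103, min ess 44)

r <- repeatability(fit, "activity")
cat(sprintf("repeatability (activity): %.2f (%.2f to %.2f)\n",
            r$mean, r$hpd[["lower"]], r$hpd[["upper"]]))
#> repeatability (activity): 0.36 (0.09 to 0.65)

cp <- coefficient_of_predictability(fit, "sociability")
cat(sprintf("CV_p (sociability): %.2f (%.2f to %.2f)\n",
            cp$mean, cp$hpd[["lower"]], cp$hpd[["upper"]]))
#> CV_p (sociability): 0.36 (0.22 to 0.51)

print(random_effect_correlations(fit), digits = 2)
#>    quantity    pair  mean hpd_low hpd_high significant
#> 1 mean_riiv     soc -0.38   -0.82   0.2279       FALSE
#> 2 mean_riiv     act -0.15   -0.49   0.1523       FALSE
#> 3 mean_riiv     fid -0.54   -0.87  -0.1852        TRUE
#> 4  syndrome soc_act -0.35   -0.70   0.0052       FALSE
#> 5  syndrome soc_fid  0.17   -0.26   0.6370       FALSE
#> 6  syndrome act_fid -0.44   -0.72  -0.1776        TRUE
```

The generating truth here puts the among-individual variance share of
activity at roughly a third, a negative sociability–activity syndrome and
negative mean–rIIV correlations for sociability and site fidelity; the
desk-scale posterior recovers those magnitudes with honest (wide)
intervals, and the convergence warning is the short chains talking — at
the default 4 × 8000 configuration the contract (split-R̂ < 1.01,
ESS > 1000) is met on panels of this size. `run_pipeline()` wires the
same steps (or the raw-detection route:
`simulate_detections()` → `monthly_behaviours()`) end to end, writing
every table plus a manifest; `sensitivity_analysis()` refits across
minimum-observation thresholds.

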