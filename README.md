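# mealshare

Bayesian analysis of **individual feed ingestion rates in group-reared
fish** from per-pellet feeding-trial records.

When a cage of eight tagged fish is fed one pellet at a time, every
pellet is a categorical observation: it is taken by fish 1–8 or sinks
uneaten.  `mealshare` models these outcomes with a hierarchical
multinomial softmax (discrete-choice) model,

```
prob[i] = exp(sco[i]) / sum_k exp(sco[k]),   k = 1..9

sco[i,j,c] = b0[D] + bL2·L²[i,c] + bT·T[j,c] + bT2·T²[j,c]
             + bS·S[j,c] + bR·R[j,c] + Fish[i,c] + Replicate[j,c]
sco[nc,j,c] = -sum_i sco[i,j,c]
```

with body surface `L² = (LT·δ)²` (shape coefficient δ = 0.148 for
European seabass), water temperature `T`, a boat-traffic stress proxy
`S`, chronic diet level `D` (60/75/90% of recommended ration), delivered
ration `R`, and crossed Gaussian random effects for fish
(`σ_Fish`) and feeding trial (`σ_Replicate`).  The ninth (not-consumed)
score is pinned to minus the sum of the fish scores, which fixes the
softmax gauge and lets the overall score level govern feed waste.  The
central scientific quantity is the partition of residual variability,
`σ_Fish / (σ_Fish + σ_Replicate)`: how much of the unexplained variation
in who-gets-the-pellet is stable fish identity (a feeding hierarchy)
rather than trial-to-trial noise.

Because temperature and boat traffic are seasonally collinear, the model
is fitted in two variants (stress-based or temperature-based, never
both) and compared by PSIS-LOO.

The package provides

* `simulate_intake_data()` — a seeded generator reproducing the sea-cage
  trial design (6 cages × 8 fish × 8 trials, seasonal cooling
  21.8–27.6 °C, temperature-correlated boat counts, rations 10–80% of
  plan) with known ground truth;
* `read_intake_data()` / `write_intake_data()` — plain-CSV I/O with
  validation;
* `fit_intake()` — Hamiltonian Monte Carlo with analytic gradients,
  non-centred random effects and split-R-hat/ESS diagnostics
  (3 chains × 2,000 draws after 2,000 warm-up by default);
* `loo_intake()` / `loo_compare_intake()` — Pareto-smoothed
  importance-sampling leave-one-out cross-validation;
* `variance_partition()`, `meal_shares()`, `fish_effect_table()`,
  `predicted_counts()`, `clone_curve()` and ggplot helpers — the derived
  quantities describing feeding hierarchies.

See the vignette `vignettes/feeding-hierarchies.Rmd` for the model,
priors, sampler and generator in detail.

## Worked example

```r
library(mealshare)

sim <- simulate_intake_data(seed = 1)   # study design, known truth
sim$data
#> Feeding-trial dataset: 48 fish in 6 cages, 48 trials, 913 pellet events
#>   diet levels: 60/75/90 | waste fraction: 9.1%
#>   covariates standardized

meal_shares(sim$data)
#> Meal shares: 48 fish, 48 trials
#> Waste by diet level (%):
#>  diet_level waste_pct
#>          60       6.4
#>          75      11.3
#>          90       9.5
#> Top fish by median share (reference under even split: 12.5%):
#>  fish_id diet_level median_share   q25  q75
#>    C1-F4         60         21.1 19.55 27.1
#>    C2-F5         60         19.5 16.26 21.1
#>    ...

fit <- fit_intake(sim$data, variant = "stress", seed = 1)
#> HMC stress variant: 3 chains x 2000 draws | max core R-hat 1.0069 |
#> min core ESS 513 | divergent 0.00%
summary(fit)
#>         parameter     q05  median    q95 rhat  ess
#> 1           beta0 -0.0148  0.1995  0.418    1  523
#> 2      sigma_fish  0.3168  0.4038  0.510    1 1138
#> 3 sigma_replicate  0.1766  0.2497  0.372    1  894
#> 4         beta_L2  0.0091  0.1227  0.242    1  947
#> 5          beta_S -0.1768 -0.0958 -0.021    1  805
#> ...
```

The posterior medians sit close to the generating truth
(`σ_Fish = 0.431`, `σ_Replicate = 0.183`, `β_S = -0.104`): the fish
dispersion dominates the replicate dispersion, the stress slope is
credibly negative (boat traffic suppresses feeding), and the size slope
is small.  The derived quantities:

```r
s <- summary(fit)
variance_partition(s$median[s$parameter == "sigma_fish"],
                   s$median[s$parameter == "sigma_replicate"])
#> [1] 0.618            # fish identity carries ~62% of residual variance here

fe <- fish_effect_table(fit)
cor(fe$effect_median, fe$median_share)
#> [1] 0.890            # fish effects track observed meal shares

loo_intake(fit)
#> PSIS-LOO (stress variant; 913 pellets, 6000 draws)
#>   elpd_loo  -1870.3 (se 17.1)
#>   p_loo        58.4 (se 4.0)
#>   looic      3740.6 (se 34.1)
#>   Pareto k > 0.7: 3 of 913 observations
```

With the dispersion medians reported for the original study's fitted
stress model, `variance_partition(0.431, 0.183)` returns `0.702` — fish
identity accounting for 70.2% of the residual variance in ingestion
rate.  Marginal-effect curves for a population-typical cage come from
`clone_curve(fit, "S")` (or `"L2"`, `"R"`; `"T"` for the temperature
variant), and `plot_meal_shares()`, `plot_predicted_counts()`,
`plot_clone_curve()` draw the standard figures.

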