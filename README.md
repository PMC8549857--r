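# lichenrisk

Critical loads and ecological risk for epiphytic macrolichen communities
under atmospheric nitrogen and sulfur deposition.

Forest managers and air-quality regulators need to know not just *whether*
deposition harms forests, but *how much* harm a given loading implies.
Epiphytic macrolichens answer both questions earlier than almost any other
receptor. This package turns FIA-style lichen survey data — site × species
detections with ordinal ocular abundance codes, plus per-site deposition
and climate covariates — into quantitative risk statements:

* **Site metrics**: total species richness, N- and S-sensitive species
  richness, and abundance indices (sum of ocular codes 3–4) for the
  forage, cyanolichen and matrix functional groups.
* **Dose–response**: 90th-percentile quantile regressions of each metric
  on deposition, `Q₀.₉(y|x) = β₀ + β₁x + β₂x²`, fit by minimizing the
  pinball loss `ρ_τ(u) = u(τ − 1[u<0])` with a purpose-built
  Frisch–Newton interior-point LP solver; goodness of fit by R1 (one
  minus the pinball-objective ratio against the intercept-only fit) and
  nested-model selection by ΔAIC > 25.
* **Critical loads**: the fitted curve is inverted at a 20% decline from
  its value at minimum observed deposition; 20/50/80% declines mark
  moderate / high / very-high risk. Confidence intervals come from a
  pairs (site) bootstrap.
* **Species extirpation risk**: depositions at 20/50/90% declines in a
  species' detection frequency past its peak.
* **Community statistics**: analysis-of-means comparisons (on ranks, and
  on Levene absolute deviations from the median for spread) of
  sensitivity ratings among functional groups and between rare and
  common species.
* **Synthetic data**: a seeded generator of FIA-style surveys whose
  conditional 90th quantile follows a *known* quadratic, so every stage
  is testable against closed-form truth.

## Worked example

Simulate a 2000-site survey whose true richness envelope is
`f(x) = 30 − 3x + 0.05x²` (critical load 2.245 kg from the data minimum of
0.2 kg), fit the 90% quantile curve, and invert it:

```r
library(lichenrisk)

cfg <- synthetic_config(
  n_sites = 2000, seed = 42,
  deposition_law = list(west = c(min = 0.2, max = 12),
                        east = c(min = 2.2, max = 12)),
  true_curve = list(total_richness = c(30, -3, 0.05)))
d <- generate_dataset(cfg, mode = "metric")

x <- d$sites$n_dep
fit <- fit_quantile_regression(deposition_design(x, 2),
                               d$metrics$total_richness, tau = 0.9)
fit
#> Quantile regression fit (tau = 0.9, n = 2000, p = 3)
#>   intercept         dep        dep2
#> 30.17731679 -3.10322786  0.05828961
#> pinball objective: 2033.26

build_risk_table(fit, x_min = min(x), window = 12,
                 metric = "total_richness", pollutant = "N")
#> Critical load (total_richness, N): 2.2 kg ha-1 yr-1
#>  decline deposition value
#>      0.0  0.2013995    30
#>      0.1  1.1791392    27
#>      0.2  2.1959898    24
#>      0.5  5.5388156    15
#>      0.8  9.5232407     6

boot <- bootstrap_fits(deposition_design(x, 2), d$metrics$total_richness,
                       0.9, n_reps = 500, seed = 1)
cl_confidence_interval(boot, min(x), 12)[c("lower", "upper")]
#> bootstrap 95% CI for the critical load: 2.10 - 2.31 kg
```

The fitted coefficients track the generating curve, the estimated
critical load (2.2 kg, the deposition at the 20% decline of the fitted
envelope) sits within 2% of the closed-form truth, and the bootstrap
interval covers it. The `value` column gives the metric value at each
decline anchor — e.g. 6 of the reference 30 species remain at the 80%
(very-high-risk) anchor.

## The analysis workflow

Numbered drivers under `analysis/` run the full study on simulated data
and write their tables under `results/`:

| script | what it does |
|---|---|
| `01_simulate.R` | seeded species-mode and metric-mode survey datasets |
| `02_site_metrics.R` | six per-site metrics, sensitivity ratings, rarity |
| `03_fit_quantile_curves.R` | 90% quantile fits, R1, ΔAIC model selection |
| `04_critical_loads.R` | critical loads, anchors, risk classes, bootstrap CIs |
| `05_species_extirpation.R` | extirpation thresholds and rare-species risk |
| `06_group_comparisons.R` | ANOM/ADM group tests, gamma diversity |

Run them in order with `Rscript analysis/01_simulate.R`, etc.

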