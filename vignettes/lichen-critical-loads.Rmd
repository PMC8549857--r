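---
title: "Critical loads and ecological risk for epiphytic macrolichens"
author: "lichenrisk"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Critical loads and ecological risk for epiphytic macrolichens}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lichenrisk)
```

## The model

Epiphytic macrolichens are among the most pollution-sensitive components
of forest ecosystems, and nitrogen (N) and sulfur (S) deposition reshapes
their communities well before most other receptors respond. This package
implements a complete workflow for quantifying that risk from survey
data: site × species detection records with ordinal "ocular abundance"
codes (1–4), per-site deposition and climate covariates, and per-species
sensitivity ratings.

Six per-site indicator metrics summarize each community: total species
richness; richness of N-sensitive species ("oligotrophs", regional rating
< 4.2 kg N ha⁻¹ yr⁻¹) and of S-sensitive species (rating < 2.7 kg S
ha⁻¹ yr⁻¹), both strict inequalities; and abundance indices for the
forage, cyanolichen and matrix functional groups, each the sum of ocular
codes of 3 and 4 over the group's species (codes 1–2 are excluded because
they are the least repeatable part of the survey signal).

When a metric is plotted against deposition, its upper envelope declines
while a cloud of sub-maximal values persists at every deposition level —
sites can be poor for many reasons (climate, substrate, surveyor), but
they can only be *maximally* rich where air quality permits. The workflow
therefore models the conditional 90th percentile,

$$Q_{0.9}(y \mid x) = \beta_0 + \beta_1 x + \beta_2 x^2,$$

by minimizing the pinball (check) loss
$\rho_\tau(u) = u(\tau - \mathbf{1}[u<0])$ at $\tau = 0.9$. The fitted
curve is read as the response to deposition alone under otherwise
favorable conditions.

The decline at deposition $x$ relative to the fitted value at the
minimum observed deposition $x_{\min}$ is
$d(x) = 1 - f(x)/f(x_{\min})$, clipped to $[0,1]$. The **critical load**
is the deposition at $d(x) = 0.2$; declines of 20–50%, 50–80% and >80%
mark moderate, high and very high risk (boundaries belong to the upper
class). Species-level extirpation risk uses the same construction on a
species' detection-frequency curve, with thresholds at 20/50/90% declines
past the peak.

## Fitting machinery

The $\tau$-quantile fit is an exact linear program. `fit_quantile_regression()`
solves its bounded-variable dual with a Frisch–Newton (Mehrotra
predictor–corrector) interior-point method written for this package, then
"polishes" the solution onto the optimal vertex using the exact-fit
property (an optimal basic solution interpolates $p$ observations). The
duality gap is driven below 1e-10, and every fit is checked against the
subgradient condition: at an optimum at most $n\tau$ residuals are
strictly negative and at most $n(1-\tau)$ strictly positive. The test
suite verifies the solver against an exhaustive search over all
interpolating $p$-subsets on small instances.

Goodness of fit is R1, one minus the ratio of the fitted model's pinball
objective to the intercept-only model's. Model comparison uses AIC with
the asymmetric-Laplace pseudo-log-likelihood
$L = n(\log(\tau(1-\tau)) - 1 - \log(\hat V/n))$; only differences
between nested fits on the same response are meaningful, and a richer
model is adopted only when it improves AIC by more than 25 — a
deliberately strict hurdle appropriate to survey samples of thousands of
sites, where trivial effects are easily "significant". Uncertainty comes
from a pairs (site) bootstrap: sites are resampled with replacement and
the whole fit is repeated (10,000 replicates for headline intervals;
tests and examples use hundreds). A residual bootstrap was the main
alternative; pairs resampling was chosen because it preserves the joint
(deposition, response) distribution and makes no homogeneity assumption
across the gradient.

## Tunable parameters

| Parameter | Default | Units | Why |
|---|---|---|---|
| `tau` | 0.9 | — | upper-envelope response; robust to sub-maximal sites |
| polynomial degree | 2 | — | degree 3 available but adds no fit on these shapes |
| fit window | 12 (N), 20 (S) | kg ha⁻¹ yr⁻¹ | data beyond are too sparse to constrain the curve |
| N / S sensitivity cut-offs | 4.2 / 2.7 | kg ha⁻¹ yr⁻¹ | minimum Eastern deposition; strict `<` |
| abundance code floor | 3 | code | repeatability of the abundance signal |
| site richness floor | 5 | species | very poor lists carry no community signal |
| rating support | 8 | detections | below this a frequency curve is noise |
| rare / common | <1% / >10% | share of sites | regional presence classes |
| ΔAIC threshold | 25 | — | nested-model adoption hurdle |
| CL decline | 20% | — | low-risk cut-off defining the critical load |

All of these surface as arguments (`metric_config()`, `risk_config()`,
`run_config()`), and `run_pipeline()` echoes every one it uses to its
log, so alternative target loads can be derived by re-running with
different cut-offs.

## The synthetic generator

Real national survey data cannot ship with a package, so the generator
produces FIA-style datasets with *known* ground truth in two modes.

**Metric mode** guarantees the quantile structure exactly: metric values
are $y_i = \mathrm{round}(f(x_i)\,U_i)$ with $U_i \sim
\mathrm{Uniform}(0, 1/0.9)$, whose 90th percentile is exactly 1, so
$Q_{0.9}(y\mid x) = f(x)$ before rounding (rounding perturbs this by at
most 0.5; rounding is half-away-from-zero). Any other multiplier law is
accepted if renormalized so its 90th percentile is 1. Default curves are
parameterized as $f(x) = \mathrm{peak}(1 - x/x_0)^2$ — nonnegative
everywhere with the vertex touching zero — because a generic downward
quadratic turns negative inside the Eastern deposition range and a
negative conditional quantile for a count is meaningless. The canonical
test curve $30 - 3x + 0.05x^2$ (critical load 2.243 kg from $x_{\min} =
0.2$ by the quadratic formula) is used with the deposition law capped at
the 12 kg modeling window, where it is positive.

**Species mode** draws per-species detection probabilities as Gaussian
bumps in log-deposition (optimum $\mu_s$, width, peak frequency) and
ocular codes from an ordinal cut of a latent abundance that decays past
$\mu_s$. Peak frequencies are log-uniform on (0.01, 0.9) so that the
simulated flora has a realistic rarity spectrum — most species
infrequent, a minority common — which exercises the rare/common
comparisons. Deposition is log-uniform per region (West concentrated
low, 0.2–12 kg; East starting higher, 2.2–20 kg), and the five climate
normals are Gaussian with configurable correlation to log-deposition.

What the generator does *not* emulate: spatial autocorrelation and
geography, temporal trends, observer error structure, within-site
correlation between metrics (treated independently, as nothing in the
source analyses constrains it), and N–S interaction. Passing tests
therefore demonstrate that the estimators recover the generating law
under the stated sampling conditions — not that real communities follow
quadratic envelopes.

## Numerical choices

* **Reference point.** The curve maximum is the fitted value at the
  minimum *observed* deposition, even if the quadratic's algebraic
  maximum lies further right; in that case a warning is raised and the
  reference stays at $x_{\min}$. Published anchor tables print reference
  depositions of 0.1–0.2 kg while the stated minimum increments are
  0.2 kg; the package always uses the data minimum and documents rather
  than resolves that discrepancy.
* **Root finding.** Decline inversion brackets the *first* crossing on a
  2048-point grid, then refines by `uniroot()` to 1e-6 kg, so the
  smallest qualifying deposition is returned even for non-monotone
  polynomials. The closed-form quadratic inverse
  (`true_deposition_at_decline()`) serves as an independent oracle.
* **Rounding.** Counts at anchors are rounded half away from zero.
  Published anchor tables contain internally inconsistent roundings
  (values rounded from printed, already-rounded maxima); the package
  rounds only final reported values, once.
* **Kernel smoother.** Detection frequency is smoothed with a Gaussian
  kernel on log-deposition (Silverman bandwidth, 200-point grid). The
  source analyses used splines whose parameters are not published; the
  smoother is a stated stand-in, and tests confirm ratings of
  well-sampled species are insensitive to grid resolution.
* **ANOM limits.** Decision limits use Bonferroni-adjusted normal
  quantiles at $\alpha/2k$ with the one-way-ANOVA pooled spread, a
  conservative replacement for proprietary exact tables; the measured
  family-wise false-flag rate under the null is close to the nominal
  0.05 (verified by simulation in the test suite). The rank transform is
  plain ranks over all groups.
* **Degenerate inputs.** Interpolating fits get an AIC of −∞ (flagged);
  a constant response makes R1 undefined (NA with warning); bootstrap
  replicates with degenerate designs are dropped and counted, with >10%
  dropped an error; curve inversions that never reach the target within
  the window are NA, and a critical-load interval with >50% such
  replicates is an error.

## Open design points, decided

* A species rated in only one region does **not** count toward
  sensitive richness in the other; ratings are region-matched.
* "Common" is >10% of sites (the published range ">10–40%" is read as
  descriptive of the data, not as an upper bound of the class).
* East/West is an input column; splitting at the Great Plains is a
  data-preparation concern, not a package computation.
* Only the descending limb past the peak is searched for extirpation
  thresholds; a monotone-increasing species is flagged `"increaser"`
  and cannot be classified.
* Sites under the richness floor are flagged, never silently dropped.

## Problem sizes

The shipped analyses and tests are sized for a desk run: simulated
surveys of 2000–3000 sites, bootstrap intervals from 500–1000
replicates, coverage studies of 50 simulations at 500 replicates, and
ANOM calibration from 1000 null simulations. The headline-scale choices
(10,000 bootstrap replicates, national 8855-site surveys) are exposed as
arguments but not exercised by default.

## Limitations

Quantile dose–response on observational gradients is not a causal
estimate; deposition is confounded with climate and geography, and the
delta-AIC comparison only shows deposition carries signal beyond the
measured climate normals. Critical loads inherit the uncertainty of the
deposition surfaces used as inputs. The matrix-lichen index is flat
against deposition by construction of the group (a broad tolerance
spectrum) and is retained in outputs only to demonstrate that the
workflow declines to invert an unresponsive curve.
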