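---
title: "Methods: monitoring shortfall and overshoot in the doughnut framework"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: monitoring shortfall and overshoot in the doughnut framework}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(doughnut)
```

## The model

The doughnut framework assesses humanity's position between two concentric
sets of boundaries: a *social foundation* of minimum standards (falling below
it is **shortfall**) and an *ecological ceiling* of planetary boundaries
(going beyond it is **overshoot**). This package implements that assessment
as a pipeline: a validated indicator registry, boundary normalization,
trend estimation, elimination-pathway scenarios, income-cluster
disaggregation and two visualizations, all exercised end to end on a seeded
synthetic world.

### Normalization

Social indicators arrive as the percentage of population below a minimum
standard, so they *are* the normalized shortfall, bounded in $[0, 100]$.
Ecological indicators arrive in native units ($x_t$) and are scaled against
their planetary boundary $x^\*$ and pre-industrial Holocene baseline
$x_\mathrm{base}$:

$$\mathrm{overshoot}_t = \frac{x_t - x_\mathrm{base}}{x^\* - x_\mathrm{base}} - 1,$$

so the baseline maps to $-100\%$, the boundary to $0\%$, and overshoot is
unbounded above. Three indicators (aragonite saturation, forest area,
stratospheric ozone) are framed inversely — a *decrease* means degradation —
and use

$$\mathrm{overshoot}_t =
  \left(1 - \frac{x_t}{x_\mathrm{base}}\right) \Big/
  \left(1 - \frac{x^\*}{x_\mathrm{base}}\right) - 1,$$

which is algebraically identical to applying the direct formula to
$(x_\mathrm{base} - x_t)$ with boundary $(x_\mathrm{base} - x^\*)$ and zero
baseline — a property the test suite verifies on randomized triples.
Within-boundary values are kept as negative percentages with a
`within_boundary` flag; they are never clipped, so dashboards can show how
much safe space remains.

Dashboard levels are reported as period averages: two years by default, five
for stratospheric ozone because of its high annual variability. Display
rounding is half-away-from-zero at the printed precision; internal values
keep full precision.

```{r}
# worked value: CO2 at 416 ppm against the 350 ppm boundary, 280 ppm baseline
round_half_away(100 * overshoot_direct(416, 350, 280))
```

Some published table cells cannot be recomputed exactly from their *printed*
native values because those are themselves rounded (e.g. a HANPP level
printed as "15" Gt C); the tests document each such cell and require
agreement within the slack the input rounding implies.

### Trend estimation

Each normalized series is fit by OLS on a year index anchored at 2000,
$y = \beta_0 + \beta_1 t$, and $\beta_1$ (in %pt per year) is tested
two-sidedly with autocorrelation-robust inference. Annual series here are
short (23 points), where conventional Newey–West t-intervals over-reject
badly: with a Bartlett kernel at the usual automatic lag and a $t(n-2)$
reference, we measured a 6.5% rejection rate at the nominal 1% level on
AR(1) noise with $\rho = 0.3$.

The default inference therefore uses:

1. the **full-bandwidth Bartlett (fixed-b) HAC** standard error, whose
   wide-bandwidth variance estimate has the best known small-sample size
   control in the HAC family; and
2. a **Monte Carlo calibrated null distribution**: the robust t statistic is
   recomputed on `nsim` simulated AR(1) null series whose coefficient is
   drawn, per replicate, from the sampling distribution of the bias-corrected
   residual AR(1) estimate (Marriott–Pope-type correction plus a normal
   draw with sd $\sqrt{(1-\hat\rho^2)/T}$, truncated to the stationary
   region). The p-value is the exact Monte Carlo rank and confidence
   intervals use the order-statistic critical value.

Measured on 23-point AR(1) series, this keeps the 1%-level null rejection
rate at 1.7–2.4% for $\rho \in [0.3, 0.5]$ and 95% CI coverage at 92–94%,
versus 6.5%+ rejection for the plain Newey–West option (which remains
available as `method = "neweywest"`, with a configurable lag, for matching
externally published standard errors). The Monte Carlo default `nsim = 1999`
resolves p-values below the 0.001 significance tier used for the dashboard's
two-star marks; p-values are seeded per indicator so tables are exactly
reproducible.

Classification: a slope is `improving`/`worsening` only when significant at
the 1% level (negative slopes are improvement in both domains, since both
scales measure distance from the goal), `no_change` otherwise, `not_known`
without time series, and `no_data` for the racial-inequality placeholder,
which has no global indicator at all — this keeps exactly four `not_known`
rows in a default-registry trend table.

### Scenarios

Elimination pathways are linear: the rate needed to reach zero by the
horizon year is $-\mathrm{level}/(\mathrm{horizon} - 2022)$, with horizons
2030 (social) and 2050 (ecological), starting from the end-of-period average
level. Ecological indicators already at or below their boundary need no
pathway and are flagged `within_boundary`. Acceleration factors
($|\mathrm{required}| / |\hat\beta_1|$) are reported only for significantly
improving trends; significantly worsening trends are flagged
`reverse_required` — a number would suggest a meaningful ratio where the
direction itself must change.

### Income clusters and attribution

Countries are ranked by period-mean GNI per capita and partitioned into the
poorest 40%, middle 40% and richest 20% *of countries*: the poorest block
takes $\lceil 0.4N \rceil$ countries and the richest $\lfloor 0.2N \rfloor$,
the middle the remainder — for $N = 193$ this gives the published 78/77/38
split. The counts, not the rounding rule, are published; this rule is the
choice that reproduces them and is fixed by test. Ties across a cut break
deterministically by country code.

Cluster shortfall aggregates national values over cluster countries *with
data* (absent countries leave both numerator and denominator): a
population-weighted mean share for headcount indicators, or the population
share in countries breaching the registry threshold for threshold
indicators. Attribution follows

$$\mathrm{share\ of\ shortfall}_n =
  \frac{\mathrm{share\ deprived}_n \times \mathrm{population}_n}
       {\mathrm{population\ deprived}_{total}},
\qquad
\mathrm{share\ of\ excess}_n =
  \frac{(\mathrm{EF}_n - b_n)\,\mathrm{population}_n}
       {\mathrm{excess}_{total}},$$

with per-capita footprints $\mathrm{EF}_n$ and fair-share budgets $b_n$.
Whether under-budget clusters offset the total is not determined by the
formula alone; the default **clamp** policy zeroes negative excess before
totalling (shares are then proper proportions summing to one, matching the
non-negative published ranges), and the literal **signed** policy is kept as
an option. Both are exposed via `share_of_global_excess(..., clamp =)`.

The bundled registry ships order-of-magnitude stand-in values for the six
per-capita fair-share budgets (documented in the registry file itself);
users holding published downscaled budgets should edit them in. Cluster-level
published magnitudes that depend on external GNI/footprint data are
deliberately *not* reproduced — the tests pin the structural guarantees
instead (conservation, share-sum-to-one, and the affluence gradient).

## The synthetic world

The generator emulates the statistical structure the pipeline assumes, not
any particular country:

* **GNI and population** are lognormal (meanlog $\log 12000$, sdlog 1.3;
  meanlog $\log 5\times10^6$, sdlog 1.6) — heavy-tailed cross-country
  spreads of realistic magnitude.
* **Deprivation shares** follow
  $\mathrm{clip}(\alpha_c + \beta t + \mathrm{AR(1)}, 0, 100)$ with default
  slope $-0.5$ %pt/yr, $\rho = 0.5$, innovation sd 2, and country intercepts
  shifted down with standardized log GNI (gradient $-20$), so poorer
  countries sit deeper in shortfall. Clipping is a generator artifact of
  bounding shares and is documented as such.
* **Threshold indicators** generate native national rates lognormally around
  the registry threshold with a negative log-GNI gradient, so
  classification against thresholds is genuinely exercised.
* **Ecological series** are generated on the overshoot scale
  ($o_t = 0.3 + 0.025t + \mathrm{AR(1)}$, $\rho = 0.3$, sd 2 %pt — drift and
  level of the magnitude the global dashboard reports) and mapped back to
  native units by inverting the normalization, which exercises both the
  direct and inverted formulas end to end. The $\rho = 0.3$ default matches
  the residual autocorrelation regime the trend-inference guarantees are
  stated for.
* **Footprints** follow
  $b \cdot 0.8 \cdot (\mathrm{gni}/\mathrm{median})^{0.8} e^{\varepsilon}$,
  $\varepsilon \sim N(0, 0.3^2)$: a positive affluence elasticity guarantees
  the published qualitative gradient (richest cluster overshoots fair shares
  most, poorest least).

Everything is reproducible from one master seed, with per-component offsets
so tables are independent of generation order.

What passing on this world does **not** show: real indicator series have
reporting breaks, method revisions, and cross-indicator dependence that the
generator does not emulate; footprint data have structural (input–output)
uncertainty; and the AR(1) noise model is a deliberate simplification. The
statistical guarantees are about the estimators under their stated
assumptions, not about any specific published series.

## Numerical choices and degenerate inputs

* Degenerate boundary pairs ($x^\* = x_\mathrm{base}$, or a zero baseline in
  the inverted formula) raise typed errors; an empty averaging window yields
  a missing value with a coverage flag, not an error.
* A numerically exact fit (noise-free line or constant series) short-circuits
  the trend machinery: zero slope gives $p = 1$, a nonzero exact slope
  gives the machine-limit $p = 0$.
* Fewer than 4 observations yield an insufficient-data trend row.
* Cluster cut counts use epsilon guards so exact fractions (e.g. $N = 5$)
  stay exact in floating point.
* Radial wedges are linear in value (so wedge *area* grows quadratically —
  the documented perceptual caveat motivating the bar representation);
  ecological overshoot beyond the clip cap (150% of ring width by default)
  is truncated and flagged for a faded edge.

## Problem sizes

The Monte Carlo guarantees are verified in the test suite at 1,000
replicates (slope bias and CI coverage), 2,000 replicates (null rejection)
and 200 seeds (affluence gradient), with 399-replicate calibrated fits
inside the loops; pipeline tests use worlds of 30–150 countries. These sizes
give Monte Carlo standard errors well inside the asserted bands while
keeping the default test run fast.

## Known limitations

* The per-capita fair-share budgets bundled in the registry are synthetic
  stand-ins; cluster overshoot magnitudes are therefore only structurally
  meaningful out of the box.
* The Gender Inequality Index is a population-weighted score, not a
  headcount; it is treated as a percentage-like shortfall (flagged in the
  registry) because no rescaling rule is published.
* Trend inference assumes AR(1)-like residual dependence; strongly seasonal
  or long-memory errors would need a different calibration.
* Footprint time series, within-country disaggregation and cumulative
  historical attribution are out of scope.
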