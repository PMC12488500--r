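# doughnut

Monitoring social shortfall and ecological overshoot against the doughnut of
social and planetary boundaries.

The doughnut framework pictures a safe and just space for humanity between
two rings: a **social foundation** of minimum standards (energy, food,
health, education, political voice, ...) and an **ecological ceiling** of
planetary boundaries (climate, biosphere integrity, nutrient flows,
freshwater, ...). This package turns that picture into a reproducible
monitoring pipeline for researchers and practitioners who maintain such
dashboards:

* a validated, human-editable **registry** of 21 dimensions and 35
  indicators with boundaries, baselines, orientations and thresholds;
* **normalization** of raw indicator values into boundary-relative percent:
  social shortfall passes through (share of population in deprivation),
  ecological indicators are scaled by
  `overshoot = (x − x_base)/(x* − x_base) − 1` so the pre-industrial
  Holocene baseline is −100% and the boundary 0% (with the inverse framing
  for indicators where decline means degradation);
* autocorrelation-robust **linear trends** (`y = β₀ + β₁t`, OLS slope with a
  fixed-b Bartlett HAC standard error and a Monte-Carlo-calibrated null
  distribution suited to 23-point annual series);
* **elimination pathways**: the linear rate `−level/(horizon − 2022)` needed
  to reach zero shortfall by 2030 and zero overshoot by 2050, with
  acceleration factors versus history;
* **income clusters**: poorest 40% / middle 40% / richest 20% of countries
  by GNI per capita, population-weighted cluster aggregation, fair-share
  per-capita boundaries and attribution of global shortfall/excess shares;
* **doughnut and bar charts** (ggplot2), and a seeded **synthetic world
  generator** so everything above is testable offline.

## Worked example

Normalize the bundled published global levels and read off the dashboard
status:

```r
library(doughnut)
status <- published_status()
dplyr::filter(status, indicator_id %in% c("co2", "chemical_pollution",
                                          "ocean_acidification"))
#>   indicator_id        domain     period native_value   value within_boundary
#> 1 co2                 ecological start        370      28.6  FALSE
#> 2 co2                 ecological end          416      94.3  FALSE
#> 3 ocean_acidification ecological start          2.99  -34.6  TRUE
#> 4 ocean_acidification ecological end            2.8    -6.98 TRUE
#> 5 chemical_pollution  ecological start        933    1455    FALSE
#> 6 chemical_pollution  ecological end         1964    3173.   FALSE
```

CO₂ at 416 ppm sits 94% beyond the safe distance from the Holocene baseline
to the 350 ppm boundary; hazardous-chemicals production is more than thirty
times past its ceiling; ocean acidification is still (just) within its
boundary, with 7% of safe space left. The elimination pathway for the
health-coverage shortfall (28% of population in 2021–22, horizon 2030):

```r
elimination_rate(28, 2030)
#>   required_rate within_boundary
#> 1          -3.5 FALSE
```

i.e. shortfall must fall by 3.5 percentage points per year. A full pipeline
run on a synthetic world:

```r
w <- gen_world(world_config(n_countries = 60, seed = 42))
manifest <- run_all(w, out_dir = "out")
readr::read_csv("out/trends.csv")[1:6, c(1, 4, 5, 6, 7, 12)]
#>   indicator_id         beta1 se_beta1 p_value stars classification
#> 1 undernourishment    -0.443  0.0248   0.0035 *     improving
#> 2 food_insecurity     -0.478  0.0283   0.002  *     improving
#> 3 child_mortality     -0.201  0.0306   0.084        no_change
#> 4 health_coverage     -0.353  0.0271   0.0145       no_change
#> 5 illiteracy          -0.554  0.00910  0.0005 **    improving
#> 6 secondary_education -0.551  0.0228   0.0005 **    improving
```

`beta1` is the trend in percentage points of shortfall per year; stars mark
significance at the 1% (`*`) and 0.1% (`**`) levels under the calibrated
robust test; classification is directional only when significant. The
scenario table then reports, per indicator, the required rate and how many
times faster than history that is (`acceleration`), and
`doughnut_plot(...)` / `bar_panel(...)` draw the radial and bar views.

## Layout

* `R/` — registry, data IO, synthetic generator, normalization, trends,
  scenarios, clusters, visualization, pipeline.
* `inst/extdata/registry.yaml` — the editable indicator catalogue.
* `inst/extdata/global_levels.csv` — published period-average global levels.
* `inst/cli/doughnut.R` — thin command-line wrapper (`simulate`, `run`).
* `vignettes/doughnut-methods.Rmd` — models, assumptions, parameter
  defaults, numerical choices and limitations.
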