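#' Configuration of a synthetic world
#'
#' Defines the statistical structure of a generated "world" that mirrors the
#' inputs the monitoring pipeline consumes: a country panel of deprivation
#' shares and national rates with populations, global annual ecological
#' series, a GNI-per-capita table and a single-year footprint table with an
#' affluence gradient. Every stochastic component is driven by `seed` and an
#' AR(1) innovation process, so HAC-robust trend inference is exercised on
#' realistic serially correlated noise.
#'
#' Defaults (documented in the methods vignette): 193 countries over
#' 2000-2022; lognormal GNI (meanlog `log(12000)`, sdlog 1.3) and population
#' (meanlog `log(5e6)`, sdlog 1.6); country deprivation series with slope
#' -0.5 %pt per year, AR(1) rho 0.5, innovation sd 2 and a negative gradient
#' on log-GNI; global ecological overshoot drifting +2.5 %pt per year with
#' AR(1) rho 0.3 and innovation sd 2 %pt; footprints with affluence
#' elasticity 0.8 and lognormal noise sd 0.3.
#'
#' @param n_countries number of countries (>= 3).
#' @param years integer vector of panel years.
#' @param seed integer master seed.
#' @param gni_lognormal list `(meanlog, sdlog)` for GNI per capita.
#' @param population_lognormal list `(meanlog, sdlog)` for populations.
#' @param social list `(intercept, slope, rho, sigma, gni_gradient)` for
#'   weighted-share deprivation series; `gni_gradient` shifts country
#'   intercepts per standard deviation of log GNI (negative: richer countries
#'   have less deprivation).
#' @param threshold list `(spread, slope_rel, rho, sigma_rel, gni_gradient)`
#'   for native national rates behind country-threshold indicators, generated
#'   on the log scale around each indicator's registry threshold.
#' @param eco list `(start_overshoot, drift, rho, sigma)` for global
#'   ecological series, parameterized on the normalized overshoot scale
#'   (fractions; drift per year) and mapped back to native units through each
#'   indicator's boundary/baseline.
#' @param footprint list `(elasticity, sigma, level)`; per-capita footprints
#'   follow `level * boundary * (gni / median_gni)^elasticity * exp(noise)`.
#' @return validated configuration list of class `world_config`.
#' @export
world_config <- function(n_countries = 193,
                         years = 2000:2022,
                         seed = 1,
                         gni_lognormal = list(meanlog = log(12000), sdlog = 1.3),
                         population_lognormal = list(meanlog = log(5e6), sdlog = 1.6),
                         social = list(intercept = 50, slope = -0.5, rho = 0.5,
                                       sigma = 2, gni_gradient = -20),
                         threshold = list(spread = 0.6, slope_rel = -0.015,
                                          rho = 0.5, sigma_rel = 0.05,
                                          gni_gradient = -0.8),
                         eco = list(start_overshoot = 0.3, drift = 0.025,
                                    rho = 0.3, sigma = 0.02),
                         footprint = list(elasticity = 0.8, sigma = 0.3,
                                          level = 0.8)) {
  cfg <- list(
    n_countries = as.integer(n_countries), years = as.integer(years),
    seed = as.integer(seed), gni_lognormal = gni_lognormal,
    population_lognormal = population_lognormal, social = social,
    threshold = threshold, eco = eco, footprint = footprint
  )
  if (cfg$n_countries < 3) {
    abort_doughnut("n_countries must be at least 3", "doughnut_validation_error")
  }
  for (rho in c(cfg$social$rho, cfg$threshold$rho, cfg$eco$rho)) {
    if (abs(rho) >= 1) abort_doughnut("|rho| must be < 1", "doughnut_validation_error")
  }
  for (s in c(cfg$social$sigma, cfg$threshold$sigma_rel, cfg$eco$sigma, cfg$footprint$sigma)) {
    if (s < 0) abort_doughnut("sigma must be >= 0", "doughnut_validation_error")
  }
  class(cfg) <- "world_config"
  cfg
}

# AR(1) noise matrix (T x n), innovation sd `sigma`, stationary start
ar1_noise <- function(T, n, rho, sigma) {
  if (sigma == 0) return(matrix(0, T, n))
  E <- matrix(stats::rnorm(T * n, sd = sigma), T, n)
  if (abs(rho) > 1e-12) {
    E[1, ] <- E[1, ] / sqrt(1 - rho^2)
    if (T > 1) for (i in 2:T) E[i, ] <- rho * E[i - 1, ] + E[i, ]
  }
  E
}

#' Generate the GNI-per-capita table of a synthetic world
#' @param cfg a [world_config()].
#' @return tibble with `country_code`, `gni_per_capita`, `population`.
#' @export
gen_gni <- function(cfg) {
  withr::with_seed(cfg$seed, {
    tibble::tibble(
      country_code = sprintf("C%03d", seq_len(cfg$n_countries)),
      gni_per_capita = stats::rlnorm(cfg$n_countries,
                                     cfg$gni_lognormal$meanlog,
                                     cfg$gni_lognormal$sdlog),
      population = stats::rlnorm(cfg$n_countries,
                                 cfg$population_lognormal$meanlog,
                                 cfg$population_lognormal$sdlog)
    )
  })
}

#' Generate a synthetic country panel
#'
#' Weighted-share indicators follow
#' `value_t = clip(intercept_c + slope * t + AR(1) noise, 0, 100)` with the
#' country intercept shifted along standardized log GNI (poorer countries
#' start deeper in deprivation). Country-threshold indicators emit native
#' national rates generated on the log scale around the registry threshold,
#' so that classification against the threshold is exercised. Populations are
#' constant per country. Clipping to [0, 100] is a generator artifact of
#' bounding shares.
#'
#' @param cfg a [world_config()].
#' @param registry registry tibble (social indicators are generated).
#' @param gni optional GNI table from [gen_gni()]; generated if missing.
#' @return a validated country-panel tibble.
#' @export
gen_country_panel <- function(cfg, registry = default_registry(), gni = NULL) {
  gni <- gni %||% gen_gni(cfg)
  yrs <- cfg$years
  T <- length(yrs)
  n <- nrow(gni)
  z <- as.numeric(scale(log(gni$gni_per_capita)))
  soc <- registry[registry$domain == "social" & registry$has_data, ]
  withr::with_seed(cfg$seed + 1L, {
    purrr::map_dfr(seq_len(nrow(soc)), function(k) {
      spec <- soc[k, ]
      yr_keep <- yrs[yrs >= spec$start_year]
      if (!spec$has_timeseries) yr_keep <- max(yrs)
      tt <- matrix(rep(yr_keep - min(yrs), each = 1), nrow = length(yr_keep))
      if (spec$aggregation_mode == "weighted_share") {
        p <- cfg$social
        intercept_c <- p$intercept + p$gni_gradient * z
        noise <- ar1_noise(length(yr_keep), n, p$rho, p$sigma)
        vals <- outer(yr_keep - min(yrs), rep(p$slope, n)) +
          matrix(intercept_c, length(yr_keep), n, byrow = TRUE) + noise
        vals <- pmin(pmax(vals, 0), 100)
      } else {
        p <- cfg$threshold
        # deprivation is a high value for ">"-type thresholds and a low value
        # for "<"-type ones (e.g. a coverage index); flip the gradient and the
        # improvement drift accordingly
        dir <- if (spec$threshold_comparator %in% c("<", "<=")) -1 else 1
        base_c <- spec$threshold_value *
          exp(p$spread * stats::rnorm(n) + dir * p$gni_gradient * z)
        noise <- ar1_noise(length(yr_keep), n, p$rho, p$sigma_rel)
        vals <- matrix(base_c, length(yr_keep), n, byrow = TRUE) *
          exp(outer(yr_keep - min(yrs), rep(dir * p$slope_rel, n)) + noise)
      }
      tibble::tibble(
        country_code = rep(gni$country_code, each = length(yr_keep)),
        year = rep(yr_keep, times = n),
        indicator_id = spec$id,
        value = as.vector(vals),
        population = rep(gni$population, each = length(yr_keep))
      )
    }) |> as_country_panel()
  })
}

#' Generate synthetic global ecological series
#'
#' Each ecological indicator's overshoot path is generated as
#' `o_t = start_overshoot + drift * t + AR(1) noise` (fractions) and mapped
#' back to native units by inverting the orientation-appropriate
#' normalization, so direct indicators drift upward and inverted indicators
#' (forest, aragonite, ozone) decline in native units while their overshoot
#' worsens. Indicators without time series receive a single value in the
#' final year.
#'
#' @param cfg a [world_config()].
#' @param registry registry tibble (ecological indicators are generated).
#' @return a validated global-series tibble in native units.
#' @export
gen_global_series <- function(cfg, registry = default_registry()) {
  eco <- registry[registry$domain == "ecological", ]
  yrs <- cfg$years
  p <- cfg$eco
  withr::with_seed(cfg$seed + 2L, {
    purrr::map_dfr(seq_len(nrow(eco)), function(k) {
      spec <- eco[k, ]
      yr_keep <- if (spec$has_timeseries) yrs[yrs >= spec$start_year] else max(yrs)
      tt <- yr_keep - min(yrs)
      o <- p$start_overshoot + p$drift * tt +
        as.vector(ar1_noise(length(yr_keep), 1, p$rho, p$sigma))
      o <- pmax(o, -0.99)          # overshoot is bounded below by -1
      x <- if (spec$orientation == "direct") {
        (o + 1) * (spec$boundary - spec$baseline) + spec$baseline
      } else {
        spec$baseline * (1 - (o + 1) * (1 - spec$boundary / spec$baseline))
      }
      tibble::tibble(indicator_id = spec$id, year = yr_keep, value = x)
    }) |> as_global_series()
  })
}

#' Generate a synthetic footprint table
#'
#' Per-capita footprints follow a power law in affluence,
#' `ef = level * boundary * (gni / median_gni)^elasticity * exp(noise)`, so a
#' positive elasticity guarantees the affluence-footprint gradient (richer
#' country clusters overshoot fair-share budgets more).
#'
#' @param cfg a [world_config()].
#' @param gni GNI table from [gen_gni()] (supplies countries/populations).
#' @param registry registry tibble; its footprint indicators (those with a
#'   `per_capita_boundary`) are generated.
#' @return a validated footprint tibble.
#' @export
gen_footprint_table <- function(cfg, gni, registry = default_registry()) {
  fp_specs <- registry[!is.na(registry$per_capita_boundary), ]
  p <- cfg$footprint
  rel <- (gni$gni_per_capita / stats::median(gni$gni_per_capita))^p$elasticity
  withr::with_seed(cfg$seed + 3L, {
    purrr::map_dfr(seq_len(nrow(fp_specs)), function(k) {
      spec <- fp_specs[k, ]
      noise <- if (p$sigma > 0) exp(stats::rnorm(nrow(gni), sd = p$sigma)) else 1
      tibble::tibble(
        country_code = gni$country_code,
        footprint_id = spec$id,
        ef_per_capita = p$level * spec$per_capita_boundary * rel * noise,
        population = gni$population,
        per_capita_boundary = spec$per_capita_boundary
      )
    }) |> as_footprint_table()
  })
}

#' Generate a complete synthetic world
#'
#' Bundles [gen_gni()], [gen_country_panel()], [gen_global_series()] and
#' [gen_footprint_table()] with a consistent country set. Fully reproducible
#' under a fixed `cfg$seed` and independent of record ordering.
#'
#' @param cfg a [world_config()].
#' @param registry registry tibble.
#' @return list with elements `gni`, `panel`, `global_series`, `footprints`
#'   and `config`.
#' @export
gen_world <- function(cfg = world_config(), registry = default_registry()) {
  gni <- gen_gni(cfg)
  list(
    gni = gni,
    panel = gen_country_panel(cfg, registry, gni),
    global_series = gen_global_series(cfg, registry),
    footprints = gen_footprint_table(cfg, gni, registry),
    config = cfg
  )
}

#' Aggregate a country panel to global shortfall series
#'
#' Applies each social indicator's aggregation rule over all countries with
#' data, year by year: population-weighted mean share for weighted-share
#' indicators, population share in breaching countries for threshold
#' indicators. The result feeds [normalize_table()] (where it passes through
#' as percent).
#'
#' @param panel country-panel tibble.
#' @param registry registry tibble.
#' @return global-series tibble of shortfall percentages.
#' @export
aggregate_panel_global <- function(panel, registry) {
  soc <- registry[registry$domain == "social" & registry$has_data, ]
  purrr::map_dfr(seq_len(nrow(soc)), function(k) {
    spec <- soc[k, ]
    d <- panel[panel$indicator_id == spec$id, ]
    if (nrow(d) == 0) return(tibble::tibble())
    if (spec$aggregation_mode == "weighted_share") {
      out <- dplyr::summarise(
        dplyr::group_by(d, .data$year),
        value = sum(.data$value * .data$population) / sum(.data$population),
        .groups = "drop"
      )
    } else {
      breach <- comparator_fun(spec$threshold_comparator)(d$value, spec$threshold_value)
      d$dep <- d$population * as.numeric(breach)
      out <- dplyr::summarise(
        dplyr::group_by(d, .data$year),
        value = 100 * sum(.data$dep) / sum(.data$population),
        .groups = "drop"
      )
    }
    tibble::tibble(indicator_id = spec$id, year = out$year, value = out$value)
  })
}
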