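#' Run configuration
#'
#' Central configuration of a pipeline run: scenario horizons, significance
#' levels, cluster cut fractions, excess-attribution policy and the master
#' seed. Serializable to/from YAML via [read_run_config()].
#'
#' @param horizon_social social elimination horizon year.
#' @param horizon_eco ecological elimination horizon year.
#' @param ref_year reference year pathways start from (also the last year of
#'   the analysis period).
#' @param alpha significance level for a directional trend call.
#' @param cut_fractions income-percentile cut fractions for country clusters.
#' @param clamp excess-attribution policy (`"clamp"` or `"signed"`).
#' @param cluster_year reference year of the cluster disaggregation.
#' @param trend_method trend-inference method, see [fit_linear_trend()].
#' @param seed master seed.
#' @param plots render figures during [run_all()]?
#' @return validated configuration list of class `run_config`.
#' @export
run_config <- function(horizon_social = 2030, horizon_eco = 2050,
                       ref_year = 2022, alpha = 0.01,
                       cut_fractions = c(0.4, 0.8), clamp = "clamp",
                       cluster_year = 2017, trend_method = "fixedb_mc",
                       seed = 1, plots = FALSE) {
  if (horizon_social <= ref_year || horizon_eco <= ref_year) {
    abort_doughnut("horizons must lie after the reference year",
                   "doughnut_validation_error")
  }
  cfg <- list(
    horizon_social = horizon_social, horizon_eco = horizon_eco,
    ref_year = ref_year, alpha = alpha,
    cut_fractions = as.numeric(cut_fractions), clamp = clamp,
    cluster_year = cluster_year, trend_method = trend_method,
    seed = as.integer(seed), plots = isTRUE(plots)
  )
  # reuses the cluster validation for the fractions
  if (!(cfg$cut_fractions[1] > 0 && cfg$cut_fractions[2] > cfg$cut_fractions[1] &&
        cfg$cut_fractions[2] < 1)) {
    abort_doughnut("cut_fractions must be strictly increasing within (0, 1)",
                   "doughnut_validation_error")
  }
  class(cfg) <- "run_config"
  cfg
}

#' Run the full monitoring pipeline
#'
#' Executes normalize -> trends -> scenarios -> clusters (-> plots) on a world
#' (either a synthetic one from [gen_world()] or user tables of the same
#' shape), writes every output table under `out_dir` and returns a manifest
#' with a content hash per file. Identical inputs and config produce
#' byte-identical outputs.
#'
#' @param world list with elements `panel`, `global_series`, `footprints`,
#'   `gni` (see [gen_world()]); `footprints`/`gni` may be `NULL`, in which
#'   case the cluster stage errors if requested.
#' @param registry registry tibble.
#' @param config a [run_config()].
#' @param out_dir output directory.
#' @return tibble manifest (`file`, `md5`), invisibly; also attached as the
#'   `manifest.csv` output.
#' @export
run_all <- function(world, registry = default_registry(),
                    config = run_config(), out_dir = tempfile("doughnut-run-")) {
  if (is.null(world$panel) || is.null(world$global_series)) {
    abort_doughnut("world must provide panel and global_series tables",
                   "doughnut_validation_error")
  }
  social_global <- aggregate_panel_global(world$panel, registry)
  eco <- world$global_series[world$global_series$indicator_id %in%
                               registry$id[registry$domain == "ecological"], ]
  normalized <- normalize_table(dplyr::bind_rows(social_global, eco), registry)
  levels <- period_levels(normalized, registry, end_year = config$ref_year)
  trends <- trend_table(normalized, registry, seed = config$seed,
                        method = config$trend_method)
  scenarios <- scenario_table(levels, trends, registry,
                              horizon_social = config$horizon_social,
                              horizon_eco = config$horizon_eco,
                              ref_year = config$ref_year)
  if (is.null(world$gni)) {
    abort_doughnut("cluster stage requested but no GNI table supplied",
                   "doughnut_validation_error")
  }
  if (is.null(world$footprints)) {
    abort_doughnut("cluster stage requested but no footprint table supplied",
                   "doughnut_validation_error")
  }
  assignment <- assign_clusters(world$gni, config$cut_fractions)
  clusters <- cluster_table(world$panel, world$footprints, registry,
                            assignment, year = config$cluster_year,
                            clamp = config$clamp)
  tables <- list(
    normalized = normalized,
    period_levels = levels,
    trends = trends,
    scenarios = scenarios,
    cluster_assignment = assignment$assignment,
    cluster_table = clusters
  )
  acc <- attr(scenarios, "acceleration_summary")
  manifest <- write_results(tables, out_dir, summary = list(
    seed = config$seed,
    ref_year = config$ref_year,
    horizons = c(config$horizon_social, config$horizon_eco),
    acceleration_median = acc$median,
    acceleration_iqr = c(acc$q25, acc$q75),
    n_indicators = nrow(registry)
  ))
  if (config$plots) {
    end_vals <- levels[levels$period == "end", c("indicator_id", "value")]
    p <- doughnut_plot(end_vals, registry)
    pp <- file.path(out_dir, "doughnut.pdf")
    save_plot(p, pp)
    manifest <- dplyr::bind_rows(
      manifest, tibble::tibble(file = pp, md5 = unname(tools::md5sum(pp)))
    )
  }
  mp <- file.path(out_dir, "manifest.csv")
  readr::write_csv(manifest, mp, progress = FALSE)
  invisible(manifest)
}

#' Path to the bundled table of published global indicator levels
#'
#' Period-average global levels of every indicator (start of period 2000-2001
#' and end of period 2021-2022; ozone 2000-2004 and 2018-2022; late-start
#' indicators from their first window) in native units, as published for the
#' doughnut dashboard. Social values are shortfall percentages; ecological
#' values are raw indicator levels to be normalized against the registry
#' boundaries.
#'
#' @return path to the bundled CSV.
#' @export
global_levels_path <- function() {
  system.file("extdata", "global_levels.csv", package = "doughnut",
              mustWork = TRUE)
}

#' Load the bundled published global levels
#'
#' @return tibble with `indicator_id`, `period` (`start`/`end`), `value`.
#' @export
load_global_levels <- function() {
  readr::read_csv(global_levels_path(),
                  col_types = readr::cols(
                    indicator_id = readr::col_character(),
                    period = readr::col_character(),
                    value = readr::col_double()
                  ), progress = FALSE)
}

#' Normalized dashboard levels from the published global levels
#'
#' Applies the boundary normalization to the bundled published period-average
#' levels, reproducing the dashboard's status columns: social shortfall
#' passes through; ecological levels are normalized against the registry
#' boundary/baseline pairs.
#'
#' @param levels tibble from [load_global_levels()].
#' @param registry registry tibble.
#' @return tibble with `indicator_id`, `domain`, `period`, `native_value`,
#'   `value` (normalized percent) and `within_boundary`.
#' @export
published_status <- function(levels = load_global_levels(),
                             registry = default_registry()) {
  purrr::map_dfr(seq_len(nrow(levels)), function(k) {
    spec <- registry[registry$id == levels$indicator_id[k], ]
    if (nrow(spec) != 1) {
      abort_doughnut(paste0("unknown indicator: ", levels$indicator_id[k]),
                     "doughnut_validation_error")
    }
    norm <- normalize_series(
      tibble::tibble(year = NA_integer_, value = levels$value[k]), spec
    )
    tibble::tibble(
      indicator_id = spec$id, domain = spec$domain,
      period = levels$period[k], native_value = levels$value[k],
      value = norm$value, within_boundary = norm$within_boundary
    )
  })
}
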