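#' Assign countries to income clusters
#'
#' Ranks countries by mean GNI per capita and partitions them into the poorest
#' 40%, middle 40% and richest 20% of countries. The poorest block takes
#' `ceiling(f1 * N)` countries and the richest `floor((1 - f2) * N)`, with the
#' middle absorbing the remainder; for the 193 countries with income data this
#' reproduces the published 78/77/38 split. Ties across a cut are broken
#' deterministically by country code.
#'
#' @param gni tibble with columns `country_code` and `gni_per_capita`
#'   (period-mean GNI per capita, positive).
#' @param cut_fractions two strictly increasing fractions in (0, 1); the
#'   cumulative country-count fractions of the lower two clusters.
#' @return list with `assignment` (tibble `country_code`, `gni_per_capita`,
#'   `cluster`), `cut_points` (upper GNI bound of the two lower clusters) and
#'   `counts` (named integer vector).
#' @export
#' @examples
#' gni <- tibble::tibble(country_code = sprintf("C%02d", 1:5), gni_per_capita = 1:5)
#' assign_clusters(gni)$counts
assign_clusters <- function(gni, cut_fractions = c(0.4, 0.8)) {
  stopifnot(length(cut_fractions) == 2)
  if (!(cut_fractions[1] > 0 && cut_fractions[2] > cut_fractions[1] && cut_fractions[2] < 1)) {
    abort_doughnut("cut_fractions must be strictly increasing within (0, 1)",
                   "doughnut_validation_error")
  }
  n <- nrow(gni)
  if (n < 3) abort_doughnut("need at least 3 countries", "doughnut_validation_error")
  if (any(gni$gni_per_capita <= 0)) {
    abort_doughnut("GNI per capita must be positive", "doughnut_validation_error")
  }
  ord <- order(gni$gni_per_capita, gni$country_code)
  # epsilon guards keep exact fractions exact under floating point
  n_poor <- ceiling(cut_fractions[1] * n - 1e-9)
  n_rich <- floor((1 - cut_fractions[2]) * n + 1e-9)
  n_mid <- n - n_poor - n_rich
  cluster_levels <- c("poorest40", "middle40", "richest20")
  cl <- rep(cluster_levels, times = c(n_poor, n_mid, n_rich))
  assignment <- tibble::tibble(
    country_code = gni$country_code[ord],
    gni_per_capita = gni$gni_per_capita[ord],
    cluster = cl
  )
  counts <- c(poorest40 = n_poor, middle40 = n_mid, richest20 = n_rich)
  cut_points <- c(
    poor_mid = assignment$gni_per_capita[n_poor],
    mid_rich = assignment$gni_per_capita[n_poor + n_mid]
  )
  list(assignment = assignment, cut_points = cut_points, counts = counts)
}

comparator_fun <- function(comparator) {
  switch(comparator,
    "<" = `<`, "<=" = `<=`, ">" = `>`, ">=" = `>=`,
    abort_doughnut(paste0("unknown comparator: ", comparator), "doughnut_validation_error")
  )
}

#' Population-weighted social shortfall per cluster
#'
#' For weighted-share indicators: the population-weighted mean of national
#' deprivation shares over the cluster countries with data. For
#' country-threshold indicators: the share of the cluster population (with
#' data) living in countries breaching the registry threshold. Countries
#' lacking data for the indicator are excluded from both numerator and
#' denominator.
#'
#' @param panel country-panel tibble.
#' @param spec one-row registry tibble of a social indicator.
#' @param assignment cluster assignment from [assign_clusters()].
#' @param year reference year.
#' @return tibble with `cluster`, `share_deprived` (%), `population`
#'   (cluster population with data), `n_countries`. Clusters with no data are
#'   omitted.
#' @export
cluster_social_share <- function(panel, spec, assignment, year) {
  stopifnot(nrow(spec) == 1, spec$domain == "social")
  d <- panel[panel$indicator_id == spec$id & panel$year == year, ]
  d <- dplyr::inner_join(d, assignment$assignment[c("country_code", "cluster")],
                         by = "country_code")
  if (nrow(d) == 0) {
    return(tibble::tibble(cluster = character(), share_deprived = numeric(),
                          population = numeric(), n_countries = integer()))
  }
  if (spec$aggregation_mode == "weighted_share") {
    out <- dplyr::summarise(
      dplyr::group_by(d, .data$cluster),
      share_deprived = sum(.data$value * .data$population) / sum(.data$population),
      population = sum(.data$population),
      n_countries = dplyr::n(),
      .groups = "drop"
    )
  } else {
    breach <- comparator_fun(spec$threshold_comparator)(d$value, spec$threshold_value)
    d$deprived_pop <- d$population * as.numeric(breach)
    out <- dplyr::summarise(
      dplyr::group_by(d, .data$cluster),
      share_deprived = 100 * sum(.data$deprived_pop) / sum(.data$population),
      population = sum(.data$population),
      n_countries = dplyr::n(),
      .groups = "drop"
    )
  }
  dplyr::arrange(out, match(.data$cluster, c("poorest40", "middle40", "richest20")))
}

#' Population-weighted per-capita footprint per cluster
#'
#' @param fps footprint tibble (see [read_footprint_table()]).
#' @param assignment cluster assignment from [assign_clusters()].
#' @return tibble with `footprint_id`, `cluster`, `ef_per_capita`
#'   (population-weighted mean), `per_capita_boundary`, `population`.
#' @export
cluster_footprint <- function(fps, assignment) {
  d <- dplyr::inner_join(fps, assignment$assignment[c("country_code", "cluster")],
                         by = "country_code")
  out <- dplyr::summarise(
    dplyr::group_by(d, .data$footprint_id, .data$cluster),
    ef_per_capita = sum(.data$ef_per_capita * .data$population) / sum(.data$population),
    per_capita_boundary = unique(.data$per_capita_boundary)[1],
    population = sum(.data$population),
    .groups = "drop"
  )
  dplyr::arrange(out, .data$footprint_id,
                 match(.data$cluster, c("poorest40", "middle40", "richest20")))
}

#' Overshoot of a per-capita footprint beyond its fair-share boundary
#'
#' Same normalization as the global ecological ceiling with a zero baseline:
#' `(ef / boundary - 1) * 100`, bounded below by -100%.
#'
#' @param ef_per_capita per-capita footprint.
#' @param per_capita_boundary equality-based per-capita budget (> 0).
#' @return overshoot in percent.
#' @export
cluster_overshoot <- function(ef_per_capita, per_capita_boundary) {
  100 * overshoot_direct(ef_per_capita, per_capita_boundary, 0)
}

#' Cluster shares of global social shortfall
#'
#' Each cluster's deprived population (share deprived times population) as a
#' proportion of the total deprived population across clusters.
#'
#' @param shares tibble from [cluster_social_share()].
#' @return the input with `deprived_population` and `share_of_global_shortfall`
#'   added; shares sum to 1. If no one is deprived, shares are all zero and
#'   the attribute `no_shortfall` is `TRUE`.
#' @export
share_of_global_shortfall <- function(shares) {
  shares$deprived_population <- shares$share_deprived / 100 * shares$population
  total <- sum(shares$deprived_population)
  if (total <= 0) {
    shares$share_of_global_shortfall <- 0
    attr(shares, "no_shortfall") <- TRUE
  } else {
    shares$share_of_global_shortfall <- shares$deprived_population / total
  }
  shares
}

#' Cluster shares of global excess footprint
#'
#' Each cluster's footprint beyond its equality-based budget,
#' `(ef_per_capita - boundary) * population`, as a proportion of the summed
#' excess. Under the default `clamp` policy, clusters within their budget
#' contribute zero (negative excess is clamped before totalling), so shares
#' lie in `[0, 1]` and sum to 1. The `signed` policy applies the attribution
#' formula literally, so under-budget clusters carry negative shares.
#'
#' @param cfp tibble from [cluster_footprint()], one footprint at a time or
#'   several (grouped by `footprint_id`).
#' @param clamp `"clamp"` (default) or `"signed"`.
#' @return input with `excess`, `share_of_global_excess` and `within_boundary`
#'   columns; for a footprint with no cluster above its boundary the shares
#'   are `NA` and `within_boundary` is `TRUE` for all its rows.
#' @export
share_of_global_excess <- function(cfp, clamp = c("clamp", "signed")) {
  clamp <- match.arg(clamp)
  purrr::map_dfr(split(cfp, cfp$footprint_id), function(d) {
    raw <- (d$ef_per_capita - d$per_capita_boundary) * d$population
    d$excess <- if (clamp == "clamp") pmax(raw, 0) else raw
    if (all(raw <= 0)) {
      d$share_of_global_excess <- NA_real_
      d$within_boundary <- TRUE
    } else {
      d$share_of_global_excess <- d$excess / sum(d$excess)
      d$within_boundary <- raw <= 0
    }
    d
  })
}

#' Full cluster table for one reference year
#'
#' Joins the social and ecological cluster aggregates into the dashboard's
#' cluster table: per-cluster population, deprivation share and share of
#' global shortfall for every social indicator, and per-capita footprint,
#' fair-share overshoot and share of global excess for every footprint
#' indicator.
#'
#' @param panel country-panel tibble.
#' @param fps footprint tibble.
#' @param registry registry tibble.
#' @param assignment cluster assignment from [assign_clusters()].
#' @param year reference year for the social indicators.
#' @param clamp excess-attribution policy, see [share_of_global_excess()].
#' @return tibble with one row per (indicator, cluster).
#' @export
cluster_table <- function(panel, fps, registry, assignment, year = 2017,
                          clamp = "clamp") {
  soc_specs <- registry[registry$domain == "social" & registry$has_data, ]
  soc <- purrr::map_dfr(seq_len(nrow(soc_specs)), function(k) {
    spec <- soc_specs[k, ]
    s <- cluster_social_share(panel, spec, assignment, year)
    if (nrow(s) == 0) return(tibble::tibble())
    s <- share_of_global_shortfall(s)
    dplyr::bind_cols(tibble::tibble(indicator_id = spec$id, domain = "social"), s)
  })
  eco <- tibble::tibble()
  if (!is.null(fps) && nrow(fps)) {
    cf <- cluster_footprint(fps, assignment)
    cf <- share_of_global_excess(cf, clamp = clamp)
    cf$cluster_overshoot <- cluster_overshoot(cf$ef_per_capita, cf$per_capita_boundary)
    eco <- dplyr::bind_cols(
      tibble::tibble(indicator_id = cf$footprint_id, domain = "ecological"),
      cf[setdiff(names(cf), "footprint_id")]
    )
  }
  dplyr::bind_rows(soc, eco)
}
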