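#' Linear elimination rate to a horizon year
#'
#' The annual linear rate of change (in %pt per year) needed to bring a
#' current shortfall/overshoot level to zero by `end_year`:
#' `-current_level / (end_year - ref_year)`. An ecological indicator already
#' at or below its boundary (level <= 0) needs no pathway; it returns 0 and is
#' flagged `within_boundary`.
#'
#' @param current_level current normalized level in percent (the end-of-period
#'   average by convention).
#' @param end_year horizon year (2030 for social, 2050 for ecological).
#' @param ref_year reference year the pathway starts from.
#' @param domain `"social"` or `"ecological"`.
#' @return tibble with `required_rate` (%pt per year, negative = reduction)
#'   and `within_boundary`.
#' @export
#' @examples
#' elimination_rate(28, 2030) # -3.5 %pt per year
elimination_rate <- function(current_level, end_year, ref_year = 2022,
                             domain = "social") {
  if (any(end_year <= ref_year)) {
    abort_doughnut("end_year must be after ref_year", "doughnut_validation_error")
  }
  wb <- domain == "ecological" & !is.na(current_level) & current_level <= 0
  rate <- -current_level / (end_year - ref_year)
  rate[wb] <- 0
  tibble::tibble(required_rate = rate, within_boundary = wb)
}

#' Acceleration factor of a required rate over the historical trend
#'
#' How many times faster than the 2000-2022 historical trend an indicator
#' would need to improve to meet its elimination pathway. Defined only for
#' statistically significant improving trends (`|required| / |historical|`);
#' a significantly worsening trend must stop and accelerate in reverse
#' (`reverse_required`), and indicators without a significant or known trend
#' carry their trend flag instead of a number.
#'
#' @param required_rate required %pt-per-year rate from [elimination_rate()].
#' @param beta1 historical slope (%pt per year).
#' @param classification trend classification from [classify_trend()].
#' @return tibble with `acceleration` (numeric or `NA`) and `status`
#'   (`improving`, `reverse_required`, `no_change`, `not_known`, `no_data`,
#'   `within_boundary`).
#' @export
acceleration_factor <- function(required_rate, beta1, classification) {
  status <- dplyr::case_when(
    classification == "worsening" ~ "reverse_required",
    TRUE ~ classification
  )
  acc <- ifelse(classification == "improving" & !is.na(beta1) & beta1 != 0,
                abs(required_rate) / abs(beta1), NA_real_)
  tibble::tibble(acceleration = acc, status = status)
}

#' Scenario table: elimination pathways for every indicator
#'
#' Combines end-of-period levels and historical trends into one pathway row
#' per registry indicator: the level the pathway starts from, the horizon, the
#' required linear rate and the acceleration factor versus history. The
#' summary attribute `acceleration_summary` holds the median and interquartile
#' range of acceleration factors across significantly improving social
#' indicators.
#'
#' @param levels period-levels tibble from [period_levels()] (rows with
#'   `period == "end"` are used).
#' @param trends trend tibble from [trend_table()].
#' @param registry registry tibble.
#' @param horizon_social social elimination horizon year.
#' @param horizon_eco ecological elimination horizon year.
#' @param ref_year year the pathways start from.
#' @return tibble, one row per registry indicator, with attribute
#'   `acceleration_summary`.
#' @export
scenario_table <- function(levels, trends, registry, horizon_social = 2030,
                           horizon_eco = 2050, ref_year = 2022) {
  if (nrow(registry) == 0) {
    return(tibble::tibble())
  }
  end_levels <- levels[levels$period == "end", c("indicator_id", "value")]
  out <- purrr::map_dfr(seq_len(nrow(registry)), function(k) {
    spec <- registry[k, ]
    lvl <- end_levels$value[match(spec$id, end_levels$indicator_id)]
    horizon <- if (spec$domain == "social") horizon_social else horizon_eco
    tr <- trends[trends$indicator_id == spec$id, ]
    cls <- if (nrow(tr)) tr$classification else "no_data"
    b1 <- if (nrow(tr)) tr$beta1 else NA_real_
    if (length(lvl) == 0 || is.na(lvl)) {
      return(tibble::tibble(
        indicator_id = spec$id, domain = spec$domain, current_level = NA_real_,
        horizon_year = horizon, horizon_years = horizon - ref_year,
        required_rate = NA_real_, acceleration = NA_real_, status = "no_data"
      ))
    }
    er <- elimination_rate(lvl, horizon, ref_year, spec$domain)
    af <- acceleration_factor(er$required_rate, b1, cls)
    status <- if (er$within_boundary) "within_boundary" else af$status
    tibble::tibble(
      indicator_id = spec$id, domain = spec$domain, current_level = lvl,
      horizon_year = horizon, horizon_years = horizon - ref_year,
      required_rate = er$required_rate,
      acceleration = if (er$within_boundary) NA_real_ else af$acceleration,
      status = status
    )
  })
  acc <- out$acceleration[out$domain == "social" & out$status == "improving" &
                            !is.na(out$acceleration)]
  attr(out, "acceleration_summary") <- tibble::tibble(
    n = length(acc),
    median = if (length(acc)) stats::median(acc) else NA_real_,
    q25 = if (length(acc)) unname(stats::quantile(acc, 0.25)) else NA_real_,
    q75 = if (length(acc)) unname(stats::quantile(acc, 0.75)) else NA_real_
  )
  out
}
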