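#' Boundary-normalized ecological overshoot (direct framing)
#'
#' Scales an ecological indicator against its planetary boundary so that the
#' pre-industrial Holocene baseline maps to -1 and the boundary to 0:
#' `(x - x_base) / (x_star - x_base) - 1`. A positive result is the fraction
#' by which the safe distance from baseline to boundary has been exceeded;
#' results are unbounded above and bounded below by -1.
#'
#' @param x indicator value in native units.
#' @param x_star planetary boundary in native units.
#' @param x_base pre-industrial Holocene baseline in native units.
#' @return overshoot as a fraction (multiply by 100 for percent).
#' @seealso [overshoot_inverted()] for indicators where a *decrease* signals
#'   degradation.
#' @export
#' @examples
#' overshoot_direct(416, 350, 280) # 0.9429 -> printed as 94%
overshoot_direct <- function(x, x_star, x_base) {
  if (any(x_star == x_base)) {
    abort_doughnut("degenerate boundary: x_star equals x_base", "doughnut_degenerate_error")
  }
  (x - x_base) / (x_star - x_base) - 1
}

#' Boundary-normalized ecological overshoot (inverted framing)
#'
#' For indicators framed inversely (aragonite saturation, forest area,
#' stratospheric ozone) a *decrease* in the native value implies worsening
#' conditions. Overshoot is expressed in comparable terms via
#' `(1 - x / x_base) / (1 - x_star / x_base) - 1`, which is strictly
#' decreasing in `x`. Algebraically this equals
#' `overshoot_direct(x_base - x, x_base - x_star, 0)`.
#'
#' @inheritParams overshoot_direct
#' @return overshoot as a fraction.
#' @export
#' @examples
#' overshoot_inverted(38, 48, 64) # forest area, 0.625
overshoot_inverted <- function(x, x_star, x_base) {
  if (any(x_base == 0)) {
    abort_doughnut("degenerate baseline: x_base is zero", "doughnut_degenerate_error")
  }
  if (any(x_star == x_base)) {
    abort_doughnut("degenerate boundary: x_star equals x_base", "doughnut_degenerate_error")
  }
  (1 - x / x_base) / (1 - x_star / x_base) - 1
}

#' Period average of a sparse annual series
#'
#' Arithmetic mean of the observations available inside a year window,
#' recording how many years contributed. Reported dashboard levels are 2-year
#' averages (5-year for stratospheric ozone, owing to high annual
#' variability); an empty window yields a missing value, not an error.
#'
#' @param years integer vector of observation years.
#' @param values numeric vector of observations, same length as `years`.
#' @param window integer vector of years defining the window (e.g.
#'   `2021:2022`).
#' @return tibble with one row: `value` (mean or `NA`), `n_years` (years that
#'   contributed), `window_years` (window length).
#' @export
#' @examples
#' period_average(c(2021, 2022), c(10, 12), 2021:2022)
period_average <- function(years, values, window) {
  stopifnot(length(years) == length(values))
  inside <- years %in% window
  n <- sum(inside)
  tibble::tibble(
    value = if (n > 0) mean(values[inside]) else NA_real_,
    n_years = as.integer(n),
    window_years = length(window)
  )
}

#' Normalize a raw indicator series to shortfall/overshoot percent
#'
#' Social series pass through unchanged (they already are the percentage of
#' population below the minimum standard, 0-100). Ecological series are
#' normalized per year with the orientation-appropriate boundary formula and
#' expressed in percent, retaining within-boundary values as negative
#' percentages (flagged, not clipped).
#'
#' @param series tibble with columns `year`, `value` for one indicator.
#' @param spec one-row registry tibble for the matching indicator.
#' @return tibble with columns `indicator_id`, `year`, `value` (percent) and
#'   `within_boundary`.
#' @export
normalize_series <- function(series, spec) {
  stopifnot(nrow(spec) == 1)
  if (spec$domain == "social") {
    if (any(series$value < 0 | series$value > 100)) {
      abort_doughnut(
        paste0("social shortfall outside [0, 100] for ", spec$id),
        "doughnut_validation_error"
      )
    }
    pct <- series$value
  } else {
    frac <- switch(spec$orientation,
      direct = overshoot_direct(series$value, spec$boundary, spec$baseline),
      inverted = overshoot_inverted(series$value, spec$boundary, spec$baseline),
      abort_doughnut(paste0("unknown orientation for ", spec$id), "doughnut_validation_error")
    )
    pct <- 100 * frac
  }
  tibble::tibble(
    indicator_id = spec$id,
    year = series$year,
    value = pct,
    within_boundary = pct <= 0
  )
}

#' Normalize every series in a global collection
#'
#' @param series a global-series tibble (see [read_global_series()]) holding
#'   raw values in native units; social rows are treated as percentages.
#' @param registry a registry tibble.
#' @return tibble of normalized series (percent), one row per indicator-year.
#' @export
normalize_table <- function(series, registry) {
  ids <- unique(series$indicator_id)
  unknown <- setdiff(ids, registry$id)
  if (length(unknown)) {
    abort_doughnut(
      paste0("series for unknown indicator(s): ", paste(unknown, collapse = ", ")),
      "doughnut_validation_error"
    )
  }
  purrr::map_dfr(ids, function(i) {
    normalize_series(series[series$indicator_id == i, ], registry[registry$id == i, ])
  })
}

#' Period-averaged normalized levels for the dashboard
#'
#' Computes start-of-period and end-of-period levels for every indicator in a
#' normalized table, honouring each indicator's averaging window (2 years by
#' default, 5 for ozone) and late start years.
#'
#' @param normalized tibble from [normalize_table()].
#' @param registry registry tibble.
#' @param end_year final year of the analysis period.
#' @return tibble with `indicator_id`, `period` (`start`/`end`), `value`,
#'   `n_years`.
#' @export
period_levels <- function(normalized, registry, end_year = 2022) {
  purrr::map_dfr(unique(normalized$indicator_id), function(i) {
    spec <- registry[registry$id == i, ]
    s <- normalized[normalized$indicator_id == i, ]
    w <- spec$averaging_window_years
    windows <- list(
      start = spec$start_year + 0:(w - 1),
      end = (end_year - w + 1):end_year
    )
    purrr::imap_dfr(windows, function(win, nm) {
      pa <- period_average(s$year, s$value, win)
      tibble::tibble(indicator_id = i, period = nm, value = pa$value, n_years = pa$n_years)
    })
  })
}
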