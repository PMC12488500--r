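#' Tidy interchange formats
#'
#' All stages exchange tidy (long) CSV tables; wide tables are view-only
#' exports. Missing data is encoded by row absence, never by sentinel values,
#' because coverage is sparse and indicator-specific. Countries are identified
#' by ISO 3166-1 alpha-3 codes only.
#'
#' Three table families are used:
#' \describe{
#'   \item{global series}{`indicator_id`, `year`, `value` - annual global
#'     values in native units, possibly sparse.}
#'   \item{country panel}{`country_code`, `year`, `indicator_id`, `value`,
#'     `population` - national deprivation shares (weighted-share indicators)
#'     or native national rates (threshold indicators).}
#'   \item{footprint table}{`country_code`, `footprint_id`, `ef_per_capita`,
#'     `population`, `per_capita_boundary` - single-reference-year
#'     consumption-based footprints with equality-based per-person budgets.}
#' }
#'
#' @name data_io
NULL

read_csv_strict <- function(path, col_types) {
  if (!file.exists(path)) {
    abort_doughnut(paste0("file not found: ", path), "doughnut_io_error")
  }
  df <- suppressWarnings(readr::read_csv(path, col_types = col_types, progress = FALSE))
  expected <- names(col_types$cols)
  missing <- setdiff(expected, names(df))
  if (length(missing)) {
    abort_doughnut(
      paste0("missing column(s) in ", basename(path), ": ", paste(missing, collapse = ", ")),
      "doughnut_parse_error"
    )
  }
  probs <- readr::problems(df)
  if (nrow(probs)) {
    abort_doughnut(
      paste0(
        "non-numeric or malformed value(s) in ", basename(path), " at row(s): ",
        paste(utils::head(probs$row, 5), collapse = ", ")
      ),
      "doughnut_parse_error"
    )
  }
  df
}

check_unique <- function(df, keys, what) {
  dup <- duplicated(df[keys])
  if (any(dup)) {
    abort_doughnut(
      paste0("duplicate ", what, " key(s) at row(s): ",
             paste(utils::head(which(dup), 5), collapse = ", ")),
      "doughnut_parse_error"
    )
  }
  invisible(df)
}

#' Validate a global-series table
#' @param df data frame with columns `indicator_id`, `year`, `value`.
#' @return the validated tibble.
#' @export
as_global_series <- function(df) {
  df <- tibble::as_tibble(df)[c("indicator_id", "year", "value")]
  check_unique(df, c("indicator_id", "year"), "(indicator, year)")
  if (!all(is.finite(df$value))) {
    abort_doughnut("non-finite value(s) in global series", "doughnut_parse_error")
  }
  dplyr::arrange(df, .data$indicator_id, .data$year)
}

#' Validate a country-panel table
#' @param df data frame with columns `country_code`, `year`, `indicator_id`,
#'   `value`, `population`.
#' @return the validated tibble.
#' @export
as_country_panel <- function(df) {
  df <- tibble::as_tibble(df)[c("country_code", "year", "indicator_id", "value", "population")]
  check_unique(df, c("country_code", "year", "indicator_id"), "(country, year, indicator)")
  if (any(df$population <= 0 | !is.finite(df$population))) {
    abort_doughnut("population must be a positive finite number", "doughnut_parse_error")
  }
  if (!all(is.finite(df$value))) {
    abort_doughnut("non-finite value(s) in country panel", "doughnut_parse_error")
  }
  dplyr::arrange(df, .data$indicator_id, .data$country_code, .data$year)
}

#' Validate a footprint table
#' @param df data frame with columns `country_code`, `footprint_id`,
#'   `ef_per_capita`, `population`, `per_capita_boundary`.
#' @return the validated tibble.
#' @export
as_footprint_table <- function(df) {
  df <- tibble::as_tibble(df)[c("country_code", "footprint_id", "ef_per_capita",
                                "population", "per_capita_boundary")]
  check_unique(df, c("country_code", "footprint_id"), "(country, footprint)")
  if (any(df$ef_per_capita < 0 | !is.finite(df$ef_per_capita))) {
    abort_doughnut("ef_per_capita must be non-negative and finite", "doughnut_parse_error")
  }
  if (any(df$per_capita_boundary <= 0)) {
    abort_doughnut("per_capita_boundary must be positive", "doughnut_parse_error")
  }
  if (any(df$population <= 0)) {
    abort_doughnut("population must be positive", "doughnut_parse_error")
  }
  dplyr::arrange(df, .data$footprint_id, .data$country_code)
}

#' @rdname data_io
#' @param path CSV path (UTF-8, header row, '.' decimal separator).
#' @return `read_global_series()`: a validated global-series tibble.
#' @export
read_global_series <- function(path) {
  df <- read_csv_strict(path, readr::cols(
    indicator_id = readr::col_character(),
    year = readr::col_integer(),
    value = readr::col_double()
  ))
  as_global_series(df)
}

#' @rdname data_io
#' @return `read_country_panel()`: a validated country-panel tibble.
#' @export
read_country_panel <- function(path) {
  df <- read_csv_strict(path, readr::cols(
    country_code = readr::col_character(),
    year = readr::col_integer(),
    indicator_id = readr::col_character(),
    value = readr::col_double(),
    population = readr::col_double()
  ))
  as_country_panel(df)
}

#' @rdname data_io
#' @return `read_footprint_table()`: a validated footprint tibble.
#' @export
read_footprint_table <- function(path) {
  df <- read_csv_strict(path, readr::cols(
    country_code = readr::col_character(),
    footprint_id = readr::col_character(),
    ef_per_capita = readr::col_double(),
    population = readr::col_double(),
    per_capita_boundary = readr::col_double()
  ))
  as_footprint_table(df)
}

#' Write result tables deterministically
#'
#' Writes every table in `tables` as a tidy CSV under `out_dir` plus a JSON
#' run summary, and returns a manifest with a content hash per file. Output is
#' byte-stable for identical inputs: rows are written in their (already
#' deterministic) order, floats with full precision, keys sorted in the JSON
#' summary.
#'
#' @param tables named list of data frames.
#' @param out_dir output directory (created if needed).
#' @param summary optional named list added to the JSON run summary.
#' @return tibble manifest with columns `file`, `md5`.
#' @export
write_results <- function(tables, out_dir, summary = list()) {
  stopifnot(is.list(tables), all(nzchar(names(tables))))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  for (nm in names(tables)) {
    p <- file.path(out_dir, paste0(nm, ".csv"))
    readr::write_csv(tables[[nm]], p, progress = FALSE)
    paths <- c(paths, p)
  }
  summary <- c(summary, list(tables = sort(names(tables))))
  sp <- file.path(out_dir, "run_summary.json")
  jsonlite::write_json(summary[order(names(summary))], sp, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  paths <- c(paths, sp)
  tibble::tibble(file = paths, md5 = unname(tools::md5sum(paths)))
}

#' Read a run-configuration YAML file
#'
#' Missing keys fall back to [run_config()] defaults.
#'
#' @param path YAML file.
#' @return a validated run-configuration list.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) {
    abort_doughnut(paste0("config file not found: ", path), "doughnut_io_error")
  }
  do.call(run_config, yaml::read_yaml(path))
}
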