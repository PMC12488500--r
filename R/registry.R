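#' The indicator registry
#'
#' The registry is the catalogue of dimensions and indicators that defines the
#' doughnut dashboard: 12 social-foundation dimensions carrying 22 deprivation
#' indicators and 9 ecological-ceiling dimensions carrying 13 planetary-boundary
#' indicators. It is shipped as a human-editable YAML file (the framework is
#' revised annually, so the catalogue is data, not code) and loaded into a
#' tibble with one row per indicator.
#'
#' Columns: `id`, `name`, `dimension`, `domain` (`social`/`ecological`),
#' `unit`, `orientation` (`direct`/`inverted`, ecological only), `boundary`,
#' `baseline`, `averaging_window_years`, `start_year`, `aggregation_mode`
#' (`weighted_share`/`country_threshold`, social only), `threshold_value`,
#' `threshold_comparator`, `per_capita_boundary`, `per_capita_unit`,
#' `has_timeseries`, `has_data`, `notes`.
#'
#' @param path path to a registry YAML file.
#' @return a tibble of validated indicator specifications, class
#'   `doughnut_registry`.
#' @export
#' @examples
#' reg <- default_registry()
#' table(reg$domain)
load_registry <- function(path) {
  if (!file.exists(path)) {
    abort_doughnut(paste0("registry file not found: ", path), "doughnut_io_error")
  }
  raw <- yaml::read_yaml(path)
  if (!length(raw)) abort_doughnut("registry file is empty", "doughnut_validation_error")
  specs <- purrr::map_dfr(raw, registry_row)
  report <- validate_registry(specs)
  if (!all(report$pass)) {
    bad <- report[!report$pass, ]
    abort_doughnut(
      paste0(
        "invalid registry:\n",
        paste0("- [", bad$check, "] ", bad$detail, collapse = "\n")
      ),
      "doughnut_validation_error"
    )
  }
  class(specs) <- c("doughnut_registry", class(specs))
  specs
}

# one YAML record -> one tibble row with full schema
registry_row <- function(rec) {
  get_chr <- function(f) as.character(rec[[f]] %||% NA_character_)
  get_num <- function(f) as.numeric(rec[[f]] %||% NA_real_)
  tibble::tibble(
    id = get_chr("id"),
    name = get_chr("name"),
    dimension = get_chr("dimension"),
    domain = get_chr("domain"),
    unit = get_chr("unit"),
    orientation = get_chr("orientation"),
    boundary = get_num("boundary"),
    baseline = get_num("baseline"),
    averaging_window_years = as.integer(rec$averaging_window_years %||% 2L),
    start_year = as.integer(rec$start_year %||% 2000L),
    aggregation_mode = get_chr("aggregation_mode"),
    threshold_value = get_num("threshold_value"),
    threshold_comparator = get_chr("threshold_comparator"),
    per_capita_boundary = get_num("per_capita_boundary"),
    per_capita_unit = get_chr("per_capita_unit"),
    has_timeseries = isTRUE(rec$has_timeseries %||% TRUE),
    has_data = isTRUE(rec$has_data %||% TRUE),
    notes = get_chr("notes")
  )
}

#' Path to the bundled default registry
#' @return path to the YAML registry shipped with the package.
#' @export
registry_path <- function() {
  system.file("extdata", "registry.yaml", package = "doughnut", mustWork = TRUE)
}

#' Load the bundled default registry
#' @return the default `doughnut_registry` tibble (35 indicators).
#' @export
default_registry <- function() {
  load_registry(registry_path())
}

#' Validate a registry against its structural invariants
#'
#' Report-only companion of [load_registry()]: every invariant is checked and
#' returned as one row, never raised. Checks include unique ids, known domain
#' and orientation labels, boundary/baseline ordering (direct indicators above
#' a positive distance from baseline, inverted indicators below a strictly
#' positive baseline), at most two indicators per dimension, and the
#' social/ecological field exclusivity rules.
#'
#' @param specs a registry tibble as returned by [load_registry()].
#' @return tibble with columns `check`, `pass`, `detail`.
#' @export
validate_registry <- function(specs) {
  checks <- list()
  add <- function(check, pass, detail = "") {
    checks[[length(checks) + 1]] <<- tibble::tibble(
      check = check, pass = pass, detail = detail
    )
  }

  dup <- specs$id[duplicated(specs$id)]
  add("unique_id", length(dup) == 0,
      if (length(dup)) paste("duplicate id:", paste(unique(dup), collapse = ", ")) else "")

  bad_dom <- setdiff(unique(specs$domain), c("social", "ecological"))
  add("domain_label", length(bad_dom) == 0,
      if (length(bad_dom)) paste("unknown domain:", paste(bad_dom, collapse = ", ")) else "")

  eco <- specs[specs$domain == "ecological", ]
  soc <- specs[specs$domain == "social", ]

  bad_orient <- eco$id[!eco$orientation %in% c("direct", "inverted")]
  add("orientation_label", length(bad_orient) == 0,
      if (length(bad_orient)) paste("field orientation invalid for:", paste(bad_orient, collapse = ", ")) else "")

  dir <- eco[eco$orientation %in% "direct", ]
  bad <- dir$id[!(dir$boundary > dir$baseline)]
  add("direct_boundary_above_baseline", length(bad) == 0,
      if (length(bad)) paste("field boundary must exceed baseline for direct indicators:", paste(bad, collapse = ", ")) else "")

  inv <- eco[eco$orientation %in% "inverted", ]
  bad <- inv$id[!(inv$boundary < inv$baseline & inv$baseline > 0)]
  add("inverted_boundary_below_baseline", length(bad) == 0,
      if (length(bad)) paste("field boundary/baseline invalid for inverted indicators:", paste(bad, collapse = ", ")) else "")

  per_dim <- table(specs$dimension)
  crowded <- names(per_dim)[per_dim > 2]
  add("max_two_indicators_per_dimension", length(crowded) == 0,
      if (length(crowded)) paste("dimension with >2 indicators:", paste(crowded, collapse = ", ")) else "")

  bad <- soc$id[!is.na(soc$baseline)]
  add("social_no_baseline", length(bad) == 0,
      if (length(bad)) paste("field baseline set for social indicator:", paste(bad, collapse = ", ")) else "")

  bad <- eco$id[!is.na(eco$aggregation_mode)]
  add("ecological_no_aggregation_mode", length(bad) == 0,
      if (length(bad)) paste("field aggregation_mode set for ecological indicator:", paste(bad, collapse = ", ")) else "")

  bad_mode <- soc$id[!soc$aggregation_mode %in% c("weighted_share", "country_threshold")]
  add("aggregation_mode_label", length(bad_mode) == 0,
      if (length(bad_mode)) paste("field aggregation_mode invalid for:", paste(bad_mode, collapse = ", ")) else "")

  thr <- soc[soc$aggregation_mode %in% "country_threshold", ]
  bad <- thr$id[is.na(thr$threshold_value) | !thr$threshold_comparator %in% c("<", "<=", ">", ">=")]
  add("threshold_fields", length(bad) == 0,
      if (length(bad)) paste("field threshold_value/threshold_comparator invalid for:", paste(bad, collapse = ", ")) else "")

  bad <- specs$id[is.na(specs$averaging_window_years) | specs$averaging_window_years < 1]
  add("averaging_window", length(bad) == 0,
      if (length(bad)) paste("field averaging_window_years invalid for:", paste(bad, collapse = ", ")) else "")

  bad <- specs$id[is.na(specs$start_year) | specs$start_year < 2000 | specs$start_year > 2022]
  add("start_year_range", length(bad) == 0,
      if (length(bad)) paste("field start_year outside 2000-2022 for:", paste(bad, collapse = ", ")) else "")

  dplyr::bind_rows(checks)
}

#' Write a registry back to YAML
#'
#' Round-trips with [load_registry()]: writing and re-loading yields identical
#' specifications.
#'
#' @param specs a registry tibble.
#' @param path output YAML path.
#' @return `path`, invisibly.
#' @export
write_registry <- function(specs, path) {
  recs <- purrr::pmap(specs, function(...) {
    row <- list(...)
    row <- row[!vapply(row, function(x) is.na(x) || identical(x, ""), logical(1))]
    # restore schema defaults omitted from the file
    if (isTRUE(row$has_timeseries)) row$has_timeseries <- NULL
    if (isTRUE(row$has_data)) row$has_data <- NULL
    row
  })
  yaml::write_yaml(recs, path)
  invisible(path)
}

#' Export a registry as JSON for downstream tools
#'
#' @param specs a registry tibble.
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
export_registry_json <- function(specs, path) {
  jsonlite::write_json(specs, path, dataframe = "rows", na = "null", auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}
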