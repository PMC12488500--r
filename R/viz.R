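#' Radial layout of a doughnut chart
#'
#' Computes the wedge geometry behind [doughnut_plot()] as data: one wedge per
#' registry indicator (including missing ones, rendered grey), with radial
#' extent LINEAR in the indicator value. Because wedge area then scales
#' quadratically with value, the bar representation ([bar_panel()]) is
#' provided as the perceptually safer companion.
#'
#' Geometry (global mode): social wedges start at the social foundation ring
#' and grow inward, reaching the centre at 100% shortfall; ecological wedges
#' start at the ecological ceiling and grow outward (within-boundary values
#' grow inward as neutral wedges). In cluster mode ecological wedges start at
#' the outer edge of the social foundation (zero footprint) and the ceiling
#' ring marks the fair-share boundary, so a wedge's length is proportional to
#' `1 + overshoot/100`. Values beyond `clip_cap` are truncated and flagged so
#' the renderer can draw a faded edge.
#'
#' @param values tibble with columns `indicator_id` and `value` (normalized
#'   percent; `NA` or absent rows render grey). Must cover exactly the
#'   registry's indicators (missing ids are filled as `NA`; unknown ids are an
#'   error).
#' @param registry registry tibble; wedge order is registry order, social
#'   then ecological.
#' @param mode `"global"` or `"cluster"`.
#' @param clip_cap maximum ecological overshoot rendered, in percent beyond
#'   the ceiling, expressed as percent of the ring width (default 150).
#' @param radii list of ring radii: `foundation_inner`, `foundation_outer`,
#'   `ceiling`.
#' @return tibble with one row per indicator: `indicator_id`, `domain`,
#'   `value`, `theta0`, `theta1` (angular span, radians), `r0`, `r1` (radial
#'   extent), `color_class` (`shortfall`, `overshoot`, `within`, `missing`),
#'   `clipped`.
#' @export
doughnut_layout <- function(values, registry, mode = c("global", "cluster"),
                            clip_cap = 150,
                            radii = list(foundation_inner = 1,
                                         foundation_outer = 1.25,
                                         ceiling = 2.25)) {
  mode <- match.arg(mode)
  extra <- setdiff(values$indicator_id, registry$id)
  if (length(extra)) {
    abort_doughnut(paste0("values for unknown indicator(s): ",
                          paste(extra, collapse = ", ")),
                   "doughnut_validation_error")
  }
  specs <- dplyr::arrange(registry, .data$domain != "social")
  v <- values$value[match(specs$id, values$indicator_id)]
  n <- nrow(specs)
  width <- radii$ceiling - radii$foundation_outer
  gap <- 0.04
  theta0 <- (seq_len(n) - 1) * 2 * pi / n + gap / 2
  theta1 <- seq_len(n) * 2 * pi / n - gap / 2

  out <- purrr::map_dfr(seq_len(n), function(k) {
    spec <- specs[k, ]
    val <- v[k]
    clipped <- FALSE
    if (is.na(val)) {
      cls <- "missing"
      if (spec$domain == "social") {
        r0 <- 0; r1 <- radii$foundation_inner
      } else {
        r0 <- radii$ceiling; r1 <- radii$ceiling + 0.25 * width
      }
    } else if (spec$domain == "social") {
      cls <- if (val > 0) "shortfall" else "within"
      len <- min(val, 100) / 100 * radii$foundation_inner
      r0 <- radii$foundation_inner - len
      r1 <- radii$foundation_inner
    } else if (mode == "global") {
      cls <- if (val > 0) "overshoot" else "within"
      cap_len <- clip_cap / 100 * width
      len <- abs(val) / 100 * width
      if (val > 0 && len > cap_len) {
        len <- cap_len
        clipped <- TRUE
      }
      if (val >= 0) {
        r0 <- radii$ceiling; r1 <- radii$ceiling + len
      } else {
        r0 <- radii$ceiling - min(len, width); r1 <- radii$ceiling
      }
    } else {
      # cluster mode: footprint wedge from zero (foundation outer edge);
      # the ceiling ring is the fair-share boundary
      cls <- if (val > 0) "overshoot" else "within"
      len <- (1 + val / 100) * width
      cap_len <- (1 + clip_cap / 100) * width
      if (len > cap_len) {
        len <- cap_len
        clipped <- TRUE
      }
      r0 <- radii$foundation_outer
      r1 <- radii$foundation_outer + max(len, 0)
    }
    tibble::tibble(
      indicator_id = spec$id, domain = spec$domain, value = val,
      theta0 = theta0[k], theta1 = theta1[k], r0 = r0, r1 = r1,
      color_class = cls, clipped = clipped
    )
  })
  attr(out, "radii") <- radii
  out
}

doughnut_palette <- c(
  shortfall = "#c23728", overshoot = "#c23728",
  within = "#9fc8c8", missing = "#b3b3b3"
)

#' Draw a doughnut chart
#'
#' Renders the radial wedge chart of shortfall and overshoot from a
#' [doughnut_layout()]. Red wedges fall short of the social foundation or
#' overshoot the ecological ceiling; grey marks missing data; clipped wedges
#' are drawn with a lightened edge. Returns a ggplot object; use
#' [save_plot()] to write a file.
#'
#' @inheritParams doughnut_layout
#' @param ... passed to [doughnut_layout()].
#' @return a ggplot object.
#' @export
doughnut_plot <- function(values, registry, mode = "global", ...) {
  lay <- doughnut_layout(values, registry, mode = mode, ...)
  radii <- attr(lay, "radii")
  rings <- tibble::tibble(
    r = c(radii$foundation_inner, radii$foundation_outer, radii$ceiling)
  )
  ggplot2::ggplot(lay) +
    ggplot2::geom_rect(
      ggplot2::aes(xmin = .data$theta0, xmax = .data$theta1,
                   ymin = .data$r0, ymax = .data$r1,
                   fill = .data$color_class,
                   colour = ifelse(.data$clipped, "clipped", NA)),
      linewidth = 0.6
    ) +
    ggplot2::geom_hline(data = rings, ggplot2::aes(yintercept = .data$r),
                        colour = "grey25", linewidth = 0.3) +
    ggplot2::scale_fill_manual(values = doughnut_palette, name = NULL) +
    ggplot2::scale_colour_manual(values = c(clipped = "#f2b8b0"),
                                 na.value = NA, guide = "none") +
    ggplot2::coord_polar(theta = "x") +
    ggplot2::expand_limits(y = 0) +
    ggplot2::theme_void()
}

#' Grouped bar-chart representation
#'
#' The linear companion of the doughnut chart: horizontal bars per indicator,
#' grouped by period or by country cluster, avoiding the quadratic
#' wedge-area scaling of the radial view.
#'
#' @param values tibble with columns `indicator_id`, `group` and `value`.
#' @param registry registry tibble (bar order is registry order).
#' @return a ggplot object.
#' @export
bar_panel <- function(values, registry) {
  if (nrow(values) == 0) {
    abort_doughnut("no values to plot", "doughnut_validation_error")
  }
  extra <- setdiff(values$indicator_id, registry$id)
  if (length(extra)) {
    abort_doughnut(paste0("values for unknown indicator(s): ",
                          paste(extra, collapse = ", ")),
                   "doughnut_validation_error")
  }
  values$indicator_id <- factor(values$indicator_id,
                                levels = rev(registry$id))
  ggplot2::ggplot(values,
                  ggplot2::aes(x = .data$value, y = .data$indicator_id,
                               fill = factor(.data$group))) +
    ggplot2::geom_col(position = ggplot2::position_dodge2(preserve = "single"),
                      width = 0.8) +
    ggplot2::geom_vline(xintercept = 0, linewidth = 0.4) +
    ggplot2::labs(x = "shortfall / overshoot (%)", y = NULL, fill = NULL) +
    ggplot2::theme_minimal()
}

#' Save a plot deterministically
#'
#' Thin wrapper over [ggplot2::ggsave()]; the output format follows the file
#' extension (`.pdf` and `.png` are always available; `.svg` requires a
#' capable graphics backend).
#'
#' @param plot a ggplot object.
#' @param path output file path.
#' @param width,height device size in inches.
#' @return `path`, invisibly.
#' @export
save_plot <- function(plot, path, width = 7, height = 7) {
  ggplot2::ggsave(path, plot, width = width, height = height)
  invisible(path)
}
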