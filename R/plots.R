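# Plot methods. The central diagnostic is the tract-vs-region scatter: each
# point is an area, placed at (area estimate, region estimate); solid points
# lie within their own margin of error of the region estimate (their share
# per panel equals S_j) and colour records whether the area already met the
# CV target on its own.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Diagnostic scatter of area versus region estimates
#'
#' @param object A `cvr_eval` from [evaluate_partition()].
#' @param ... Unused.
#' @return A ggplot: one panel per evaluated variable, the 45-degree line in
#'   grey, areas coloured by their own CV pass/fail and filled when the
#'   region estimate lies within the area's MOE.
#' @export
autoplot.cvr_eval <- function(object, ...) {
  d <- object$diagnostics
  ggplot2::ggplot(d, ggplot2::aes(x = .data$area_est, y = .data$region_est)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, colour = "grey60") +
    ggplot2::geom_point(ggplot2::aes(colour = .data$cv_pass, shape = .data$within_moe),
                        size = 2) +
    ggplot2::scale_colour_manual(values = c(`TRUE` = "#2e7d32", `FALSE` = "#c62828"),
                                 name = "area CV ≤ target") +
    ggplot2::scale_shape_manual(values = c(`TRUE` = 16, `FALSE` = 1),
                                name = "region est. within area MOE") +
    ggplot2::facet_wrap(ggplot2::vars(.data$variable), scales = "free") +
    ggplot2::labs(x = "area estimate", y = "region estimate") +
    ggplot2::theme_minimal()
}

#' Region-level CVs against their targets
#'
#' @param object A `cvr_solution`.
#' @param ... Unused.
#' @return A ggplot of region CVs per variable with the target line; exempt
#'   cells are hollow.
#' @export
autoplot.cvr_solution <- function(object, ...) {
  rt <- object$region_table
  ggplot2::ggplot(rt, ggplot2::aes(x = .data$variable, y = .data$cv)) +
    ggplot2::geom_jitter(ggplot2::aes(shape = .data$exempt), width = 0.15, height = 0,
                         alpha = 0.7) +
    ggplot2::geom_point(ggplot2::aes(y = .data$cv_target), colour = "#c62828", shape = 95,
                        size = 8) +
    ggplot2::scale_shape_manual(values = c(`FALSE` = 16, `TRUE` = 1), name = "exempt") +
    ggplot2::labs(x = NULL, y = "region-level CV") +
    ggplot2::theme_minimal()
}

#' Map of regions over the input polygons
#'
#' @param x A `cvr_solution` or `cvr_partition`.
#' @param geometry A geometry tibble from [read_geometry()] (or the
#'   `geometry` element of a [generate_survey()] result).
#' @return A ggplot choropleth of region membership.
#' @export
plot_regions <- function(x, geometry) {
  assignment <- if (inherits(x, c("cvr_solution", "cvr_partition"))) x$assignment else x
  rings <- purrr::map2_dfr(geometry$area_id, geometry$geometry, function(id, geom) {
    ring <- geom[[1]][[1]]
    tibble::tibble(area_id = id, x = ring[, 1], y = ring[, 2])
  })
  rings$region <- assignment$region[match(rings$area_id, assignment$area_id)]
  ggplot2::ggplot(rings, ggplot2::aes(x = .data$x, y = .data$y, group = .data$area_id,
                                      fill = factor(.data$region))) +
    ggplot2::geom_polygon(colour = "white", linewidth = 0.2) +
    ggplot2::coord_equal() +
    ggplot2::guides(fill = "none") +
    ggplot2::theme_void()
}
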