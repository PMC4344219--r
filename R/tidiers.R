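# broom-style tidiers

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a regionalization solution
#'
#' @param x A `cvr_solution`.
#' @param ... Unused.
#' @return One row per area: `area_id`, `region`, `region_size`.
#' @export
tidy.cvr_solution <- function(x, ...) {
  x$assignment |>
    dplyr::add_count(.data$region, name = "region_size")
}

#' @rdname tidy.cvr_solution
#' @export
tidy.cvr_partition <- function(x, ...) {
  x$assignment |>
    dplyr::add_count(.data$region, name = "region_size")
}

#' One-row summary of a regionalization solution
#'
#' @param x A `cvr_solution`.
#' @param ... Unused.
#' @export
glance.cvr_solution <- function(x, ...) {
  tibble::tibble(
    n_areas = nrow(x$assignment),
    n_regions = x$n_regions,
    areas_per_region = nrow(x$assignment) / x$n_regions,
    ssd = x$ssd,
    phase1_candidates = x$phase1_candidates,
    swaps_accepted = x$swaps_accepted,
    n_exempt = x$n_exempt,
    n_fallback = x$n_fallback
  )
}

#' Tidy an evaluation report
#'
#' @param x A `cvr_eval`.
#' @param ... Unused.
#' @return The per-variable `s_j` tibble.
#' @export
tidy.cvr_eval <- function(x, ...) x$s_j

#' @rdname tidy.cvr_eval
#' @export
glance.cvr_eval <- function(x, ...) {
  tibble::tibble(s = x$s, n_regions = x$n_regions, areas_per_region = x$areas_per_region)
}
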