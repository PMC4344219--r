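# Partitions: exhaustive, exclusive assignments of retained areas to
# contiguous regions, with the cached region-level uncertainty table and SSD.

#' Build and validate a partition
#'
#' Wraps an externally supplied area-to-region assignment (e.g. hand-drawn
#' aggregation units) in the same structure [regionalize()] produces, so it
#' can be written out and evaluated. Checks that the assignment covers every
#' retained area exactly once and, when a graph is given, that every region
#' induces a connected subgraph.
#'
#' @param assignment A data frame with columns `area_id` and `region`.
#' @param prep A `cvr_prep` from [preprocess()] (or a raw area table plus
#'   `specs`).
#' @param specs Variable specs, when `prep` is a raw table.
#' @param graph Optional `cvr_graph` for connectivity validation.
#' @return A `cvr_partition` with `assignment`, `region_table`, `ssd`,
#'   `n_regions`.
#' @export
partition <- function(assignment, prep, specs = NULL, graph = NULL) {
  if (!inherits(prep, "cvr_prep")) prep <- preprocess(prep, specs)
  ids <- prep$table$area_id
  if (!is.data.frame(assignment) || !all(c("area_id", "region") %in% names(assignment))) {
    stop_cvr("assignment must have columns area_id and region", "cvr_contract_error")
  }
  missing <- setdiff(ids, assignment$area_id)
  if (length(missing)) {
    stop_cvr(paste0("assignment misses retained area(s): ", paste(missing, collapse = ", ")),
             "cvr_contract_error")
  }
  extra <- setdiff(assignment$area_id, ids)
  if (length(extra)) {
    stop_cvr(paste0("assignment covers unknown/dropped area(s): ", paste(extra, collapse = ", ")),
             "cvr_contract_error")
  }
  if (anyDuplicated(assignment$area_id)) {
    stop_cvr("assignment assigns some area more than once", "cvr_contract_error")
  }
  assignment <- assignment[match(ids, assignment$area_id), ]
  lab <- match(assignment$region, unique(assignment$region))
  assignment <- tibble::tibble(area_id = ids, region = as.integer(lab))
  if (!is.null(graph)) {
    g <- restrict_graph(graph, ids)
    adj <- adjacency_index(g, ids)
    for (k in unique(lab)) {
      members <- which(lab == k)
      if (length(members) > 1L && !connected_without(adj, members, 0L)) {
        stop_cvr(paste0("region ", k, " is not connected in the contiguity graph"),
                 "cvr_contract_error")
      }
    }
  }
  region_tab <- purrr::map_dfr(sort(unique(lab)), function(k) {
    rt <- region_cv_table(prep$table, ids[lab == k], prep$specs)
    rt$region <- k
    rt
  })
  structure(list(
    assignment = assignment,
    region_table = dplyr::relocate(region_tab, "region"),
    ssd = ssd(assignment, prep$features),
    n_regions = max(lab),
    prep = prep
  ), class = "cvr_partition")
}

#' @export
print.cvr_partition <- function(x, ...) {
  cat("<cvr_partition> ", nrow(x$assignment), " areas -> ", x$n_regions,
      " regions; SSD ", format(x$ssd, digits = 6), "\n", sep = "")
  invisible(x)
}

#' Write a partition to disk
#'
#' Writes (i) `assignment.csv` (area to region), (ii) `regions.csv` (per
#' region and variable: estimate, MOE, CV, exemption flag, plus region size),
#' and, when polygon geometry is supplied, (iii) `regions.geojson` with the
#' member polygons of each region dissolved into one boundary.
#'
#' @param x A `cvr_solution` or `cvr_partition`.
#' @param dir Output directory (created if needed).
#' @param geometry Optional geometry tibble from [read_geometry()].
#' @return Invisibly, a named character vector of the files written.
#' @export
write_partition <- function(x, dir, geometry = NULL) {
  if (!inherits(x, c("cvr_solution", "cvr_partition"))) {
    stop_cvr("x must be a cvr_solution or cvr_partition", "cvr_contract_error")
  }
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(assignment = file.path(dir, "assignment.csv"),
             regions = file.path(dir, "regions.csv"))
  utils::write.csv(x$assignment, paths["assignment"], row.names = FALSE, quote = FALSE)
  sizes <- dplyr::count(x$assignment, .data$region, name = "n_areas")
  rt <- dplyr::left_join(x$region_table, sizes, by = "region")
  utils::write.csv(format_sig(rt), paths["regions"], row.names = FALSE, quote = FALSE)
  if (!is.null(geometry)) {
    missing <- setdiff(x$assignment$area_id, geometry$area_id)
    if (length(missing)) {
      stop_cvr(paste0("geometry missing for area(s): ", paste(missing, collapse = ", ")),
               "cvr_config_error")
    }
    regions <- sort(unique(x$assignment$region))
    geoms <- purrr::map(regions, function(k) {
      members <- x$assignment$area_id[x$assignment$region == k]
      gs <- geometry$geometry[match(members, geometry$area_id)]
      dissolve_areas(gs) %||% purrr::flatten(gs)  # fallback: undissolved members
    })
    paths <- c(paths, geojson = file.path(dir, "regions.geojson"))
    write_geojson(regions, geoms, paths["geojson"], id_name = "region")
  }
  invisible(paths)
}

# round-trippable text formatting: plenty of digits, no scientific notation
format_sig <- function(df) {
  as.data.frame(lapply(df, function(col) {
    if (is.double(col)) format(col, digits = 15, trim = TRUE, scientific = FALSE) else col
  }), check.names = FALSE)
}
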