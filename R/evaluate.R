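# Information-loss diagnostics for an aggregation.
#
# S_j asks, for each area, whether the region-level estimate it was assigned
# to lies within the area's own margin of error: if it does for every member,
# the aggregation lost no information about that variable at that area. S is
# the unweighted mean of S_j over the evaluated variables. Counts are
# excluded: a region's count always exceeds its members' counts, so the
# comparison is meaningless for them.

# per-(area, variable) records for the evaluated (proportion/mean) variables
diag_records <- function(assignment, table, specs, targets) {
  idx <- match(assignment$area_id, table$area_id)
  if (anyNA(idx)) {
    stop_cvr(paste0("assignment covers unknown area(s): ",
                    paste(assignment$area_id[is.na(idx)], collapse = ", ")),
             "cvr_contract_error")
  }
  ev <- which(specs$kind != "count")
  purrr::map_dfr(ev, function(v) {
    kind <- specs$kind[v]
    ne <- table[[specs$num_est[v]]][idx]
    nse <- table[[specs$num_moe[v]]][idx] / Z90
    de <- table[[specs$den_est[v]]][idx]
    dse <- table[[specs$den_moe[v]]][idx] / Z90
    a <- derived_se(ne, nse, de, dse, kind)
    dat <- tibble::tibble(region = assignment$region, ne = ne, nse = nse,
                          de = de, dse = dse)
    regs <- dat |>
      dplyr::group_by(.data$region) |>
      dplyr::summarise(sne = sum(.data$ne), snse = sqrt(sum(.data$nse^2)),
                       sde = sum(.data$de), sdse = sqrt(sum(.data$dse^2)))
    rg <- derived_se(regs$sne, regs$snse, regs$sde, regs$sdse, kind)
    region_est <- rg$estimate[match(assignment$region, regs$region)]
    diff <- abs(a$estimate - region_est)
    moe <- a$se * Z90
    tibble::tibble(
      variable = specs$name[v],
      area_id = assignment$area_id,
      region = assignment$region,
      area_est = a$estimate,
      area_moe = moe,
      region_est = region_est,
      cv_pass = cv_from_se(a$estimate, a$se) <= targets[v] + 1e-12,
      # strict inequality, with a zero-difference convention: an area equal to
      # its region estimate is never counted as information loss, even at MOE 0
      within_moe = diff < moe | diff <= 1e-12
    )
  })
}

resolve_targets <- function(specs, cv_target) {
  if (inherits(cv_target, "cvr_constraints")) cv_target <- cv_target$cv
  targets <- ifelse(is.na(specs$cv_target), cv_target %||% NA_real_, specs$cv_target)
  if (anyNA(targets)) stop_cvr("no CV target defined for every variable", "cvr_config_error")
  targets
}

#' Share of areas aggregated without information loss
#'
#' For variable `j`, `s_j` is the share of areas whose region-level estimate
#' lies strictly within the area's own margin of error (a zero difference
#' counts as within, whatever the MOE). Defined for proportion and mean
#' variables only.
#'
#' @param assignment A data frame with `area_id` and `region` (or a
#'   `cvr_solution`/`cvr_partition`).
#' @param table The area table the partition was built from.
#' @param specs Variable specification tibble.
#' @param variable Name of the variable to evaluate.
#' @return A number in `[0, 1]`.
#' @export
s_j <- function(assignment, table, specs, variable) {
  v <- match(variable, specs$name)
  if (is.na(v)) stop_cvr(paste0("unknown variable: ", variable), "cvr_config_error")
  if (specs$kind[v] == "count") {
    stop_cvr(paste0("s_j is undefined for count variables ('", variable,
                    "'): a region's count always exceeds its members' counts"),
             "cvr_contract_error")
  }
  if (inherits(assignment, c("cvr_solution", "cvr_partition"))) {
    assignment <- assignment$assignment
  }
  recs <- diag_records(assignment, table, specs[v, ], targets = Inf)
  mean(recs$within_moe)
}

#' Overall information retention
#'
#' The unweighted mean of the per-variable `s_j` values.
#'
#' @param sj Numeric vector of `s_j` values.
#' @return A number in `[0, 1]`.
#' @export
s_global <- function(sj) {
  if (!length(sj)) stop_cvr("s requires at least one evaluated variable", "cvr_domain_error")
  mean(sj)
}

#' Average number of areas per region
#'
#' @param assignment A data frame with `area_id` and `region` (or a
#'   `cvr_solution`/`cvr_partition`).
#' @return `n_areas / n_regions`.
#' @export
areas_per_region <- function(assignment) {
  if (inherits(assignment, c("cvr_solution", "cvr_partition"))) {
    assignment <- assignment$assignment
  }
  nrow(assignment) / length(unique(assignment$region))
}

#' Per-area diagnostic records
#'
#' One record per (area, evaluated variable) with the four encodings of the
#' diagnostic scatter: area estimate, region estimate, whether the area's own
#' CV met the target (`cv_pass`), and whether the region estimate lies within
#' the area's MOE (`within_moe`). The share of `within_moe` records per
#' variable equals that variable's `s_j`.
#'
#' @inheritParams s_j
#' @param cv_target Global CV target used for the `cv_pass` flag (per-variable
#'   `cv_target`s in `specs` take precedence); may also be a [constraints()]
#'   object.
#' @return A tibble of diagnostic records.
#' @export
diagnostic_table <- function(assignment, table, specs, cv_target) {
  if (inherits(assignment, c("cvr_solution", "cvr_partition"))) {
    assignment <- assignment$assignment
  }
  specs <- validate_specs(specs, table)
  targets <- resolve_targets(specs, cv_target)
  ev <- specs$kind != "count"
  if (!any(ev)) {
    stop_cvr("no proportion or mean variables to evaluate", "cvr_domain_error")
  }
  diag_records(assignment, table, specs[ev, ], targets[ev])
}

#' Evaluate a partition
#'
#' Computes the full information-loss report for a partition: per-variable
#' `s_j`, the overall `S`, areas per region, and the per-area diagnostic
#' records.
#'
#' @param x A `cvr_solution`, `cvr_partition`, or an assignment data frame.
#' @param table Area table (taken from the solution when omitted).
#' @param specs Variable specs (taken from the solution when omitted).
#' @param cv_target Global CV target for the diagnostic `cv_pass` flag
#'   (defaults to the solution's constraints).
#' @return A `cvr_eval` object: `s_j` tibble, `s`, `areas_per_region`,
#'   `n_regions`, `diagnostics`.
#' @export
evaluate_partition <- function(x, table = NULL, specs = NULL, cv_target = NULL) {
  if (inherits(x, "cvr_solution")) {
    table <- table %||% x$prep$table
    specs <- specs %||% x$prep$specs
    cv_target <- cv_target %||% x$constraints
    assignment <- x$assignment
  } else if (inherits(x, "cvr_partition")) {
    table <- table %||% x$prep$table
    specs <- specs %||% x$prep$specs
    assignment <- x$assignment
  } else {
    assignment <- x
  }
  if (is.null(table) || is.null(specs)) {
    stop_cvr("table and specs are required for a bare assignment", "cvr_contract_error")
  }
  diags <- diagnostic_table(assignment, table, specs, cv_target)
  sj <- diags |>
    dplyr::group_by(.data$variable) |>
    dplyr::summarise(s_j = mean(.data$within_moe)) |>
    dplyr::arrange(match(.data$variable, specs$name))
  structure(list(
    s_j = sj,
    s = s_global(sj$s_j),
    areas_per_region = areas_per_region(assignment),
    n_regions = length(unique(assignment$region)),
    diagnostics = diags
  ), class = "cvr_eval")
}

#' @export
print.cvr_eval <- function(x, ...) {
  cat("<cvr_eval> S = ", sprintf("%.3f", x$s), " over ", nrow(x$s_j),
      " variable(s); ", x$n_regions, " regions (",
      sprintf("%.2f", x$areas_per_region), " areas/region)\n", sep = "")
  for (i in seq_len(nrow(x$s_j))) {
    cat("  S_j[", x$s_j$variable[i], "] = ", sprintf("%.3f", x$s_j$s_j[i]), "\n", sep = "")
  }
  invisible(x)
}
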