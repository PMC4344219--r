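# Reading and writing area-attribute tables and partitions.

#' Read an area-attribute table
#'
#' One row per area. The file must contain an `area_id` column, a `households`
#' column, and every estimate/MOE column referenced by `specs`. `population`
#' and `population_moe` columns are used for population constraints when
#' present. Extra columns are carried along untouched. Values are read
#' verbatim; preprocessing (zero-household filtering, zero-estimate MOE
#' resets) happens later, in [preprocess()].
#'
#' @param path Path to a comma-delimited text file with a header row.
#' @param specs Variable specification tibble (see [variable_spec()]).
#' @return A tibble with one row per area.
#' @export
read_area_table <- function(path, specs) {
  if (!file.exists(path)) stop_cvr(paste0("file not found: ", path), "cvr_config_error")
  tab <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE,
                         colClasses = c(area_id = "character"))
  if (nrow(tab) == 0L) stop_cvr("area table has a header but no data rows", "cvr_parse_error")
  tab <- tibble::as_tibble(tab)
  for (col in c("area_id", "households")) {
    if (!col %in% names(tab)) {
      stop_cvr(paste0("required column missing from area table: ", col), "cvr_config_error")
    }
  }
  validate_specs(specs, tab)
  num_cols <- stats::na.omit(unique(c(
    "households", intersect(c("population", "population_moe"), names(tab)),
    specs$num_est, specs$num_moe, specs$den_est, specs$den_moe
  )))
  for (col in num_cols) {
    v <- tab[[col]]
    if (is.character(v)) {
      parsed <- suppressWarnings(as.numeric(v))
      bad <- which(is.na(parsed) & !is.na(v))
      if (length(bad)) {
        stop_cvr(paste0("non-numeric value in column '", col, "', row for area '",
                        tab$area_id[bad[1]], "'"), "cvr_parse_error")
      }
      v <- parsed
    }
    if (anyNA(v)) {
      stop_cvr(paste0("missing value in column '", col, "', area '",
                      tab$area_id[which(is.na(v))[1]], "'"), "cvr_parse_error")
    }
    tab[[col]] <- as.numeric(v)
  }
  if (anyDuplicated(tab$area_id)) {
    stop_cvr("duplicate area_id in area table", "cvr_config_error")
  }
  moe_cols <- stats::na.omit(unique(c(specs$num_moe, specs$den_moe,
                                      intersect("population_moe", names(tab)))))
  for (col in moe_cols) {
    if (any(tab[[col]] < 0)) stop_cvr(paste0("negative MOE in column ", col), "cvr_parse_error")
  }
  if (any(tab$households < 0)) stop_cvr("negative households", "cvr_parse_error")
  tab
}

#' Read an area-to-region assignment table
#'
#' The inverse of the assignment file written by [write_partition()]: a
#' comma-delimited file with columns `area_id` and `region`.
#'
#' @param path Path to the assignment file.
#' @return A tibble with columns `area_id` (character) and `region` (integer).
#' @export
read_assignment <- function(path) {
  if (!file.exists(path)) stop_cvr(paste0("file not found: ", path), "cvr_config_error")
  tab <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE,
                         colClasses = c(area_id = "character"))
  if (!all(c("area_id", "region") %in% names(tab))) {
    stop_cvr("assignment file must have columns area_id, region", "cvr_config_error")
  }
  tibble::tibble(area_id = as.character(tab$area_id), region = as.integer(tab$region))
}
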