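# Variable specifications: how the columns of an area table define survey
# variables (plain counts, or numerator/denominator pairs for derived
# proportions and ratio means), plus run-level constraints.

#' Declare a survey variable
#'
#' A variable is either a `count` (one estimate + MOE column pair) or a derived
#' `proportion` / `mean` (numerator and denominator column pairs). Proportions
#' are subset ratios (e.g. persons above poverty / total persons) and are the
#' only kind eligible for the small-proportion CV exemption; means are ratios
#' of distinct quantities (e.g. aggregate income / population).
#'
#' @param name Variable label.
#' @param kind `"count"`, `"proportion"`, or `"mean"`.
#' @param num_est,num_moe Column names of the (numerator) estimate and MOE.
#' @param den_est,den_moe Column names of the denominator estimate and MOE;
#'   required for proportions and means, absent for counts.
#' @param cv_target Optional per-variable CV target overriding the global one.
#' @return A one-row tibble; bind rows of these to describe several variables.
#' @examples
#' variable_spec("pov", "proportion", "pov_num", "pov_moe",
#'               "population", "population_moe")
#' @export
variable_spec <- function(name, kind = c("count", "proportion", "mean"),
                          num_est, num_moe, den_est = NULL, den_moe = NULL,
                          cv_target = NULL) {
  kind <- match.arg(kind)
  if (kind != "count" && (is.null(den_est) || is.null(den_moe))) {
    stop_cvr(paste0("variable '", name, "': kind '", kind, "' requires denominator columns"),
             "cvr_config_error")
  }
  if (!is.null(cv_target) && (!is.numeric(cv_target) || cv_target <= 0)) {
    stop_cvr(paste0("variable '", name, "': cv_target must be a positive number"),
             "cvr_config_error")
  }
  tibble::tibble(
    name = as.character(name), kind = kind,
    num_est = as.character(num_est), num_moe = as.character(num_moe),
    den_est = if (is.null(den_est)) NA_character_ else as.character(den_est),
    den_moe = if (is.null(den_moe)) NA_character_ else as.character(den_moe),
    cv_target = if (is.null(cv_target)) NA_real_ else as.numeric(cv_target)
  )
}

# check a spec tibble against an area table; returns the specs invisibly
validate_specs <- function(specs, table = NULL) {
  req <- c("name", "kind", "num_est", "num_moe", "den_est", "den_moe", "cv_target")
  if (!is.data.frame(specs) || !all(req %in% names(specs))) {
    stop_cvr("specs must be a tibble built with variable_spec()", "cvr_config_error")
  }
  if (anyDuplicated(specs$name)) {
    stop_cvr("duplicate variable names in specs", "cvr_config_error")
  }
  bad <- specs$kind != "count" & (is.na(specs$den_est) | is.na(specs$den_moe))
  if (any(bad)) {
    stop_cvr(paste0("variable(s) without denominator: ", paste(specs$name[bad], collapse = ", ")),
             "cvr_config_error")
  }
  if (any(!is.na(specs$cv_target) & specs$cv_target <= 0)) {
    stop_cvr("cv_target must be positive", "cvr_config_error")
  }
  if (!is.null(table)) {
    cols <- stats::na.omit(unique(c(specs$num_est, specs$num_moe, specs$den_est, specs$den_moe)))
    missing <- setdiff(cols, names(table))
    if (length(missing)) {
      stop_cvr(paste0("column(s) not found in area table: ", paste(missing, collapse = ", ")),
               "cvr_config_error")
    }
  }
  invisible(specs)
}

#' Read a JSON variable configuration
#'
#' The configuration maps variable names to
#' `{kind, num_est, num_moe, den_est, den_moe, cv_target}` objects under a
#' top-level `"variables"` key (or is itself such a mapping). Run-level keys
#' (`cv`, `pop_min`, `pop_max`, `n_starts`, `seed`, `tabu_length`, `max_swaps`,
#' `no_improve_stop`) are returned alongside.
#'
#' @param path Path to a JSON file.
#' @return A list with elements `specs` (tibble), `constraints`
#'   (see [constraints()]), and `config` (see [region_config()]).
#' @export
read_variable_config <- function(path) {
  if (!file.exists(path)) stop_cvr(paste0("config file not found: ", path), "cvr_config_error")
  raw <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  vars <- raw$variables %||% raw
  if (!length(vars)) stop_cvr("config declares no variables", "cvr_config_error")
  specs <- purrr::imap_dfr(vars, function(v, nm) {
    variable_spec(nm, kind = v$kind %||% "count",
                  num_est = v$num_est, num_moe = v$num_moe,
                  den_est = v$den_est, den_moe = v$den_moe,
                  cv_target = v$cv_target)
  })
  cons <- constraints(
    cv = raw$cv, pop_min = raw$pop_min, pop_max = raw$pop_max,
    specs = specs
  )
  cfg <- region_config(
    n_starts = raw$n_starts %||% 100L,
    seed = raw$seed %||% 1L,
    tabu_length = raw$tabu_length %||% 10L,
    max_swaps = raw$max_swaps %||% 10000L,
    no_improve_stop = raw$no_improve_stop %||% 500L
  )
  list(specs = specs, constraints = cons, config = cfg)
}

#' Run constraints
#'
#' At least one CV target must be defined, either globally here or per variable
#' through [variable_spec()]'s `cv_target`. Optional population bounds apply to
#' the sum of the area table's `population` estimates in each region.
#'
#' @param cv Global CV target (positive), or `NULL` if every variable carries
#'   its own target.
#' @param pop_min,pop_max Optional region population bounds.
#' @param specs Optional specs tibble, used to verify that every variable ends
#'   up with a CV target.
#' @return A `cvr_constraints` list.
#' @export
constraints <- function(cv = NULL, pop_min = NULL, pop_max = NULL, specs = NULL) {
  if (!is.null(cv) && (!is.numeric(cv) || length(cv) != 1L || cv <= 0)) {
    stop_cvr("cv must be a single positive number", "cvr_config_error")
  }
  for (b in list(pop_min, pop_max)) {
    if (!is.null(b) && (!is.numeric(b) || b < 0)) {
      stop_cvr("population bounds must be nonnegative", "cvr_config_error")
    }
  }
  if (!is.null(pop_min) && !is.null(pop_max) && pop_min > pop_max) {
    stop_cvr("pop_min must not exceed pop_max", "cvr_config_error")
  }
  if (!is.null(specs)) {
    uncovered <- is.na(specs$cv_target)
    if (is.null(cv) && any(uncovered)) {
      stop_cvr("no CV target: supply a global cv or per-variable cv_target for every variable",
               "cvr_config_error")
    }
  }
  structure(list(cv = cv, pop_min = pop_min, pop_max = pop_max),
            class = "cvr_constraints")
}

#' Heuristic configuration
#'
#' @param n_starts Number of independent phase-1 restarts (grow + leftover
#'   assignment attempts). More restarts explore more of the partition space.
#' @param seed Integer seed; identical configuration and seed reproduce the
#'   run exactly.
#' @param tabu_length Iterations for which a reversed move stays tabu.
#' @param max_swaps Hard cap on phase-2 iterations.
#' @param no_improve_stop Stop phase 2 after this many consecutive iterations
#'   without improving the best solution found.
#' @return A `cvr_config` list.
#' @export
region_config <- function(n_starts = 100L, seed = 1L, tabu_length = 10L,
                          max_swaps = 10000L, no_improve_stop = 500L) {
  vals <- list(n_starts = n_starts, seed = seed, tabu_length = tabu_length,
               max_swaps = max_swaps, no_improve_stop = no_improve_stop)
  for (nm in setdiff(names(vals), "seed")) {
    if (!is.numeric(vals[[nm]]) || vals[[nm]] < 1) {
      stop_cvr(paste0(nm, " must be a positive integer"), "cvr_config_error")
    }
  }
  structure(lapply(vals, function(x) as.integer(round(x))), class = "cvr_config")
}
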