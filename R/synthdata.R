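# Synthetic lattice surveys with known ground truth.
#
# The generator emulates the situation the method is built for: a map of
# small reporting areas, each publishing estimates with sampling-noise-
# consistent margins of error (MOE = 1.645 * sd / sqrt(completed surveys)),
# with planted homogeneous zones whose between-zone separation is controlled
# in units of the within-zone spread of observed estimates. Defaults follow
# the realities of multi-year household surveys at tract scale: an average of
# 135 completed surveys per area, five derived proportion variables over a
# shared population denominator, and area populations of a few thousand.

#' Generate a synthetic lattice survey
#'
#' Areas are unit squares on a `rows x cols` grid, ids in row-major order.
#' Each area belongs to a planted zone; a variable's true value in an area is
#' the zone mean plus small within-zone noise, and its observed estimate adds
#' sampling noise with standard error `sd / sqrt(n_i)` for the area's number
#' of completed surveys `n_i`. Every published MOE is exactly `1.645` times
#' that standard error, so the generated uncertainties are internally
#' consistent by construction.
#'
#' @param rows,cols Lattice dimensions (`rows * cols >= 4`).
#' @param zones `"quadrant"` (four blocks), `"bands"` (horizontal bands), or
#'   an integer matrix of zone labels (`rows x cols`, each zone forming a
#'   connected block).
#' @param effect Between-zone mean separation, in units of the within-zone
#'   standard deviation of observed estimates. `0` plants no signal; `3`
#'   gives strongly separated zones.
#' @param mean_sample Expected completed surveys per area (floor 10). Drives
#'   every margin of error; large values send all CVs toward zero.
#' @param n_proportions Number of derived proportion variables (numerator
#'   count over the shared population denominator).
#' @param n_counts Number of plain count variables.
#' @param zero_household Number of areas to mark as household-free (parks,
#'   water); they are dropped by [preprocess()].
#' @param seed Optional integer seed; the same seed regenerates the survey
#'   bit-identically.
#' @return A `cvr_survey`: `table` (area table), `geometry` (unit-square
#'   polygons), `truth` (zone labels, sample sizes, true values and per-cell
#'   sampling sds), `specs`, and the lattice dimensions.
#' @export
generate_survey <- function(rows, cols, zones = "quadrant", effect = 3,
                            mean_sample = 135, n_proportions = 5, n_counts = 0,
                            zero_household = 0, seed = NULL) {
  if (rows * cols < 4) stop_cvr("lattice must have at least 4 areas", "cvr_config_error")
  zone_mat <- resolve_zones(zones, rows, cols)
  gen <- function() {
    n <- rows * cols
    ids <- lattice_ids(rows, cols)
    rr <- rep(seq_len(rows), each = cols)
    cc <- rep(seq_len(cols), times = rows)
    zone <- zone_mat[cbind(rr, cc)]
    Z <- max(zone)

    n_i <- pmax(10L, as.integer(round(stats::rnorm(n, mean_sample, mean_sample / 4))))
    true_pop <- round(stats::runif(n, 2500, 5500))
    sd_pop <- 0.5 * true_pop               # per-survey spread of the population cell
    se_pop <- sd_pop / sqrt(n_i)
    obs_pop <- pmax(true_pop + stats::rnorm(n, 0, se_pop), 100)

    tab <- tibble::tibble(
      area_id = ids,
      households = round(true_pop / 2.5),
      population = obs_pop,
      population_moe = Z90 * se_pop
    )
    truth <- tibble::tibble(
      area_id = ids, zone = zone, n_sample = n_i,
      true_population = true_pop, sd_population = sd_pop
    )
    specs <- NULL

    sigma_w <- 0.02  # within-zone sd of true proportions
    p_bases <- if (n_proportions > 0) seq(0.15, 0.65, length.out = n_proportions) else numeric()
    for (j in seq_len(n_proportions)) {
      p0 <- p_bases[j]
      sigma_ref <- sqrt(sigma_w^2 + p0 * (1 - p0) / mean_sample)
      lv <- as.numeric(scale(sample(seq_len(Z))))
      if (Z == 1L || effect == 0) lv <- rep(0, Z)
      p_zone <- pmin(pmax(p0 + effect * sigma_ref * lv, 0.02), 0.90)
      p_true <- pmin(pmax(p_zone[zone] + stats::rnorm(n, 0, sigma_w), 0.01), 0.95)
      num_true <- p_true * true_pop
      sd_num <- true_pop * sqrt(p_true * (1 - p_true))
      se_num <- sd_num / sqrt(n_i)
      obs_num <- pmin(pmax(num_true + stats::rnorm(n, 0, se_num), 0), tab$population)
      nm <- paste0("p", j)
      tab[[paste0(nm, "_num")]] <- obs_num
      tab[[paste0(nm, "_num_moe")]] <- Z90 * se_num
      truth[[paste0("true_", nm)]] <- p_true
      truth[[paste0("sd_", nm)]] <- sd_num
      specs <- dplyr::bind_rows(specs, variable_spec(
        nm, "proportion", paste0(nm, "_num"), paste0(nm, "_num_moe"),
        "population", "population_moe"
      ))
    }

    c_bases <- if (n_counts > 0) seq(400, 800, length.out = n_counts) else numeric()
    for (k in seq_len(n_counts)) {
      base <- c_bases[k]
      sigma_wc <- 0.05   # relative within-zone sd of true counts
      sigma_refc <- sqrt(sigma_wc^2 + 1.3^2 / mean_sample)
      lv <- as.numeric(scale(sample(seq_len(Z))))
      if (Z == 1L || effect == 0) lv <- rep(0, Z)
      fac <- pmax(1 + effect * sigma_refc * lv, 0.1)
      c_true <- base * fac[zone] * pmax(1 + stats::rnorm(n, 0, sigma_wc), 0.1)
      sd_c <- 1.3 * c_true
      se_c <- sd_c / sqrt(n_i)
      obs_c <- pmax(c_true + stats::rnorm(n, 0, se_c), 0)
      nm <- paste0("c", k)
      tab[[nm]] <- obs_c
      tab[[paste0(nm, "_moe")]] <- Z90 * se_c
      truth[[paste0("true_", nm)]] <- c_true
      truth[[paste0("sd_", nm)]] <- sd_c
      specs <- dplyr::bind_rows(specs, variable_spec(nm, "count", nm, paste0(nm, "_moe")))
    }

    if (zero_household > 0) {
      zh <- sample(n, min(zero_household, n - 1L))
      tab$households[zh] <- 0
    }

    structure(list(
      table = tab, geometry = lattice_geometry(rows, cols), truth = truth,
      specs = specs, rows = rows, cols = cols
    ), class = "cvr_survey")
  }
  if (is.null(seed)) gen() else with_seed(seed, gen())
}

resolve_zones <- function(zones, rows, cols) {
  if (is.matrix(zones)) {
    if (!all(dim(zones) == c(rows, cols))) {
      stop_cvr("zone matrix must be rows x cols", "cvr_config_error")
    }
    zm <- matrix(match(zones, unique(as.vector(zones))), rows, cols)
  } else if (identical(zones, "quadrant")) {
    rhalf <- (seq_len(rows) > ceiling(rows / 2)) * 2L
    chalf <- as.integer(seq_len(cols) > ceiling(cols / 2))
    zm <- outer(rhalf, chalf, `+`) + 1L
  } else if (identical(zones, "bands")) {
    nb <- min(4L, rows)
    band <- as.integer(cut(seq_len(rows), nb, labels = FALSE))
    zm <- matrix(band, rows, cols)
  } else {
    stop_cvr("zones must be 'quadrant', 'bands', or a rows x cols matrix", "cvr_config_error")
  }
  # every zone must be a connected block of the lattice
  for (z in unique(as.vector(zm))) {
    cells <- which(zm == z, arr.ind = TRUE)
    if (!block_connected(cells, rows, cols)) {
      stop_cvr(paste0("zone ", z, " is not a connected block"), "cvr_config_error")
    }
  }
  zm
}

block_connected <- function(cells, rows, cols) {
  k <- nrow(cells)
  if (k <= 1L) return(TRUE)
  key <- cells[, 1] * (cols + 1L) + cells[, 2]
  seen <- logical(k)
  seen[1] <- TRUE
  stack <- 1L
  found <- 1L
  while (length(stack)) {
    i <- stack[1]
    stack <- stack[-1]
    for (d in list(c(1, 0), c(-1, 0), c(0, 1), c(0, -1))) {
      nk <- (cells[i, 1] + d[1]) * (cols + 1L) + (cells[i, 2] + d[2])
      j <- match(nk, key)
      if (!is.na(j) && !seen[j]) {
        seen[j] <- TRUE
        found <- found + 1L
        stack <- c(stack, j)
      }
    }
  }
  found == k
}

lattice_geometry <- function(rows, cols) {
  ids <- lattice_ids(rows, cols)
  geoms <- vector("list", rows * cols)
  i <- 0L
  for (r in seq_len(rows)) for (c in seq_len(cols)) {
    i <- i + 1L
    x0 <- c - 1; y0 <- rows - r  # row 1 at the top
    ring <- rbind(c(x0, y0), c(x0 + 1, y0), c(x0 + 1, y0 + 1), c(x0, y0 + 1), c(x0, y0))
    geoms[[i]] <- list(list(ring))
  }
  tibble::tibble(area_id = ids, geometry = geoms)
}

#' Degrade the data quality of selected areas
#'
#' Multiplies the margins of error of the listed areas by `factor`,
#' rescaling their recorded sample sizes by `1 / factor^2` so the generated
#' MOE-vs-sample-size consistency is preserved. Used to emulate the
#' tract-to-tract variation in estimate quality seen in real surveys and to
#' verify that only poor-quality areas need merging.
#'
#' @param survey A `cvr_survey`.
#' @param areas Character vector of area ids to degrade.
#' @param factor MOE multiplier, `> 1`.
#' @return The degraded `cvr_survey`.
#' @export
degrade_survey <- function(survey, areas, factor) {
  if (!inherits(survey, "cvr_survey")) stop_cvr("survey must be a cvr_survey", "cvr_contract_error")
  if (!is.numeric(factor) || factor <= 1) stop_cvr("factor must exceed 1", "cvr_config_error")
  if (!length(areas)) return(survey)
  idx <- match(areas, survey$table$area_id)
  if (anyNA(idx)) {
    stop_cvr(paste0("unknown area(s): ", paste(areas[is.na(idx)], collapse = ", ")),
             "cvr_config_error")
  }
  moe_cols <- grep("_moe$|^population_moe$", names(survey$table), value = TRUE)
  for (col in moe_cols) survey$table[[col]][idx] <- survey$table[[col]][idx] * factor
  tidx <- match(areas, survey$truth$area_id)
  survey$truth$n_sample[tidx] <- pmax(1L, as.integer(round(survey$truth$n_sample[tidx] / factor^2)))
  survey
}

#' @export
print.cvr_survey <- function(x, ...) {
  cat("<cvr_survey> ", x$rows, "x", x$cols, " lattice, ",
      max(x$truth$zone), " zones, ", nrow(x$specs), " variables\n", sep = "")
  invisible(x)
}

#' Write a synthetic survey as input files
#'
#' Emits exactly the formats the readers consume — `areas.csv`
#' ([read_area_table()]), `areas.geojson` ([read_geometry()]), a
#' `variables.json` configuration ([read_variable_config()]) — plus
#' `truth.csv` with the planted ground truth.
#'
#' @param survey A `cvr_survey`.
#' @param dir Output directory.
#' @param cv Optional global CV target to embed in the configuration.
#' @return Invisibly, a named vector of file paths.
#' @export
write_survey <- function(survey, dir, cv = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(table = file.path(dir, "areas.csv"),
             geometry = file.path(dir, "areas.geojson"),
             truth = file.path(dir, "truth.csv"),
             config = file.path(dir, "variables.json"))
  utils::write.csv(format_sig(survey$table), paths["table"], row.names = FALSE, quote = FALSE)
  write_geojson(survey$geometry$area_id, survey$geometry$geometry, paths["geometry"])
  utils::write.csv(format_sig(survey$truth), paths["truth"], row.names = FALSE, quote = FALSE)
  vars <- purrr::pmap(survey$specs, function(name, kind, num_est, num_moe, den_est, den_moe,
                                             cv_target) {
    v <- list(kind = kind, num_est = num_est, num_moe = num_moe)
    if (!is.na(den_est)) {
      v$den_est <- den_est
      v$den_moe <- den_moe
    }
    if (!is.na(cv_target)) v$cv_target <- cv_target
    v
  })
  names(vars) <- survey$specs$name
  cfg <- list(variables = vars)
  if (!is.null(cv)) cfg$cv <- cv
  jsonlite::write_json(cfg, paths["config"], auto_unbox = TRUE, digits = NA)
  invisible(paths)
}

#' Planted-zone recovery score of a partition
#'
#' The purity of the regions with respect to the planted zones: each region
#' contributes the size of its largest single-zone contingent, and the score
#' is the total over regions divided by the number of areas. 1 means no
#' region straddles a zone boundary; the expected value under random labels
#' approaches the largest zone share.
#'
#' @param assignment A `cvr_solution`, `cvr_partition`, or assignment data
#'   frame.
#' @param truth The `truth` tibble of a [generate_survey()] result (columns
#'   `area_id`, `zone`).
#' @return A number in `(0, 1]`.
#' @export
recovery_score <- function(assignment, truth) {
  if (inherits(assignment, c("cvr_solution", "cvr_partition"))) {
    assignment <- assignment$assignment
  }
  zone <- truth$zone[match(assignment$area_id, truth$area_id)]
  if (anyNA(zone)) stop_cvr("truth is missing some assigned areas", "cvr_contract_error")
  tab <- table(assignment$region, zone)
  sum(apply(tab, 1, max)) / nrow(assignment)
}
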