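# Preprocessing: the fixed pipeline that turns a raw area table into the
# inputs of the optimizer. Order matters and is enforced by preprocess():
# zero-household areas are dropped first, then zero-estimate MOEs are reset,
# then the per-variable point estimates are z-scored, and finally
# variance-weighted principal component scores are computed. The component
# scores (not the raw attributes) are what the SSD objective compares.

#' Drop areas without households
#'
#' Areas with no households (parks, water, institutional tracts) would force
#' divide-by-zero in derived proportions and carry no survey signal; they are
#' removed before any other step. The contiguity graph must subsequently be
#' restricted to the survivors ([preprocess()] and [regionalize()] do this).
#'
#' @param table An area table.
#' @return The filtered tibble, with the dropped ids in
#'   `attr(, "dropped_areas")`.
#' @export
filter_zero_household <- function(table) {
  if (!"households" %in% names(table)) {
    stop_cvr("area table has no households column", "cvr_config_error")
  }
  drop <- table$area_id[table$households == 0]
  out <- table[table$households > 0, , drop = FALSE]
  if (nrow(out) == 0L) {
    stop_cvr("all areas have zero households: nothing to regionalize", "cvr_config_error")
  }
  attr(out, "dropped_areas") <- drop
  out
}

#' Reset margins of error on zero estimates
#'
#' Published MOEs for zero estimates are a fixed state-level filler value, not
#' a sampling quantity, and can be large (e.g. a count of 0 with an MOE of
#' 89). Every `(estimate = 0, MOE > 0)` cell among the columns referenced by
#' `specs` (and `population`/`population_moe` when present) becomes `(0, 0)`.
#'
#' @param table An area table.
#' @param specs Variable specification tibble.
#' @return The table with resets applied; the number of reset cells is in
#'   `attr(, "n_reset")`.
#' @export
reset_zero_moes <- function(table, specs) {
  validate_specs(specs, table)
  pairs <- unique(rbind(
    data.frame(est = specs$num_est, moe = specs$num_moe),
    stats::na.omit(data.frame(est = specs$den_est, moe = specs$den_moe))
  ))
  if (all(c("population", "population_moe") %in% names(table))) {
    pairs <- unique(rbind(pairs, data.frame(est = "population", moe = "population_moe")))
  }
  n_reset <- 0L
  for (k in seq_len(nrow(pairs))) {
    hit <- table[[pairs$est[k]]] == 0 & table[[pairs$moe[k]]] > 0
    n_reset <- n_reset + sum(hit)
    table[[pairs$moe[k]]][hit] <- 0
  }
  dropped <- attr(table, "dropped_areas")
  attr(table, "n_reset") <- n_reset
  attr(table, "dropped_areas") <- dropped
  table
}

#' Standardize attribute columns to z-scores
#'
#' Attributes arrive on wildly different scales (dollars, shares, counts);
#' deviations entering the SSD objective must be comparable, so every column
#' is centred and scaled to sample standard deviation one (n - 1 denominator).
#'
#' @param x A numeric matrix (areas x attributes).
#' @return The standardized matrix.
#' @export
zscore <- function(x) {
  x <- as.matrix(x)
  if (nrow(x) < 2L) stop_cvr("z-scoring needs at least two areas", "cvr_domain_error")
  sds <- apply(x, 2, stats::sd)
  zero <- sds <= 0 | !is.finite(sds)
  if (any(zero)) {
    nm <- colnames(x)[zero] %||% which(zero)
    stop_cvr(paste0("constant attribute column(s) carry no clustering information: ",
                    paste(nm, collapse = ", ")), "cvr_domain_error")
  }
  scale(x, center = TRUE, scale = sds)[, , drop = FALSE]
}

#' Variance-weighted principal component features
#'
#' Correlated attributes would otherwise count the same information twice in
#' the SSD objective. All principal components of the standardized attributes
#' are retained (capturing 100% of the variance); each component's scores are
#' whitened to unit variance and multiplied by the component's explained
#' variance share `w_c = lambda_c / sum(lambda)`, so a component's maximum
#' possible contribution to the objective is proportional to the variance it
#' explains. Components with eigenvalue below `1e-10` (rank-deficient input)
#' are dropped and the weights renormalized, with a warning.
#'
#' @param z A standardized attribute matrix from [zscore()].
#' @return A `cvr_features` object: `scores` (areas x components, weighted),
#'   `weights` (explained-variance shares, summing to 1).
#' @export
pca_features <- function(z) {
  z <- as.matrix(z)
  if (nrow(z) < ncol(z)) {
    stop_cvr("principal components need at least as many areas as attributes", "cvr_domain_error")
  }
  pc <- stats::prcomp(z, center = FALSE, scale. = FALSE)
  lambda <- pc$sdev^2
  keep <- lambda > 1e-10
  if (!all(keep)) {
    warning("dropping ", sum(!keep), " degenerate principal component(s); weights renormalized")
  }
  lambda <- lambda[keep]
  w <- lambda / sum(lambda)
  scores <- pc$x[, keep, drop = FALSE]
  scores <- sweep(scores, 2, pc$sdev[keep], "/")   # whiten
  scores <- sweep(scores, 2, w, "*")               # variance-share weight
  rownames(scores) <- rownames(z)
  structure(list(scores = scores, weights = w), class = "cvr_features")
}

# per-area point estimates used for clustering: counts verbatim, derived
# variables as their ratio; errors if a retained denominator is nonpositive
attribute_matrix <- function(table, specs) {
  cols <- purrr::pmap(specs, function(name, kind, num_est, num_moe, den_est, den_moe, cv_target) {
    if (kind == "count") return(table[[num_est]])
    den <- table[[den_est]]
    if (any(den <= 0)) {
      stop_cvr(paste0("nonpositive denominator '", den_est, "' for retained area(s): ",
                      paste(table$area_id[den <= 0], collapse = ", ")), "cvr_domain_error")
    }
    table[[num_est]] / den
  })
  m <- do.call(cbind, cols)
  dimnames(m) <- list(table$area_id, specs$name)
  m
}

#' Preprocess an area table for regionalization
#'
#' Runs the fixed pipeline: [filter_zero_household()], [reset_zero_moes()],
#' attribute extraction, [zscore()], [pca_features()]. This is the only path
#' that produces the feature matrix consumed by the optimizer, which is how
#' the pipeline order is enforced. Features are computed once on the full
#' retained table: the objective compares areas in one common space.
#'
#' @param table An area table (see [read_area_table()]).
#' @param specs Variable specification tibble.
#' @return A `cvr_prep` object: the retained `table`, `specs`, `features`,
#'   the raw `attributes` matrix, `dropped` area ids and the `n_reset` count.
#' @export
preprocess <- function(table, specs) {
  specs <- validate_specs(specs, table)
  tab <- filter_zero_household(table)
  dropped <- attr(tab, "dropped_areas")
  tab <- reset_zero_moes(tab, specs)
  n_reset <- attr(tab, "n_reset")
  a <- attribute_matrix(tab, specs)
  feats <- pca_features(zscore(a))
  structure(list(table = tab, specs = specs, features = feats, attributes = a,
                 dropped = dropped, n_reset = n_reset),
            class = "cvr_prep")
}

#' @export
print.cvr_prep <- function(x, ...) {
  cat("<cvr_prep> ", nrow(x$table), " retained areas, ",
      nrow(x$specs), " variables\n", sep = "")
  cat("  dropped (zero households): ", length(x$dropped),
      "; zero-estimate MOE resets: ", x$n_reset, "\n", sep = "")
  cat("  component weights: ", paste(sprintf("%.3f", x$features$weights), collapse = " "),
      "\n", sep = "")
  invisible(x)
}
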