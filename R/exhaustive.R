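# Exhaustive search over all contiguous partitions of a small map. Intended
# for validating the heuristic on instances of at most ~10 areas, where the
# full partition lattice (Bell-number sized) can be enumerated and filtered.

# all set partitions of 1..n as restricted-growth strings (list of int vectors)
all_set_partitions <- function(n) {
  res <- vector("list", 0L)
  rg <- integer(n)
  rec <- function(i, maxb) {
    if (i > n) {
      res[[length(res) + 1L]] <<- rg
      return(invisible())
    }
    for (b in seq_len(maxb + 1L)) {
      rg[i] <<- b
      rec(i + 1L, max(maxb, b))
    }
  }
  rec(1L, 0L)
  res
}

#' Exhaustively solve a small regionalization instance
#'
#' Enumerates every partition of the retained areas into connected regions,
#' keeps the feasible ones (all non-exempt CVs at or below target, population
#' within bounds), and reports the maximum feasible region count `p_star`,
#' the minimum SSD among feasible partitions with `p_star` regions, and the
#' corresponding assignment. Cost grows with the Bell number of the area
#' count; refuse instances above 12 areas.
#'
#' @param table An area table or `cvr_prep`.
#' @param graph A `cvr_graph`.
#' @param specs Variable specs (ignored for a `cvr_prep`).
#' @param constraints A [constraints()] object.
#' @return A list: `p_star`, `min_ssd`, `assignment` (tibble), `n_feasible`,
#'   `n_partitions`.
#' @export
exhaustive_regionalize <- function(table, graph, specs = NULL, constraints) {
  prep <- if (inherits(table, "cvr_prep")) table else preprocess(table, specs)
  prob <- build_problem(prep, graph, constraints)
  if (prob$n > 12L) {
    stop_cvr("exhaustive enumeration is limited to 12 areas", "cvr_config_error")
  }
  parts <- all_set_partitions(prob$n)
  p_star <- 0L
  best <- NULL
  n_feas <- 0L
  for (rg in parts) {
    p <- max(rg)
    blocks <- split(seq_len(prob$n), rg)
    ok <- TRUE
    for (blk in blocks) {
      if (length(blk) > 1L && !connected_without(prob$adj, blk, 0L)) {
        ok <- FALSE
        break
      }
      if (!feasible_idx(prob, blk)) {
        ok <- FALSE
        break
      }
    }
    if (!ok) next
    n_feas <- n_feas + 1L
    s <- ssd_of(rg, prob$F, prob$rowsq)
    if (p > p_star || (p == p_star && s < best$ssd - 1e-12)) {
      p_star <- p
      best <- list(rg = rg, ssd = s)
    }
  }
  if (is.null(best)) {
    stop_cvr("no feasible partition found: relax the CV target or population bounds",
             "cvr_infeasible_error")
  }
  list(
    p_star = p_star,
    min_ssd = best$ssd,
    assignment = tibble::tibble(area_id = prob$ids, region = as.integer(best$rg)),
    n_feasible = n_feas,
    n_partitions = length(parts)
  )
}
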