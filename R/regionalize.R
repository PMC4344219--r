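# The two-phase max-p heuristic.
#
# Phase 1 (repeated n_starts times): pick a random unassigned seed area; if it
# is not feasible on its own, grow it concentrically — consume the current
# frontier ring in uniform-random order, then expand to the next ring — until
# the region is feasible or the frontier is exhausted. Seeds that never reach
# feasibility dissolve back to unassigned. When no further feasible region can
# be seeded, the leftover areas are absorbed, each joining the adjacent region
# whose SSD increase is smallest among regions that stay feasible; an attempt
# with an unabsorbable leftover is discarded. The best partition across
# attempts has the most regions, ties broken by lowest SSD.
#
# Phase 2: tabu search over single-area moves between adjacent regions. A move
# is feasible when the donor stays nonempty and connected and both regions
# stay constraint-feasible (the region count never changes). The best non-tabu
# move is applied each iteration, worsening or not; a tabu move is admitted
# only when it beats the best solution seen (aspiration). Reversing a move is
# tabu for tabu_length iterations. The best solution ever seen is returned.

# --- mutable partition state (environment) ---------------------------------

state_from_reg <- function(prob, reg) {
  p <- max(reg)
  st <- new.env(parent = emptyenv())
  st$reg <- reg
  st$p <- p
  st$members <- lapply(seq_len(p), function(k) which(reg == k))
  st$m <- vapply(st$members, length, integer(1))
  st$SS <- t(vapply(st$members, function(idx) colSums(prob$F[idx, , drop = FALSE]),
                    numeric(prob$C)))
  dim(st$SS) <- c(p, prob$C)
  st$sumsq <- vapply(st$members, function(idx) sum(prob$rowsq[idx]), numeric(1))
  st$SNE <- t(vapply(st$members, function(idx) colSums(prob$NE[idx, , drop = FALSE]),
                     numeric(prob$V)))
  dim(st$SNE) <- c(p, prob$V)
  st$SNSE2 <- t(vapply(st$members, function(idx) colSums(prob$NSE2[idx, , drop = FALSE]),
                       numeric(prob$V)))
  dim(st$SNSE2) <- c(p, prob$V)
  st$SDE <- t(vapply(st$members, function(idx) colSums(prob$DE[idx, , drop = FALSE]),
                     numeric(prob$V)))
  dim(st$SDE) <- c(p, prob$V)
  st$SDSE2 <- t(vapply(st$members, function(idx) colSums(prob$DSE2[idx, , drop = FALSE]),
                       numeric(prob$V)))
  dim(st$SDSE2) <- c(p, prob$V)
  st$spop <- vapply(st$members, function(idx) sum(prob$pop[idx]), numeric(1))
  st$ssd_k <- st$sumsq - rowSums(st$SS^2) / st$m
  st
}

state_ssd <- function(st) sum(st$ssd_k)

delta_add <- function(st, prob, r, a) {
  Snew <- st$SS[r, ] + prob$F[a, ]
  (st$sumsq[r] + prob$rowsq[a] - sum(Snew^2) / (st$m[r] + 1L)) - st$ssd_k[r]
}

delta_remove <- function(st, prob, r, a) {
  Snew <- st$SS[r, ] - prob$F[a, ]
  (st$sumsq[r] - prob$rowsq[a] - sum(Snew^2) / (st$m[r] - 1L)) - st$ssd_k[r]
}

add_area <- function(st, prob, r, a) {
  st$reg[a] <- r
  st$members[[r]] <- c(st$members[[r]], a)
  st$m[r] <- st$m[r] + 1L
  st$SS[r, ] <- st$SS[r, ] + prob$F[a, ]
  st$sumsq[r] <- st$sumsq[r] + prob$rowsq[a]
  st$SNE[r, ] <- st$SNE[r, ] + prob$NE[a, ]
  st$SNSE2[r, ] <- st$SNSE2[r, ] + prob$NSE2[a, ]
  st$SDE[r, ] <- st$SDE[r, ] + prob$DE[a, ]
  st$SDSE2[r, ] <- st$SDSE2[r, ] + prob$DSE2[a, ]
  st$spop[r] <- st$spop[r] + prob$pop[a]
  st$ssd_k[r] <- st$sumsq[r] - sum(st$SS[r, ]^2) / st$m[r]
  invisible(st)
}

remove_area <- function(st, prob, r, a) {
  st$reg[a] <- 0L
  st$members[[r]] <- st$members[[r]][st$members[[r]] != a]
  st$m[r] <- st$m[r] - 1L
  st$SS[r, ] <- st$SS[r, ] - prob$F[a, ]
  st$sumsq[r] <- st$sumsq[r] - prob$rowsq[a]
  st$SNE[r, ] <- st$SNE[r, ] - prob$NE[a, ]
  st$SNSE2[r, ] <- st$SNSE2[r, ] - prob$NSE2[a, ]
  st$SDE[r, ] <- st$SDE[r, ] - prob$DE[a, ]
  st$SDSE2[r, ] <- st$SDSE2[r, ] - prob$DSE2[a, ]
  st$spop[r] <- st$spop[r] - prob$pop[a]
  st$ssd_k[r] <- st$sumsq[r] - sum(st$SS[r, ]^2) / st$m[r]
  invisible(st)
}

region_feasible_sums <- function(prob, st, r) {
  feasible_sums(prob, st$SNE[r, ], st$SNSE2[r, ], st$SDE[r, ], st$SDSE2[r, ], st$spop[r])
}

# --- phase 1 ----------------------------------------------------------------

grow_one_region <- function(prob, assigned, seed) {
  region <- seed
  sums <- list(sne = prob$NE[seed, ], snse2 = prob$NSE2[seed, ],
               sde = prob$DE[seed, ], sdse2 = prob$DSE2[seed, ], spop = prob$pop[seed])
  if (feasible_sums(prob, sums$sne, sums$snse2, sums$sde, sums$sdse2, sums$spop)) {
    return(region)
  }
  visited <- assigned
  visited[seed] <- TRUE
  frontier <- prob$adj[[seed]][!visited[prob$adj[[seed]]]]
  visited[frontier] <- TRUE
  ring <- shuffle(frontier)
  next_ring <- integer()
  while (length(ring)) {
    a <- ring[1L]
    ring <- ring[-1L]
    region <- c(region, a)
    sums$sne <- sums$sne + prob$NE[a, ]
    sums$snse2 <- sums$snse2 + prob$NSE2[a, ]
    sums$sde <- sums$sde + prob$DE[a, ]
    sums$sdse2 <- sums$sdse2 + prob$DSE2[a, ]
    sums$spop <- sums$spop + prob$pop[a]
    if (feasible_sums(prob, sums$sne, sums$snse2, sums$sde, sums$sdse2, sums$spop)) {
      return(region)
    }
    nb <- prob$adj[[a]][!visited[prob$adj[[a]]]]
    if (length(nb)) {
      visited[nb] <- TRUE
      next_ring <- c(next_ring, nb)
    }
    if (!length(ring) && length(next_ring)) {
      ring <- shuffle(next_ring)
      next_ring <- integer()
    }
  }
  NULL
}

grow_partition_int <- function(prob) {
  reg <- integer(prob$n)
  failed <- logical(prob$n)
  nreg <- 0L
  repeat {
    cand <- which(reg == 0L & !failed)
    if (!length(cand)) break
    seed <- sample_one(cand)
    grown <- grow_one_region(prob, reg != 0L, seed)
    if (is.null(grown)) {
      failed[seed] <- TRUE
    } else {
      nreg <- nreg + 1L
      reg[grown] <- nreg
    }
  }
  list(reg = reg, nreg = nreg, leftovers = which(reg == 0L))
}

assign_leftovers_int <- function(prob, st, leftovers) {
  queue <- shuffle(leftovers)
  while (length(queue)) {
    requeue <- integer()
    progress <- FALSE
    for (a in queue) {
      regs <- unique(st$reg[prob$adj[[a]]])
      regs <- regs[regs > 0L]
      if (!length(regs)) {
        requeue <- c(requeue, a)
        next
      }
      best_r <- 0L
      best_d <- Inf
      for (r in regs) {
        ok <- feasible_sums(prob,
                            st$SNE[r, ] + prob$NE[a, ], st$SNSE2[r, ] + prob$NSE2[a, ],
                            st$SDE[r, ] + prob$DE[a, ], st$SDSE2[r, ] + prob$DSE2[a, ],
                            st$spop[r] + prob$pop[a])
        if (ok) {
          d <- delta_add(st, prob, r, a)
          if (d < best_d - 1e-12) {
            best_d <- d
            best_r <- r
          }
        }
      }
      if (best_r == 0L) return(NULL)  # no adjacent region can absorb it feasibly
      add_area(st, prob, best_r, a)
      progress <- TRUE
    }
    if (length(requeue) && !progress) return(NULL)
    queue <- requeue
  }
  st
}

# --- phase 2 ----------------------------------------------------------------

tabu_improve_int <- function(prob, reg, config, counters = NULL) {
  st <- state_from_reg(prob, reg)
  p <- st$p
  tabu_until <- matrix(0L, prob$n, p)
  best_reg <- st$reg
  best_ssd <- state_ssd(st)
  cur_ssd <- best_ssd
  no_improve <- 0L
  accepted <- 0L
  iter <- 0L
  while (iter < config$max_swaps && no_improve < config$no_improve_stop) {
    iter <- iter + 1L
    best_move <- NULL
    best_delta <- Inf
    donor_ok <- rep(NA, prob$n)
    for (a in seq_len(prob$n)) {
      r1 <- st$reg[a]
      nb_regs <- unique(st$reg[prob$adj[[a]]])
      nb_regs <- nb_regs[nb_regs != r1 & nb_regs > 0L]
      if (!length(nb_regs)) next
      if (st$m[r1] == 1L) next  # donor would vanish: region count must not change
      # donor-side checks are independent of the target region
      d_rem <- delta_remove(st, prob, r1, a)
      donor_feasible <- feasible_sums(prob,
                                      st$SNE[r1, ] - prob$NE[a, ], st$SNSE2[r1, ] - prob$NSE2[a, ],
                                      st$SDE[r1, ] - prob$DE[a, ], st$SDSE2[r1, ] - prob$DSE2[a, ],
                                      st$spop[r1] - prob$pop[a])
      if (!donor_feasible) next
      if (!connected_without(prob$adj, st$members[[r1]], a)) next
      for (r2 in sort(nb_regs)) {
        ok <- feasible_sums(prob,
                            st$SNE[r2, ] + prob$NE[a, ], st$SNSE2[r2, ] + prob$NSE2[a, ],
                            st$SDE[r2, ] + prob$DE[a, ], st$SDSE2[r2, ] + prob$DSE2[a, ],
                            st$spop[r2] + prob$pop[a])
        if (!ok) next
        delta <- d_rem + delta_add(st, prob, r2, a)
        is_tabu <- tabu_until[a, r2] >= iter
        aspires <- cur_ssd + delta < best_ssd - 1e-12
        if (is_tabu && !aspires) next
        if (delta < best_delta - 1e-12) {
          best_delta <- delta
          best_move <- c(a, r1, r2)
        }
      }
    }
    if (is.null(best_move)) break
    a <- best_move[1L]; r1 <- best_move[2L]; r2 <- best_move[3L]
    remove_area(st, prob, r1, a)
    add_area(st, prob, r2, a)
    tabu_until[a, r1] <- iter + config$tabu_length
    cur_ssd <- cur_ssd + best_delta
    accepted <- accepted + 1L
    if (cur_ssd < best_ssd - 1e-12) {
      best_ssd <- cur_ssd
      best_reg <- st$reg
      no_improve <- 0L
    } else {
      no_improve <- no_improve + 1L
    }
  }
  list(reg = best_reg, ssd = ssd_of(best_reg, prob$F, prob$rowsq),
       accepted = accepted, iterations = iter)
}

# --- driver -----------------------------------------------------------------

#' Select the best partition from a candidate set
#'
#' The best partition is the one with the most regions; ties are broken by the
#' lowest SSD, remaining ties by earliest candidate.
#'
#' @param candidates A nonempty list of objects with `n_regions` and `ssd`
#'   elements (e.g. `cvr_partition` or `cvr_solution` objects).
#' @return The selected element.
#' @export
best_partition <- function(candidates) {
  if (!length(candidates)) {
    stop_cvr("no feasible partition found: relax the CV target or population bounds",
             "cvr_infeasible_error")
  }
  p <- vapply(candidates, function(x) as.numeric(x$n_regions), numeric(1))
  s <- vapply(candidates, function(x) as.numeric(x$ssd), numeric(1))
  top <- which(p == max(p))
  candidates[[top[which.min(s[top])]]]
}

#' Within-region sum of squared deviations
#'
#' The homogeneity objective: the sum over regions, members and feature
#' columns of the squared deviation of the member's (variance-weighted
#' principal component) score from the region mean.
#'
#' @param assignment A data frame with columns `area_id` and `region`, or a
#'   `cvr_partition`/`cvr_solution`.
#' @param features A `cvr_features` object from [pca_features()] (or a plain
#'   numeric matrix with `area_id` rownames).
#' @return Nonnegative numeric scalar.
#' @export
ssd <- function(assignment, features) {
  if (inherits(assignment, c("cvr_partition", "cvr_solution"))) {
    assignment <- assignment$assignment
  }
  F <- if (inherits(features, "cvr_features")) features$scores else as.matrix(features)
  idx <- match(assignment$area_id, rownames(F))
  if (anyNA(idx)) stop_cvr("assignment contains areas missing from the feature matrix",
                           "cvr_contract_error")
  reg <- as.integer(factor(assignment$region))
  ssd_of(reg, F[idx, , drop = FALSE])
}

#' Regionalize an area table under uncertainty constraints
#'
#' Runs the full two-phase heuristic: `n_starts` independent randomized
#' grow-and-absorb attempts, selection of the best feasible partition (most
#' regions, then lowest SSD), then tabu-search swap refinement of the SSD
#' objective. Identical inputs, configuration and seed reproduce the result
#' exactly.
#'
#' @param table An area table, or a `cvr_prep` from [preprocess()] (a raw
#'   table is preprocessed internally).
#' @param graph A `cvr_graph` covering at least the retained areas.
#' @param specs Variable specification tibble (ignored when `table` is a
#'   `cvr_prep`).
#' @param constraints A [constraints()] object.
#' @param config A [region_config()].
#' @return A `cvr_solution`: `assignment` (tibble `area_id`, `region`),
#'   `region_table` (per region and variable: estimate, SE, MOE, CV,
#'   exemption), `regions` (per-region summary), `ssd`, `n_regions`,
#'   `phase1_candidates`, `swaps_accepted`, plus the inputs needed to replay.
#' @export
regionalize <- function(table, graph, specs = NULL, constraints, config = region_config()) {
  prep <- if (inherits(table, "cvr_prep")) table else preprocess(table, specs)
  prob <- build_problem(prep, graph, constraints)
  res <- with_seed(config$seed, {
    best <- NULL
    n_feasible <- 0L
    for (s in seq_len(config$n_starts)) {
      g <- grow_partition_int(prob)
      if (g$nreg == 0L) next
      if (length(g$leftovers)) {
        reg_part <- g$reg
        st <- state_from_partial(prob, reg_part, g$nreg)
        st <- assign_leftovers_int(prob, st, g$leftovers)
        if (is.null(st)) next
        reg <- st$reg
      } else {
        reg <- g$reg
      }
      n_feasible <- n_feasible + 1L
      cand_ssd <- ssd_of(reg, prob$F, prob$rowsq)
      if (is.null(best) || g$nreg > best$nreg ||
          (g$nreg == best$nreg && cand_ssd < best$ssd - 1e-12)) {
        best <- list(reg = reg, nreg = g$nreg, ssd = cand_ssd)
      }
    }
    if (is.null(best)) {
      stop_cvr("no feasible partition found: relax the CV target or population bounds",
               "cvr_infeasible_error")
    }
    tb <- tabu_improve_int(prob, best$reg, config)
    list(reg = tb$reg, nreg = best$nreg, ssd = tb$ssd,
         phase1 = n_feasible, accepted = tb$accepted)
  })
  build_solution(prep, graph, constraints, config, res)
}

# partial state where some areas are unassigned (reg == 0): region sums only
state_from_partial <- function(prob, reg, p) {
  st <- new.env(parent = emptyenv())
  st$reg <- reg
  st$p <- p
  st$members <- lapply(seq_len(p), function(k) which(reg == k))
  st$m <- vapply(st$members, length, integer(1))
  colsum_or_zero <- function(M, idx) {
    if (length(idx)) colSums(M[idx, , drop = FALSE]) else numeric(ncol(M))
  }
  st$SS <- do.call(rbind, lapply(st$members, function(i) colsum_or_zero(prob$F, i)))
  st$sumsq <- vapply(st$members, function(i) sum(prob$rowsq[i]), numeric(1))
  st$SNE <- do.call(rbind, lapply(st$members, function(i) colsum_or_zero(prob$NE, i)))
  st$SNSE2 <- do.call(rbind, lapply(st$members, function(i) colsum_or_zero(prob$NSE2, i)))
  st$SDE <- do.call(rbind, lapply(st$members, function(i) colsum_or_zero(prob$DE, i)))
  st$SDSE2 <- do.call(rbind, lapply(st$members, function(i) colsum_or_zero(prob$DSE2, i)))
  st$spop <- vapply(st$members, function(i) sum(prob$pop[i]), numeric(1))
  st$ssd_k <- st$sumsq - rowSums(st$SS^2) / st$m
  st
}

#' Refine a solution with tabu search
#'
#' Re-runs phase 2 on an existing solution (for example with a different tabu
#' configuration). The returned SSD is never worse and the region count never
#' changes.
#'
#' @param solution A `cvr_solution` from [regionalize()].
#' @param config A [region_config()]; defaults to the solution's own.
#' @return A refined `cvr_solution`.
#' @export
tabu_improve <- function(solution, config = solution$config) {
  if (!inherits(solution, "cvr_solution")) {
    stop_cvr("solution must come from regionalize()", "cvr_contract_error")
  }
  prob <- build_problem(solution$prep, solution$graph, solution$constraints)
  reg <- solution$assignment$region[match(prob$ids, solution$assignment$area_id)]
  res <- with_seed(config$seed, tabu_improve_int(prob, as.integer(reg), config))
  build_solution(solution$prep, solution$graph, solution$constraints, config,
                 list(reg = res$reg, nreg = max(res$reg), ssd = res$ssd,
                      phase1 = solution$phase1_candidates, accepted = res$accepted))
}

build_solution <- function(prep, graph, constraints, config, res) {
  ids <- prep$table$area_id
  # relabel regions densely in order of first appearance (cosmetic)
  lab <- match(res$reg, unique(res$reg))
  assignment <- tibble::tibble(area_id = ids, region = as.integer(lab))
  region_tab <- purrr::map_dfr(sort(unique(lab)), function(k) {
    members <- ids[lab == k]
    rt <- region_cv_table(prep$table, members, prep$specs)
    rt$region <- k
    rt
  })
  region_tab <- dplyr::relocate(region_tab, "region")
  regions <- assignment |>
    dplyr::count(.data$region, name = "n_areas") |>
    dplyr::left_join(
      tibble::tibble(region = as.integer(lab),
                     population = if ("population" %in% names(prep$table)) {
                       prep$table$population
                     } else NA_real_) |>
        dplyr::group_by(.data$region) |>
        dplyr::summarise(population = sum(.data$population)),
      by = "region"
    )
  targets <- ifelse(is.na(prep$specs$cv_target), constraints$cv %||% NA_real_,
                    prep$specs$cv_target)
  region_tab$cv_target <- targets[match(region_tab$variable, prep$specs$name)]
  structure(list(
    assignment = assignment,
    region_table = region_tab,
    regions = regions,
    ssd = res$ssd,
    n_regions = max(lab),
    phase1_candidates = res$phase1,
    swaps_accepted = res$accepted,
    n_exempt = sum(region_tab$exempt),
    n_fallback = sum(region_tab$fallback),
    config = config,
    constraints = constraints,
    prep = prep,
    graph = graph
  ), class = "cvr_solution")
}

#' @export
print.cvr_solution <- function(x, ...) {
  cat("<cvr_solution> ", nrow(x$assignment), " areas -> ", x$n_regions,
      " regions (", sprintf("%.2f", nrow(x$assignment) / x$n_regions),
      " areas/region)\n", sep = "")
  cat("  SSD: ", format(x$ssd, digits = 6),
      "; phase-1 feasible attempts: ", x$phase1_candidates,
      "; swaps accepted: ", x$swaps_accepted, "\n", sep = "")
  cat("  exempt region-variable cells: ", x$n_exempt,
      "; proportion-formula fallbacks: ", x$n_fallback, "\n", sep = "")
  invisible(x)
}
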