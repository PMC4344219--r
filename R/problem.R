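# Internal problem representation for the optimizer: integer-indexed
# adjacency, per-variable numerator/denominator estimate and SE vectors, CV
# targets, population bounds, and the weighted feature matrix. All hot-path
# feasibility checks run on running sums over these arrays; the user-facing
# region_cv_table() is the reference implementation the tests compare against.

build_problem <- function(prep, graph, constraints) {
  if (!inherits(prep, "cvr_prep")) stop_cvr("prep must come from preprocess()", "cvr_contract_error")
  if (!inherits(constraints, "cvr_constraints")) {
    stop_cvr("constraints must come from constraints()", "cvr_config_error")
  }
  tab <- prep$table
  specs <- prep$specs
  ids <- tab$area_id
  n <- length(ids)
  g <- restrict_graph(graph, ids)
  adj <- adjacency_index(g, ids)

  targets <- ifelse(is.na(specs$cv_target), constraints$cv %||% NA_real_, specs$cv_target)
  if (anyNA(targets)) {
    stop_cvr("no CV target for variable(s): supply constraints(cv=) or per-variable cv_target",
             "cvr_config_error")
  }
  V <- nrow(specs)
  kind <- match(specs$kind, c("count", "proportion", "mean")) # 1,2,3
  NE <- matrix(0, n, V); NSE2 <- matrix(0, n, V)
  DE <- matrix(0, n, V); DSE2 <- matrix(0, n, V)
  for (v in seq_len(V)) {
    NE[, v] <- tab[[specs$num_est[v]]]
    NSE2[, v] <- (tab[[specs$num_moe[v]]] / Z90)^2
    if (kind[v] > 1L) {
      DE[, v] <- tab[[specs$den_est[v]]]
      DSE2[, v] <- (tab[[specs$den_moe[v]]] / Z90)^2
    }
  }

  need_pop <- !is.null(constraints$pop_min) || !is.null(constraints$pop_max)
  if (need_pop && !"population" %in% names(tab)) {
    stop_cvr("population constraints require a population column", "cvr_config_error")
  }
  pop <- if ("population" %in% names(tab)) tab$population else rep(0, n)

  F <- prep$features$scores
  stopifnot(nrow(F) == n)

  list(
    ids = ids, n = n, adj = adj, V = V, kind = kind,
    NE = NE, NSE2 = NSE2, DE = DE, DSE2 = DSE2,
    targets = targets, pop = pop,
    pmin = constraints$pop_min %||% -Inf, pmax = constraints$pop_max %||% Inf,
    F = F, rowsq = rowSums(F^2), C = ncol(F)
  )
}

# vectorized over variables; sums are length-V vectors
feasible_sums <- function(prob, sne, snse2, sde, sdse2, spop) {
  if (spop < prob$pmin - 1e-9 || spop > prob$pmax + 1e-9) return(FALSE)
  kind <- prob$kind
  # running-sum updates can leave tiny negatives by floating cancellation
  sne <- pmax(sne, 0)
  snse2 <- pmax(snse2, 0)
  sdse2 <- pmax(sdse2, 0)
  est <- sne
  se2 <- snse2
  derived <- kind > 1L
  if (any(derived)) {
    d <- sde[derived]
    if (any(d <= 0)) return(FALSE)
    p <- sne[derived] / d
    rad <- snse2[derived] - p^2 * sdse2[derived]
    plus <- snse2[derived] + p^2 * sdse2[derived]
    rad <- pmax(ifelse(kind[derived] == 3L | rad < 0, plus, rad), 0)
    est[derived] <- p
    se2[derived] <- rad / d^2
  }
  cvv <- ifelse(est > 0, sqrt(se2) / est, ifelse(se2 > 0, Inf, 0))
  exempt <- kind == 2L & est < 0.05
  all(exempt | cvv <= prob$targets + 1e-12)
}

region_sums <- function(prob, idx) {
  if (length(idx) == 1L) {
    list(sne = prob$NE[idx, ], snse2 = prob$NSE2[idx, ],
         sde = prob$DE[idx, ], sdse2 = prob$DSE2[idx, ], spop = prob$pop[idx])
  } else {
    list(sne = colSums(prob$NE[idx, , drop = FALSE]),
         snse2 = colSums(prob$NSE2[idx, , drop = FALSE]),
         sde = colSums(prob$DE[idx, , drop = FALSE]),
         sdse2 = colSums(prob$DSE2[idx, , drop = FALSE]),
         spop = sum(prob$pop[idx]))
  }
}

feasible_idx <- function(prob, idx) {
  s <- region_sums(prob, idx)
  feasible_sums(prob, s$sne, s$snse2, s$sde, s$sdse2, s$spop)
}

# is `members` minus `drop` still connected? BFS on the induced subgraph
connected_without <- function(adj, members, drop) {
  rest <- members[members != drop]
  k <- length(rest)
  if (k <= 1L) return(TRUE)
  inset <- logical(length(adj))
  inset[rest] <- TRUE
  seen <- logical(length(adj))
  stack <- rest[1]
  seen[rest[1]] <- TRUE
  found <- 1L
  while (length(stack)) {
    u <- stack[[1]]
    stack <- stack[-1]
    for (w in adj[[u]]) {
      if (inset[w] && !seen[w]) {
        seen[w] <- TRUE
        found <- found + 1L
        stack <- c(stack, w)
      }
    }
  }
  found == k
}

# total within-region sum of squared deviations for an integer assignment
ssd_of <- function(reg, F, rowsq = rowSums(F^2)) {
  tot <- 0
  for (k in unique(reg)) {
    idx <- which(reg == k)
    S <- colSums(F[idx, , drop = FALSE])
    tot <- tot + sum(rowsq[idx]) - sum(S^2) / length(idx)
  }
  tot
}

#' Is a candidate region feasible?
#'
#' A region is feasible when every non-exempt variable's region-level CV is at
#' or below its target and the region population lies within the configured
#' bounds. Proportion variables whose region-level estimate is below 5% are
#' exempt from the CV constraint.
#'
#' @param table An area table.
#' @param region Character vector of member `area_id`s.
#' @param specs Variable specification tibble.
#' @param constraints A [constraints()] object.
#' @return Logical scalar with a per-variable report in `attr(, "report")`.
#' @export
region_feasible <- function(table, region, specs, constraints) {
  rep <- region_cv_table(table, region, specs)
  targets <- ifelse(is.na(specs$cv_target), constraints$cv %||% NA_real_, specs$cv_target)
  if (anyNA(targets)) stop_cvr("no CV target defined for every variable", "cvr_config_error")
  rep$cv_target <- targets
  rep$pass <- rep$exempt | (is.finite(rep$cv) & rep$cv <= targets + 1e-12)
  rep$pass[is.nan(rep$estimate)] <- FALSE  # undefined aggregate denominator
  pop_ok <- TRUE
  if (!is.null(constraints$pop_min) || !is.null(constraints$pop_max)) {
    if (!"population" %in% names(table)) {
      stop_cvr("population constraints require a population column", "cvr_config_error")
    }
    spop <- sum(table$population[match(region, table$area_id)])
    pop_ok <- spop >= (constraints$pop_min %||% -Inf) && spop <= (constraints$pop_max %||% Inf)
  }
  out <- all(rep$pass) && pop_ok
  attr(out, "report") <- rep
  out
}
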