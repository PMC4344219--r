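# the two-phase max-p heuristic

loose <- function(cv = 10) constraints(cv = cv)

test_that("region_feasible reports per-variable passes and names violations", {
  sv <- generate_survey(3, 3, seed = 2)
  cons <- constraints(cv = 0.40, specs = sv$specs)
  ok <- region_feasible(sv$table, sv$table$area_id[1], sv$specs, cons)
  rep <- attr(ok, "report")
  expect_equal(nrow(rep), 5)
  expect_equal(ok, all(rep$pass), ignore_attr = TRUE)

  tight <- constraints(cv = 0.001, specs = sv$specs)
  bad <- region_feasible(sv$table, sv$table$area_id[1], sv$specs, tight)
  expect_false(as.logical(bad))
  expect_true(any(!attr(bad, "report")$pass))
})

test_that("a region violating only an exempt small proportion is feasible", {
  tab <- tibble::tibble(
    area_id = c("a", "b"), households = 10,
    population = c(1000, 1000), population_moe = c(10, 10),
    rare_num = c(10, 15), rare_num_moe = c(40, 40)
  )
  specs <- variable_spec("rare", "proportion", "rare_num", "rare_num_moe",
                         "population", "population_moe")
  cons <- constraints(cv = 0.10, specs = specs)
  rt <- region_cv_table(tab, c("a", "b"), specs)
  expect_gt(rt$cv, 0.10)     # the CV itself is way over target
  expect_true(rt$exempt)     # but the 1.25% estimate is exempt
  expect_true(as.logical(region_feasible(tab, c("a", "b"), specs, cons)))
})

test_that("individually feasible areas stay singletons", {
  sv <- generate_survey(2, 2, seed = 21, mean_sample = 1e5, n_proportions = 3)
  sol <- regionalize(sv$table, lattice_contiguity(2, 2), sv$specs,
                     constraints = constraints(cv = 0.25, specs = sv$specs),
                     config = region_config(n_starts = 5, seed = 1))
  expect_equal(sol$n_regions, 4)
})

test_that("a two-area instance feasible only as a pair yields one region", {
  tab <- count_table(est = c(100, 104), moe = 1.645 * c(30, 30), ids = c("a", "b"))
  g <- chain_graph(c("a", "b"))
  sol <- regionalize(tab, g, count_specs(), constraints = constraints(cv = 0.25),
                     config = region_config(n_starts = 5, seed = 2))
  expect_equal(sol$n_regions, 1)
  expect_equal(sort(sol$assignment$region), c(1, 1))
})

test_that("when no region of fewer than 3 areas is feasible, none is produced", {
  set.seed(3)
  est <- round(runif(9, 95, 110), 1)
  tab <- count_table(est = est, moe = 1.645 * 30)
  specs <- count_specs()
  # oracle: every single and pair exceeds the target
  for (i in 1:9) expect_gt(naive_region_cv(tab, tab$area_id[i], specs)$cv, 0.18)
  g <- lattice_contiguity(3, 3)
  for (k in seq_len(nrow(g$edges))) {
    pair <- c(g$edges$from[k], g$edges$to[k])
    expect_gt(naive_region_cv(tab, pair, specs)$cv, 0.18)
  }
  sol <- regionalize(tab, g, specs, constraints = constraints(cv = 0.18),
                     config = region_config(n_starts = 30, seed = 4))
  expect_true(all(table(sol$assignment$region) >= 3))
  expect_regions_connected(sol$assignment, g)
})

test_that("leftovers join the feasible neighbour with least SSD increase", {
  tab <- count_table(est = c(10, 12, 20), moe = c(1, 1, 1), ids = c("a", "b", "c"))
  g <- chain_graph(c("a", "b", "c"))
  prep <- preprocess(tab, count_specs())
  prob <- cvregion:::build_problem(prep, g, loose())
  st <- cvregion:::state_from_partial(prob, c(1L, 0L, 2L), 2L)
  got <- cvregion:::assign_leftovers_int(prob, st, 2L)
  expect_false(is.null(got))
  expect_equal(got$reg, c(1L, 1L, 2L))  # b is closer to a than to c
  # oracle: evaluating both merges directly
  F <- prep$features$scores
  d_left <- naive_ssd(data.frame(area_id = c("a", "b"), region = 1), F)
  d_right <- naive_ssd(data.frame(area_id = c("b", "c"), region = 1), F)
  expect_lt(d_left, d_right)
})

test_that("a leftover that breaks every neighbour's population cap fails the attempt", {
  tab <- count_table(est = c(10, 12, 20), moe = c(1, 1, 1), ids = c("a", "b", "c"),
                     population = c(500, 200, 500))
  g <- chain_graph(c("a", "b", "c"))
  prep <- preprocess(tab, count_specs())
  cons <- constraints(cv = 10, pop_max = 600)
  prob <- cvregion:::build_problem(prep, g, cons)
  st <- cvregion:::state_from_partial(prob, c(1L, 0L, 2L), 2L)
  expect_null(cvregion:::assign_leftovers_int(prob, st, 2L))
})

test_that("best_partition maximizes regions then minimizes SSD, stably", {
  a <- list(n_regions = 5, ssd = 9, tag = "a")
  b <- list(n_regions = 4, ssd = 1, tag = "b")
  c_ <- list(n_regions = 5, ssd = 3, tag = "c")
  c2 <- list(n_regions = 5, ssd = 3, tag = "c2")
  expect_equal(best_partition(list(a, b))$tag, "a")
  expect_equal(best_partition(list(a, c_))$tag, "c")
  expect_equal(best_partition(list(c_, c2))$tag, "c")
  expect_equal(best_partition(list(b))$tag, "b")
  expect_error(best_partition(list()), "relax")
})

test_that("ssd matches hand arithmetic and a brute-force oracle", {
  F1 <- matrix(c(0, 2), ncol = 1, dimnames = list(c("a", "b"), NULL))
  one <- tibble::tibble(area_id = c("a", "b"), region = 1)
  expect_equal(ssd(one, F1), 2)
  singletons <- tibble::tibble(area_id = c("a", "b"), region = 1:2)
  expect_equal(ssd(singletons, F1), 0)

  sv <- generate_survey(3, 4, seed = 23)
  prep <- preprocess(sv$table, sv$specs)
  set.seed(24)
  asg <- tibble::tibble(area_id = sv$table$area_id, region = sample(1:4, 12, replace = TRUE))
  expect_equal(ssd(asg, prep$features), naive_ssd(asg, prep$features$scores),
               tolerance = 1e-10)
})

test_that("tabu search recovers a planted split on a 4-chain", {
  tab <- count_table(est = c(10, 11, 30, 31), moe = rep(0.5, 4),
                     ids = c("a", "b", "c", "d"))
  g <- chain_graph(c("a", "b", "c", "d"))
  prep <- preprocess(tab, count_specs())
  prob <- cvregion:::build_problem(prep, g, loose())
  # oracle: the three contiguous 2-splits
  F <- prep$features$scores
  splits <- list(c(1, 2, 2, 2), c(1, 1, 2, 2), c(1, 1, 1, 2))
  ssds <- vapply(splits, function(rg) {
    naive_ssd(data.frame(area_id = tab$area_id, region = rg), F)
  }, numeric(1))
  expect_equal(which.min(ssds), 2L)
  res <- cvregion:::tabu_improve_int(prob, c(1L, 2L, 2L, 2L), region_config(seed = 1))
  expect_equal(res$reg, c(1L, 1L, 2L, 2L))
  expect_equal(res$ssd, min(ssds), tolerance = 1e-12)
})

test_that("tabu search leaves an enumerated optimum unchanged", {
  sv <- generate_survey(2, 2, seed = 26, n_proportions = 3)
  g <- lattice_contiguity(2, 2)
  prep <- preprocess(sv$table, sv$specs)
  prob <- cvregion:::build_problem(prep, g, constraints(cv = 10, specs = sv$specs))
  F <- prep$features$scores
  ids <- sv$table$area_id
  best <- NULL
  for (rg in oracle_set_partitions(4)) {
    if (max(rg) != 2) next  # all regions of a queen 2x2 are connected
    s <- naive_ssd(data.frame(area_id = ids, region = rg), F)
    if (is.null(best) || s < best$ssd) best <- list(rg = rg, ssd = s)
  }
  res <- cvregion:::tabu_improve_int(prob, as.integer(best$rg), region_config(seed = 1))
  expect_equal(res$ssd, best$ssd, tolerance = 1e-12)
})

test_that("phase 2 never worsens SSD or changes the region count", {
  sv <- generate_survey(5, 5, seed = 27)
  g <- lattice_contiguity(5, 5)
  cons <- constraints(cv = 0.10, specs = sv$specs)
  sol <- regionalize(sv$table, g, sv$specs, cons,
                     config = region_config(n_starts = 10, seed = 5, no_improve_stop = 50))
  again <- tabu_improve(sol, region_config(n_starts = 1, seed = 6, no_improve_stop = 100))
  expect_lte(again$ssd, sol$ssd + 1e-12)
  expect_equal(again$n_regions, sol$n_regions)
})

test_that("identical config and seed reproduce the assignment exactly", {
  sv <- generate_survey(4, 4, seed = 28)
  g <- lattice_contiguity(4, 4)
  cons <- constraints(cv = 0.12, specs = sv$specs)
  cfg <- region_config(n_starts = 10, seed = 9, no_improve_stop = 50)
  s1 <- regionalize(sv$table, g, sv$specs, cons, cfg)
  s2 <- regionalize(sv$table, g, sv$specs, cons, cfg)
  expect_identical(s1$assignment, s2$assignment)
  expect_identical(s1$ssd, s2$ssd)
})

test_that("looser CV targets give near-singleton regions; tighter give fewer regions", {
  sv <- generate_survey(6, 6, seed = 29)
  g <- lattice_contiguity(6, 6)
  cfg <- region_config(n_starts = 10, seed = 3, no_improve_stop = 50)
  sol_loose <- regionalize(sv$table, g, sv$specs,
                           constraints(cv = 0.40, specs = sv$specs), cfg)
  sol_tight <- regionalize(sv$table, g, sv$specs,
                           constraints(cv = 0.10, specs = sv$specs), cfg)
  expect_lt(areas_per_region(sol_loose), 1.5)
  expect_lt(sol_tight$n_regions, sol_loose$n_regions)
})

test_that("cached SSD equals a from-scratch recomputation", {
  sv <- generate_survey(4, 4, seed = 30)
  g <- lattice_contiguity(4, 4)
  sol <- regionalize(sv$table, g, sv$specs, constraints(cv = 0.12, specs = sv$specs),
                     config = region_config(n_starts = 10, seed = 2, no_improve_stop = 50))
  expect_equal(sol$ssd, naive_ssd(sol$assignment, sol$prep$features$scores),
               tolerance = 1e-9)
})

test_that("an impossible target raises the infeasibility error", {
  sv <- generate_survey(2, 2, seed = 31, n_proportions = 3)
  expect_error(
    regionalize(sv$table, lattice_contiguity(2, 2), sv$specs,
                constraints(cv = 1e-6, specs = sv$specs),
                config = region_config(n_starts = 3, seed = 1)),
    class = "cvr_infeasible_error"
  )
})

test_that("degraded areas are the ones that get merged", {
  sv <- generate_survey(6, 6, seed = 32, effect = 0, mean_sample = 2000)
  corner <- sv$table$area_id[c(1, 2, 7, 8)]  # 2x2 top-left block
  bad <- degrade_survey(sv, corner, factor = 8)
  sol <- regionalize(bad$table, lattice_contiguity(6, 6), bad$specs,
                     constraints(cv = 0.10, specs = bad$specs),
                     config = region_config(n_starts = 15, seed = 7, no_improve_stop = 50))
  sizes <- table(sol$assignment$region)
  multi <- as.integer(names(sizes)[sizes > 1])
  expect_gt(length(multi), 0)
  for (k in multi) {
    members <- sol$assignment$area_id[sol$assignment$region == k]
    expect_true(any(members %in% corner))
  }
})
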