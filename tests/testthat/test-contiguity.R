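# polygon adjacency, adjacency files, island repair

test_that("queen and rook edge counts on small lattices match the closed form", {
  for (R in 2:4) for (C in 2:4) {
    geom <- cvregion:::lattice_geometry(R, C)
    queen <- build_contiguity(geom, "queen")
    rook <- build_contiguity(geom, "rook")
    rook_expect <- (R - 1) * C + R * (C - 1)
    expect_equal(nrow(rook$edges), rook_expect)
    expect_equal(nrow(queen$edges), rook_expect + 2 * (R - 1) * (C - 1))
  }
})

test_that("2x2 and 3x3 lattices have the known queen topology", {
  expect_equal(nrow(build_contiguity(cvregion:::lattice_geometry(2, 2))$edges), 6)
  expect_equal(nrow(build_contiguity(cvregion:::lattice_geometry(3, 3))$edges), 20)
})

test_that("geometric adjacency matches a brute-force box-intersection oracle", {
  R <- 3; C <- 4
  geom <- cvregion:::lattice_geometry(R, C)
  corners <- expand.grid(c = 0:(C - 1), r = 0:(R - 1))
  queen <- build_contiguity(geom, "queen")
  rook <- build_contiguity(geom, "rook")
  key <- function(g) paste(pmin(g$edges$from, g$edges$to), pmax(g$edges$from, g$edges$to))
  want_q <- character(); want_r <- character()
  for (i in 1:(R * C - 1)) for (j in (i + 1):(R * C)) {
    rel <- squares_relation(c(corners$c[i], corners$r[i]), c(corners$c[j], corners$r[j]))
    pair <- paste(pmin(geom$area_id[i], geom$area_id[j]), pmax(geom$area_id[i], geom$area_id[j]))
    if (rel %in% c("edge", "point")) want_q <- c(want_q, pair)
    if (rel == "edge") want_r <- c(want_r, pair)
  }
  expect_setequal(key(queen), want_q)
  expect_setequal(key(rook), want_r)
  # and the analytic lattice graph agrees with the geometric one
  expect_setequal(key(lattice_contiguity(R, C)), key(queen))
})

test_that("disjoint squares produce no edges and two components", {
  geom <- tibble::tibble(
    area_id = c("a", "b"),
    geometry = list(
      list(list(rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1), c(0, 0)))),
      list(list(rbind(c(5, 5), c(6, 5), c(6, 6), c(5, 6), c(5, 5))))
    )
  )
  g <- build_contiguity(geom)
  expect_equal(nrow(g$edges), 0)
  expect_equal(max(graph_components(g)$component), 2)
})

test_that("duplicate ids and invalid rings are rejected by name", {
  geom <- cvregion:::lattice_geometry(2, 2)
  dup <- geom
  dup$area_id[2] <- dup$area_id[1]
  expect_error(contiguity_graph(dup$area_id), "duplicate")
  dir <- withr::local_tempdir()
  p <- file.path(dir, "bad.geojson")
  jsonlite::write_json(list(
    type = "FeatureCollection",
    features = list(list(
      type = "Feature", properties = list(area_id = "brokenA"),
      geometry = list(type = "Polygon",
                      coordinates = list(list(c(0, 0), c(1, 0), c(1, 1))))
    ))
  ), p, auto_unbox = TRUE, digits = NA)
  expect_error(read_geometry(p), "brokenA")
})

test_that("geometry writing and reading round-trip", {
  sv <- generate_survey(2, 3, seed = 3)
  dir <- withr::local_tempdir()
  paths <- write_survey(sv, dir)
  geom <- read_geometry(paths[["geometry"]])
  expect_equal(geom$area_id, sv$geometry$area_id)
  expect_equal(geom$geometry[[4]][[1]][[1]], sv$geometry$geometry[[4]][[1]][[1]])
  g <- build_contiguity(geom)
  expect_equal(nrow(g$edges), nrow(lattice_contiguity(2, 3)$edges))
})

test_that("adjacency files symmetrize and validate", {
  dir <- withr::local_tempdir()
  f <- file.path(dir, "adj.txt")
  writeLines(c("A B", "B C"), f)
  g <- read_adjacency(f, c("A", "B", "C", "D"))
  expect_equal(nrow(g$edges), 2)
  expect_equal(length(g$nodes), 4)

  writeLines(c("A B", "B  A"), f)
  g2 <- read_adjacency(f, c("A", "B"))
  expect_equal(nrow(g2$edges), 1)

  writeLines(character(), f)
  g3 <- read_adjacency(f, c("A", "B"))
  expect_equal(nrow(g3$edges), 0)
  expect_equal(g3$nodes, c("A", "B"))

  writeLines("A Z", f)
  expect_error(read_adjacency(f, c("A", "B")), "unknown")
  writeLines("A A", f)
  expect_error(read_adjacency(f, c("A", "B")), "self")
})

test_that("island repair bridges, drops, and stays symmetric", {
  g <- contiguity_graph(c("a", "b", "c", "d"),
                        tibble::tibble(from = c("a", "c"), to = c("b", "d")))
  expect_equal(max(graph_components(g)$component), 2)
  fixed <- repair_islands(g, add_links = data.frame(from = "b", to = "c"))
  expect_equal(max(graph_components(fixed)$component), 1)
  expect_equal(attr(fixed, "components")$n_areas, 4L)

  g2 <- contiguity_graph(c("a", "b", "s"), tibble::tibble(from = "a", to = "b"))
  dropped <- repair_islands(g2, drop_areas = "s")
  expect_equal(max(graph_components(dropped)$component), 1)

  same <- repair_islands(g)
  expect_equal(same$edges, g$edges)
  expect_equal(same$nodes, g$nodes)

  expect_error(repair_islands(g, add_links = data.frame(from = "a", to = "d"),
                              drop_areas = "d"), "dropped")
  # symmetry: normalized storage means no (x, y) with a separate (y, x)
  e <- fixed$edges
  expect_true(all(e$from <= e$to))
  expect_false(any(duplicated(paste(e$from, e$to))))
})
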