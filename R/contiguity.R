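# Contiguity graphs: which areas touch which. A region must induce a connected
# subgraph of this graph. Queen contiguity (sharing any boundary point,
# including a single corner) is the default; rook (sharing a boundary segment
# of positive length) is available. Geometry handling is a lightweight planar
# toolkit for polygon collections whose members tile the plane (census-style
# tract polygons, lattices): vertex/edge sharing with a coordinate tolerance.

COORD_TOL <- 1e-8

#' Construct a contiguity graph from an edge list
#'
#' @param nodes Character vector of area ids (isolated nodes allowed).
#' @param edges A two-column data frame (`from`, `to`) of unordered adjacent
#'   pairs; duplicates and orientation are normalized away.
#' @return A `cvr_graph` object.
#' @export
contiguity_graph <- function(nodes, edges = NULL) {
  nodes <- as.character(nodes)
  if (anyDuplicated(nodes)) stop_cvr("duplicate area ids in graph nodes", "cvr_config_error")
  if (is.null(edges) || nrow(edges) == 0L) {
    edges <- tibble::tibble(from = character(), to = character())
  } else {
    from <- as.character(edges[[1]]); to <- as.character(edges[[2]])
    unknown <- setdiff(c(from, to), nodes)
    if (length(unknown)) {
      stop_cvr(paste0("edge references unknown area id(s): ", paste(unique(unknown), collapse = ", ")),
               "cvr_config_error")
    }
    if (any(from == to)) stop_cvr("self-loop edges are not allowed", "cvr_config_error")
    a <- pmin(from, to); b <- pmax(from, to)
    keep <- !duplicated(paste(a, b, sep = "\r"))
    edges <- tibble::tibble(from = a[keep], to = b[keep])
  }
  structure(list(nodes = nodes, edges = edges), class = "cvr_graph")
}

#' @export
print.cvr_graph <- function(x, ...) {
  comp <- graph_components(x)
  cat("<cvr_graph> ", length(x$nodes), " areas, ", nrow(x$edges), " edges, ",
      max(comp$component), " component(s)\n", sep = "")
  invisible(x)
}

as_igraph <- function(graph) {
  igraph::graph_from_data_frame(graph$edges, directed = FALSE,
                                vertices = data.frame(name = graph$nodes))
}

#' Connected components of a contiguity graph
#'
#' @param graph A `cvr_graph`.
#' @return A tibble with columns `area_id` and `component` (1-based, ordered by
#'   first appearance).
#' @export
graph_components <- function(graph) {
  cm <- igraph::components(as_igraph(graph))
  tibble::tibble(area_id = graph$nodes,
                 component = as.integer(cm$membership[graph$nodes]))
}

# subset a graph to `ids`; every id must be a node
restrict_graph <- function(graph, ids) {
  missing <- setdiff(ids, graph$nodes)
  if (length(missing)) {
    stop_cvr(paste0("area(s) missing from contiguity graph: ", paste(missing, collapse = ", ")),
             "cvr_config_error")
  }
  keep <- graph$edges$from %in% ids & graph$edges$to %in% ids
  contiguity_graph(ids, graph$edges[keep, ])
}

# adjacency as a list of integer index vectors, in the order of `ids`
adjacency_index <- function(graph, ids = graph$nodes) {
  idx <- stats::setNames(seq_along(ids), ids)
  adj <- vector("list", length(ids))
  for (i in seq_along(ids)) adj[[i]] <- integer()
  f <- idx[graph$edges$from]; t <- idx[graph$edges$to]
  keep <- !is.na(f) & !is.na(t)
  f <- f[keep]; t <- t[keep]
  for (k in seq_along(f)) {
    adj[[f[k]]] <- c(adj[[f[k]]], t[k])
    adj[[t[k]]] <- c(adj[[t[k]]], f[k])
  }
  lapply(adj, function(v) sort(unique(v)))
}

#' Read area polygons from GeoJSON
#'
#' Expects a FeatureCollection of Polygon/MultiPolygon features, each carrying
#' an `area_id` property. Rings are returned as closed coordinate matrices.
#'
#' @param path Path to a GeoJSON file.
#' @return A tibble with columns `area_id` and `geometry` (list of lists of
#'   ring matrices).
#' @export
read_geometry <- function(path) {
  if (!file.exists(path)) stop_cvr(paste0("file not found: ", path), "cvr_config_error")
  gj <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  feats <- gj$features
  if (is.null(feats)) stop_cvr("not a GeoJSON FeatureCollection", "cvr_parse_error")
  rows <- purrr::map(feats, function(f) {
    id <- f$properties$area_id
    if (is.null(id)) stop_cvr("feature without an area_id property", "cvr_parse_error")
    g <- f$geometry
    polys <- switch(g$type %||% "",
      Polygon = list(g$coordinates),
      MultiPolygon = g$coordinates,
      stop_cvr(paste0("area '", id, "': unsupported geometry type"), "cvr_parse_error")
    )
    rings <- purrr::map(polys, function(poly) {
      purrr::map(poly, function(ring) {
        m <- do.call(rbind, purrr::map(ring, function(pt) c(pt[[1]], pt[[2]])))
        if (!is.numeric(m) || nrow(m) < 4) {
          stop_cvr(paste0("invalid geometry for area '", id, "': ring with fewer than 4 points"),
                   "cvr_parse_error")
        }
        if (max(abs(m[1, ] - m[nrow(m), ])) > COORD_TOL) {
          stop_cvr(paste0("invalid geometry for area '", id, "': unclosed ring"),
                   "cvr_parse_error")
        }
        m
      })
    })
    list(area_id = as.character(id), geometry = rings)
  })
  ids <- purrr::map_chr(rows, "area_id")
  if (anyDuplicated(ids)) {
    stop_cvr(paste0("duplicate area_id in geometry: ",
                    paste(unique(ids[duplicated(ids)]), collapse = ", ")), "cvr_config_error")
  }
  tibble::tibble(area_id = ids, geometry = purrr::map(rows, "geometry"))
}

# all boundary segments of one area's rings, as an n x 4 matrix (x1 y1 x2 y2)
area_segments <- function(geom) {
  segs <- purrr::map(geom, function(poly) purrr::map(poly, function(ring) {
    n <- nrow(ring)
    cbind(ring[-n, 1], ring[-n, 2], ring[-1, 1], ring[-1, 2])
  }))
  do.call(rbind, purrr::flatten(segs))
}

vertex_keys <- function(segs, tol = COORD_TOL) {
  pts <- rbind(segs[, 1:2, drop = FALSE], segs[, 3:4, drop = FALSE])
  unique(paste(round(pts[, 1] / tol), round(pts[, 2] / tol)))
}

# do segments a (1x4) and b (1x4) overlap collinearly with positive length?
seg_overlap_len <- function(a, b, tol = COORD_TOL) {
  da <- c(a[3] - a[1], a[4] - a[2])
  la <- sqrt(sum(da^2))
  if (la < tol) return(0)
  u <- da / la
  # both endpoints of b must lie on the line through a
  for (p in list(b[1:2], b[3:4])) {
    d <- c(p[1] - a[1], p[2] - a[2])
    if (abs(d[1] * u[2] - d[2] * u[1]) > tol) return(0)
  }
  t1 <- sum((b[1:2] - a[1:2]) * u)
  t2 <- sum((b[3:4] - a[1:2]) * u)
  max(0, min(la, max(t1, t2)) - max(0, min(t1, t2)))
}

point_on_segs <- function(p, segs, tol = COORD_TOL) {
  dx <- segs[, 3] - segs[, 1]; dy <- segs[, 4] - segs[, 2]
  len2 <- dx^2 + dy^2
  px <- p[1] - segs[, 1]; py <- p[2] - segs[, 2]
  cross <- abs(px * dy - py * dx)
  dot <- px * dx + py * dy
  any(cross <= tol * pmax(sqrt(len2), 1) & dot >= -tol & dot <= len2 + tol)
}

# classify the boundary relation of two areas: "none", "point", or "edge"
pair_relation <- function(segs_i, keys_i, segs_j, keys_j, tol = COORD_TOL) {
  edge <- FALSE
  for (a in seq_len(nrow(segs_i))) {
    for (b in seq_len(nrow(segs_j))) {
      if (seg_overlap_len(segs_i[a, ], segs_j[b, ], tol) > tol) {
        edge <- TRUE
        break
      }
    }
    if (edge) break
  }
  if (edge) return("edge")
  if (length(intersect(keys_i, keys_j))) return("point")
  pts_i <- rbind(segs_i[, 1:2, drop = FALSE], segs_i[, 3:4, drop = FALSE])
  pts_j <- rbind(segs_j[, 1:2, drop = FALSE], segs_j[, 3:4, drop = FALSE])
  for (k in seq_len(nrow(pts_i))) if (point_on_segs(pts_i[k, ], segs_j, tol)) return("point")
  for (k in seq_len(nrow(pts_j))) if (point_on_segs(pts_j[k, ], segs_i, tol)) return("point")
  "none"
}

#' Build a contiguity graph from polygons
#'
#' Two areas are queen-contiguous when their boundaries share at least one
#' point (a shared corner suffices) and rook-contiguous when they share a
#' boundary segment of positive length. Queen is the default: it is the more
#' permissive convention for tract-like polygons and avoids spurious islands
#' at four-corner meeting points.
#'
#' @param geometry A geometry tibble from [read_geometry()], or a path to a
#'   GeoJSON file.
#' @param rule `"queen"` or `"rook"`.
#' @return A `cvr_graph`.
#' @export
build_contiguity <- function(geometry, rule = c("queen", "rook")) {
  rule <- match.arg(rule)
  if (is.character(geometry)) geometry <- read_geometry(geometry)
  n <- nrow(geometry)
  segs <- purrr::map(geometry$geometry, area_segments)
  keys <- purrr::map(segs, vertex_keys)
  bbox <- t(vapply(segs, function(s) {
    c(min(s[, c(1, 3)]), max(s[, c(1, 3)]), min(s[, c(2, 4)]), max(s[, c(2, 4)]))
  }, numeric(4)))
  from <- character(); to <- character()
  tol <- COORD_TOL
  for (i in seq_len(max(n - 1L, 0L))) {
    js <- which(
      bbox[, 1] <= bbox[i, 2] + tol & bbox[, 2] >= bbox[i, 1] - tol &
      bbox[, 3] <= bbox[i, 4] + tol & bbox[, 4] >= bbox[i, 3] - tol
    )
    for (j in js[js > i]) {
      rel <- pair_relation(segs[[i]], keys[[i]], segs[[j]], keys[[j]], tol)
      hit <- if (rule == "queen") rel != "none" else rel == "edge"
      if (hit) {
        from <- c(from, geometry$area_id[i])
        to <- c(to, geometry$area_id[j])
      }
    }
  }
  contiguity_graph(geometry$area_id, tibble::tibble(from = from, to = to))
}

#' Contiguity graph of a rectangular lattice
#'
#' Analytic adjacency for an `rows x cols` grid of unit squares (the synthetic
#' survey layout), equivalent to [build_contiguity()] on the lattice polygons
#' but without the geometric sweep.
#'
#' @param rows,cols Lattice dimensions.
#' @param rule `"queen"` or `"rook"`.
#' @return A `cvr_graph` over ids `A001 ...` in row-major order.
#' @export
lattice_contiguity <- function(rows, cols, rule = c("queen", "rook")) {
  rule <- match.arg(rule)
  ids <- lattice_ids(rows, cols)
  at <- function(r, c) ids[(r - 1L) * cols + c]
  from <- character(); to <- character()
  for (r in seq_len(rows)) for (c in seq_len(cols)) {
    if (c < cols) { from <- c(from, at(r, c)); to <- c(to, at(r, c + 1L)) }
    if (r < rows) { from <- c(from, at(r, c)); to <- c(to, at(r + 1L, c)) }
    if (rule == "queen" && r < rows) {
      if (c < cols) { from <- c(from, at(r, c)); to <- c(to, at(r + 1L, c + 1L)) }
      if (c > 1L) { from <- c(from, at(r, c)); to <- c(to, at(r + 1L, c - 1L)) }
    }
  }
  contiguity_graph(ids, tibble::tibble(from = from, to = to))
}

lattice_ids <- function(rows, cols) {
  n <- rows * cols
  sprintf(paste0("A%0", max(3L, nchar(n)), "d"), seq_len(n))
}

#' Read an adjacency-list file
#'
#' Each non-empty line holds two whitespace-separated area ids. The edge set
#' is symmetrized; ids must exist in `area_ids` (areas with no listed
#' neighbour are kept as isolated nodes).
#'
#' @param path Path to the adjacency file.
#' @param area_ids Character vector of all area ids.
#' @return A `cvr_graph`.
#' @export
read_adjacency <- function(path, area_ids) {
  if (!file.exists(path)) stop_cvr(paste0("file not found: ", path), "cvr_config_error")
  lines <- trimws(readLines(path, warn = FALSE))
  lines <- lines[nzchar(lines)]
  pairs <- purrr::map(lines, function(ln) {
    toks <- strsplit(ln, "[[:space:]]+")[[1]]
    if (length(toks) != 2L) {
      stop_cvr(paste0("malformed adjacency line: '", ln, "'"), "cvr_parse_error")
    }
    if (toks[1] == toks[2]) {
      stop_cvr(paste0("self-pair in adjacency file: ", toks[1]), "cvr_parse_error")
    }
    toks
  })
  edges <- if (length(pairs)) {
    tibble::tibble(from = purrr::map_chr(pairs, 1), to = purrr::map_chr(pairs, 2))
  } else NULL
  contiguity_graph(area_ids, edges)
}

#' Repair islands and exclude areas
#'
#' Survey geographies contain real islands: areas not contiguous to the
#' mainland. Two remedies are supported, mirroring analyst practice: add an
#' artificial link (a bridge) between two areas, or exclude an area entirely.
#' The returned graph carries a component report in
#' `attr(, "components")`.
#'
#' @param graph A `cvr_graph`.
#' @param add_links A two-column data frame of id pairs to connect, or `NULL`.
#' @param drop_areas Character vector of area ids to remove, or `NULL`.
#' @return The repaired `cvr_graph`.
#' @export
repair_islands <- function(graph, add_links = NULL, drop_areas = NULL) {
  drop_areas <- as.character(drop_areas %||% character())
  unknown <- setdiff(drop_areas, graph$nodes)
  if (length(unknown)) {
    stop_cvr(paste0("cannot drop unknown area(s): ", paste(unknown, collapse = ", ")),
             "cvr_config_error")
  }
  edges <- graph$edges
  if (!is.null(add_links) && nrow(add_links) > 0L) {
    lf <- as.character(add_links[[1]]); lt <- as.character(add_links[[2]])
    touched <- c(lf, lt)
    if (any(touched %in% drop_areas)) {
      stop_cvr("artificial link references a dropped area", "cvr_config_error")
    }
    unknown <- setdiff(touched, graph$nodes)
    if (length(unknown)) {
      stop_cvr(paste0("link references unknown area(s): ", paste(unknown, collapse = ", ")),
               "cvr_config_error")
    }
    edges <- dplyr::bind_rows(edges, tibble::tibble(from = lf, to = lt))
  }
  nodes <- setdiff(graph$nodes, drop_areas)
  keep <- edges$from %in% nodes & edges$to %in% nodes
  out <- contiguity_graph(nodes, edges[keep, ])
  comp <- graph_components(out)
  attr(out, "components") <- dplyr::count(comp, .data$component, name = "n_areas")
  out
}

# --- region dissolve -------------------------------------------------------

ring_signed_area <- function(ring) {
  n <- nrow(ring)
  sum(ring[-n, 1] * ring[-1, 2] - ring[-1, 1] * ring[-n, 2]) / 2
}

# union of a set of edge-conformal polygons: internal shared edges appear once
# in each direction and cancel; the surviving directed edges chain into the
# boundary rings. Falls back to the un-dissolved member polygons when the
# boundary cannot be chained (non-conformal input).
dissolve_areas <- function(geoms, tol = COORD_TOL) {
  key <- function(p) paste(round(p[1] / tol), round(p[2] / tol))
  e_from <- character(); e_to <- character()
  coord <- list()
  for (geom in geoms) for (poly in geom) for (ring in poly) {
    if (ring_signed_area(ring) < 0) ring <- ring[rev(seq_len(nrow(ring))), , drop = FALSE]
    n <- nrow(ring)
    ks <- vapply(seq_len(n), function(i) key(ring[i, ]), character(1))
    for (i in seq_len(n - 1L)) {
      coord[[ks[i]]] <- ring[i, ]
      e_from <- c(e_from, ks[i]); e_to <- c(e_to, ks[i + 1L])
    }
  }
  ekey <- paste(e_from, e_to, sep = "|")
  rkey <- paste(e_to, e_from, sep = "|")
  # cancel one reverse partner per edge
  cancel <- logical(length(ekey))
  pos <- split(seq_along(ekey), ekey)
  for (i in seq_along(ekey)) {
    if (cancel[i]) next
    partners <- pos[[rkey[i]]]
    partners <- partners[!cancel[partners] & partners != i]
    if (length(partners)) {
      cancel[i] <- TRUE
      cancel[partners[1]] <- TRUE
    }
  }
  e_from <- e_from[!cancel]; e_to <- e_to[!cancel]
  if (!length(e_from)) return(NULL)
  nxt <- split(seq_along(e_from), e_from)
  used <- logical(length(e_from))
  rings <- list()
  for (start in seq_along(e_from)) {
    if (used[start]) next
    path <- character()
    cur <- start
    ok <- TRUE
    repeat {
      used[cur] <- TRUE
      path <- c(path, e_from[cur])
      nk <- e_to[cur]
      if (nk == e_from[start]) break
      cand <- nxt[[nk]]
      cand <- cand[!used[cand]]
      if (!length(cand)) { ok <- FALSE; break }
      cur <- cand[1]
    }
    if (!ok) return(NULL)
    m <- do.call(rbind, coord[c(path, path[1])])
    rownames(m) <- NULL
    rings[[length(rings) + 1L]] <- m
  }
  # largest-area ring first (the outer boundary), holes after
  ord <- order(-abs(vapply(rings, ring_signed_area, numeric(1))))
  list(rings[ord])
}

# serialize a geometry list (list of polygons of rings) as a GeoJSON geometry
geojson_geometry <- function(geom) {
  polys <- purrr::map(geom, function(poly) purrr::map(poly, function(ring) {
    purrr::map(seq_len(nrow(ring)), function(i) c(ring[i, 1], ring[i, 2]))
  }))
  if (length(polys) == 1L) {
    list(type = "Polygon", coordinates = polys[[1]])
  } else {
    list(type = "MultiPolygon", coordinates = polys)
  }
}

write_geojson <- function(ids, geoms, path, id_name = "area_id") {
  feats <- purrr::map2(ids, geoms, function(id, g) {
    props <- stats::setNames(list(id), id_name)
    list(type = "Feature", properties = props, geometry = geojson_geometry(g))
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = feats),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
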