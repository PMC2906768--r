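#' Construct a triangular mesh
#'
#' Builds the indexed vertex/triangle container used by every other function
#' in the package, validates 2-manifoldness and consistent winding, merges
#' duplicate vertices (triangle-soup input such as STL), and precomputes the
#' adjacency structures needed for neighborhood queries.
#'
#' @param vertices numeric matrix, one row per vertex (x, y, z), model units
#'   (mm for scanned dental casts).
#' @param triangles integer matrix, one row per triangle, 1-based vertex
#'   indices, consistently wound (shared edges traversed in opposite
#'   directions by their two triangles).
#' @param merge_tolerance vertices closer than this fraction of the bounding
#'   box diagonal are merged; default 1e-9 (scanner duplicates are
#'   bit-identical in practice).
#' @param validate check manifoldness and winding (default TRUE).
#' @return an object of class \code{tc_mesh}: list with \code{vertices},
#'   \code{triangles}, vertex adjacency \code{adj}, vertex-to-triangle
#'   incidence \code{vt}, and the edge table.
#' @export
tc_mesh <- function(vertices, triangles, merge_tolerance = 1e-9,
                    validate = TRUE) {
  vertices <- as.matrix(vertices)
  storage.mode(vertices) <- "double"
  triangles <- as.matrix(triangles)
  storage.mode(triangles) <- "integer"
  if (ncol(vertices) != 3L) stop("vertices must be an n x 3 matrix")
  if (ncol(triangles) != 3L) stop("triangles must be an m x 3 matrix")
  if (nrow(triangles) == 0L) stop("mesh has no triangles")

  # Merge coincident vertices (within tolerance x bbox diagonal).
  diag_len <- vec_norm(apply(vertices, 2L, max) - apply(vertices, 2L, min))
  tol <- merge_tolerance * max(diag_len, .Machine$double.eps)
  key <- paste(round(vertices[, 1L] / tol), round(vertices[, 2L] / tol),
               round(vertices[, 3L] / tol))
  first <- !duplicated(key)
  remap <- match(key, key[first])
  # renumber to the surviving vertices
  keep_ids <- which(first)
  vertices <- vertices[keep_ids, , drop = FALSE]
  remap <- match(keep_ids[remap], keep_ids)
  triangles[] <- remap[triangles]

  # Drop degenerate and duplicate triangles.
  degen <- triangles[, 1L] == triangles[, 2L] |
    triangles[, 2L] == triangles[, 3L] | triangles[, 1L] == triangles[, 3L]
  triangles <- triangles[!degen, , drop = FALSE]
  tkey <- apply(triangles, 1L, function(t) paste(sort(t), collapse = "-"))
  triangles <- triangles[!duplicated(tkey), , drop = FALSE]

  # Drop unreferenced vertices.
  used <- sort(unique(as.vector(triangles)))
  if (length(used) < nrow(vertices)) {
    remap2 <- integer(nrow(vertices))
    remap2[used] <- seq_along(used)
    vertices <- vertices[used, , drop = FALSE]
    triangles[] <- remap2[triangles]
  }

  mesh <- structure(list(vertices = vertices, triangles = triangles),
                    class = "tc_mesh")
  mesh <- mesh_index(mesh)
  if (validate) mesh_validate(mesh)
  mesh
}

# Build edge table, vertex adjacency and vertex->triangle incidence.
mesh_index <- function(mesh) {
  tri <- mesh$triangles
  nv <- nrow(mesh$vertices)
  e <- rbind(tri[, c(1L, 2L)], tri[, c(2L, 3L)], tri[, c(3L, 1L)])
  eo <- cbind(pmin(e[, 1L], e[, 2L]), pmax(e[, 1L], e[, 2L]))
  ekey <- (as.numeric(eo[, 1L]) - 1) * nv + eo[, 2L]
  uniq <- !duplicated(ekey)
  edges <- eo[uniq, , drop = FALSE]
  edge_id <- match(ekey, ekey[uniq])
  ecount <- tabulate(edge_id, nbins = nrow(edges))

  # adjacency lists
  adj <- vector("list", nv)
  ends <- c(edges[, 1L], edges[, 2L])
  other <- c(edges[, 2L], edges[, 1L])
  ord <- order(ends)
  adj_split <- split(other[ord], ends[ord])
  adj[as.integer(names(adj_split))] <- adj_split
  for (i in seq_len(nv)) if (is.null(adj[[i]])) adj[[i]] <- integer(0)

  vt <- vector("list", nv)
  tid <- rep(seq_len(nrow(tri)), 3L)
  vs <- as.vector(tri)
  ord <- order(vs)
  vt_split <- split(tid[ord], vs[ord])
  vt[as.integer(names(vt_split))] <- vt_split
  for (i in seq_len(nv)) if (is.null(vt[[i]])) vt[[i]] <- integer(0)

  # edge -> incident triangle ids (list of length nrow(edges))
  et <- split(rep(seq_len(nrow(tri)), 3L), edge_id)
  edge_tris <- vector("list", nrow(edges))
  edge_tris[as.integer(names(et))] <- et

  mesh$edges <- edges
  mesh$edge_count <- ecount
  mesh$edge_tris <- edge_tris
  mesh$tri_edges <- matrix(edge_id, ncol = 3L)  # edge ids of (12, 23, 31)
  mesh$adj <- adj
  mesh$vt <- vt
  mesh
}

mesh_validate <- function(mesh) {
  bad <- which(mesh$edge_count > 2L)
  if (length(bad)) {
    stop(sprintf(
      "non-manifold mesh: %d edge(s) bordered by more than two triangles (e.g. edge %d-%d)",
      length(bad), mesh$edges[bad[1L], 1L], mesh$edges[bad[1L], 2L]))
  }
  # Consistent winding: interior edges must be traversed once per direction.
  tri <- mesh$triangles
  he <- rbind(tri[, c(1L, 2L)], tri[, c(2L, 3L)], tri[, c(3L, 1L)])
  nv <- nrow(mesh$vertices)
  hkey <- (as.numeric(he[, 1L]) - 1) * nv + he[, 2L]
  if (anyDuplicated(hkey)) {
    stop("inconsistent winding: some directed edge appears in two triangles")
  }
  invisible(mesh)
}

#' @export
print.tc_mesh <- function(x, ...) {
  nb <- sum(x$edge_count == 1L)
  cat(sprintf("tc_mesh: %d vertices, %d triangles, %d edges (%d boundary)\n",
              nrow(x$vertices), nrow(x$triangles), nrow(x$edges), nb))
  cat(sprintf("Euler characteristic: %d\n", euler_characteristic(x)))
  invisible(x)
}

#' Euler characteristic V - E + F
#' @param mesh a \code{tc_mesh}.
#' @return integer.
#' @export
euler_characteristic <- function(mesh) {
  nrow(mesh$vertices) - nrow(mesh$edges) + nrow(mesh$triangles)
}

#' n-ring vertex neighborhood
#'
#' Recursive ring expansion: the 1-ring of vertex i is \{i\} together with
#' its edge neighbors, and ring n is the 1-ring of ring n-1. The center is
#' always a member.
#'
#' @param mesh a \code{tc_mesh}.
#' @param i vertex index.
#' @param n ring order (>= 1).
#' @return object of class \code{tc_neighborhood}: list with \code{center},
#'   \code{ring_order}, sorted \code{members}, the 1-ring triangle ids
#'   \code{tri1} and their count \code{n_tri1}.
#' @export
neighborhood <- function(mesh, i, n = 1L) {
  nv <- nrow(mesh$vertices)
  if (length(i) != 1L || is.na(i) || i < 1L || i > nv) {
    stop("invalid vertex index")
  }
  if (n < 1L) stop("ring order must be >= 1")
  members <- neighborhood_members(mesh$adj, i, n)
  structure(list(center = i, ring_order = as.integer(n), members = members,
                 tri1 = mesh$vt[[i]], n_tri1 = length(mesh$vt[[i]])),
            class = "tc_neighborhood")
}

# Fast path used internally: sorted member vector only.
neighborhood_members <- function(adj, i, n) {
  members <- i
  frontier <- i
  for (step in seq_len(n)) {
    nb <- unique(unlist(adj[frontier], use.names = FALSE))
    frontier <- setdiff(nb, members)
    if (length(frontier) == 0L) break
    members <- c(members, frontier)
  }
  sort(members)
}

#' Extract boundary loops
#'
#' Every edge incident to exactly one triangle lies on exactly one maximal
#' cyclically ordered loop. Loops are oriented so that the single incident
#' triangle lies to the left of each directed boundary edge.
#'
#' @param mesh a \code{tc_mesh}.
#' @return list of integer vectors (cyclic vertex index sequences); empty
#'   list for a watertight mesh.
#' @export
boundary_loops <- function(mesh) {
  be <- which(mesh$edge_count == 1L)
  if (length(be) == 0L) return(list())
  tri <- mesh$triangles
  nv <- nrow(mesh$vertices)
  # Directed boundary half-edges: the triangle traverses (a,b); the boundary
  # loop, with the triangle on its left, traverses (b,a)... The triangle's own
  # traversal keeps the surface to its left under CCW winding, so boundary
  # edges are walked in the triangle's direction.
  he <- rbind(tri[, c(1L, 2L)], tri[, c(2L, 3L)], tri[, c(3L, 1L)])
  eo <- cbind(pmin(he[, 1L], he[, 2L]), pmax(he[, 1L], he[, 2L]))
  ekey <- (as.numeric(eo[, 1L]) - 1) * nv + eo[, 2L]
  bkey <- (as.numeric(mesh$edges[be, 1L]) - 1) * nv + mesh$edges[be, 2L]
  sel <- ekey %in% bkey
  dir_edges <- he[sel, , drop = FALSE]
  nxt <- integer(nv)        # successor along boundary
  nxt[dir_edges[, 1L]] <- dir_edges[, 2L]
  visited <- logical(nv)
  loops <- list()
  starts <- dir_edges[, 1L]
  for (s in starts) {
    if (visited[s]) next
    loop <- integer(0)
    v <- s
    repeat {
      loop <- c(loop, v)
      visited[v] <- TRUE
      v <- nxt[v]
      if (v == s) break
      if (visited[v]) break
    }
    loops[[length(loops) + 1L]] <- loop
  }
  loops
}

# Mean edge length of a mesh (used as the resolution scale).
mesh_mean_edge_length <- function(mesh) {
  e <- mesh$edges
  mean(rows_norm(mesh$vertices[e[, 1L], , drop = FALSE] -
                   mesh$vertices[e[, 2L], , drop = FALSE]))
}

# Per-triangle unit normals and areas.
triangle_normals <- function(mesh) {
  tri <- mesh$triangles
  a <- mesh$vertices[tri[, 1L], , drop = FALSE]
  b <- mesh$vertices[tri[, 2L], , drop = FALSE]
  cc <- mesh$vertices[tri[, 3L], , drop = FALSE]
  cr <- rows_cross(b - a, cc - a)
  nrm <- rows_norm(cr)
  list(normals = cr / pmax(nrm, .Machine$double.xmin), areas = nrm / 2)
}
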