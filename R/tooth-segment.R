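# Segmentation-boundary extraction: vertex complexity over ordered 1-rings,
# candidate peeling to a width-one skeleton, branch pruning to closed rings,
# and cutting the mesh into single-tooth submeshes.

# Ordered 1-ring of vertex i (counter-clockwise around the outward normal,
# from the consistent triangle winding). Closed cycle for interior vertices,
# open chain for boundary vertices.
ordered_one_ring <- function(mesh, i) {
  tris <- mesh$vt[[i]]
  if (length(tris) == 0L) return(integer(0))
  nbrs <- list()
  succ <- integer(0)
  names(succ) <- character(0)
  from <- integer(0)
  to <- integer(0)
  for (t in tris) {
    tv <- mesh$triangles[t, ]
    corner <- which(tv == i)
    a <- tv[if (corner == 3L) 1L else corner + 1L]
    b <- tv[if (corner == 1L) 3L else corner - 1L]
    # triangle (i, a, b): rim edge directed a -> b matches CCW around i
    from <- c(from, a)
    to <- c(to, b)
  }
  succ <- to[match(seq_len(max(c(from, to))), from)]
  # start: a rim vertex that is not anyone's successor (boundary chain),
  # else any (closed cycle)
  starts <- setdiff(from, to)
  start <- if (length(starts)) starts[1L] else from[1L]
  ring <- integer(0)
  v <- start
  closed <- FALSE
  for (s in seq_len(length(from) + 1L)) {
    ring <- c(ring, v)
    v <- if (v <= length(succ)) succ[v] else NA_integer_
    if (is.na(v)) break
    if (v == start) {
      closed <- TRUE
      break
    }
  }
  attr(ring, "closed") <- closed
  ring
}

#' Vertex complexity within a region
#'
#' The cyclic sum of absolute successive differences of the 0/1 membership
#' indicator around the vertex's ordered 1-ring (wrap-around term included):
#' twice the number of membership runs. CP = 0 with a full member ring marks
#' a center vertex; CP >= 4 marks a complex (topologically critical) vertex.
#'
#' @param region a \code{tc_region}.
#' @param i member vertex index.
#' @return integer CP value.
#' @export
vertex_complexity <- function(region, i) {
  if (!(i %in% region$members)) stop("vertex ", i, " is not in the region")
  inset <- logical(nrow(region$mesh$vertices))
  inset[region$members] <- TRUE
  cp_value(region$mesh, inset, i)
}

cp_value <- function(mesh, inset, i) {
  ring <- ordered_one_ring(mesh, i)
  if (length(ring) < 2L) return(0L)
  m <- as.integer(inset[ring])
  if (isTRUE(attr(ring, "closed"))) {
    return(sum(abs(m - c(m[-1L], m[1L]))))
  }
  # open chain (mesh-boundary vertex): the ring ends are not adjacent, so pad
  # with non-members; a 1,0,...,0,1 pattern is then two runs, not one
  m <- c(0L, m, 0L)
  sum(abs(diff(m)))
}

#' Classify region vertices by complexity
#'
#' Center vertices have their whole 1-ring inside the region; satellites are
#' the member neighbors of centers; complex vertices have CP >= 4. The
#' candidate (removable) set is the satellites that are neither complex nor
#' centers.
#'
#' @param region a \code{tc_region}.
#' @return list with integer vectors \code{cp} (named by member), and sets
#'   \code{centers}, \code{satellites}, \code{complex}, \code{candidates}.
#' @export
classify_region <- function(region) {
  mesh <- region$mesh
  members <- region$members
  inset <- logical(nrow(mesh$vertices))
  inset[members] <- TRUE
  cp <- vapply(members, function(i) cp_value(mesh, inset, i), 0L)
  names(cp) <- members
  centers <- members[vapply(members, function(i) {
    nb <- mesh$adj[[i]]
    length(nb) > 0L && all(inset[nb])
  }, TRUE)]
  satellites <- intersect(
    unique(unlist(mesh$adj[centers], use.names = FALSE)), members)
  complexv <- members[cp >= 4L]
  candidates <- setdiff(satellites, union(complexv, centers))
  list(cp = cp, centers = centers, satellites = satellites,
       complex = complexv, candidates = sort(candidates))
}

# Removability test used by the peeling loop: not a center, exactly one
# membership run (CP = 2), and at least two member neighbors. Such a vertex
# is a simple boundary vertex: deleting it retracts the region without
# changing its component count or its loops (centers would open a hole,
# complex vertices would break connectivity, run-of-one vertices are branch
# endpoints that the pruning stage owns).
peel_candidate <- function(mesh, inset, i) {
  nb <- mesh$adj[[i]]
  mem_nb <- sum(inset[nb])
  if (mem_nb < 2L || mem_nb == length(nb)) return(FALSE)
  cp_value(mesh, inset, i) == 2L
}

#' Peel a region to its width-one skeleton
#'
#' Sequentially removes one removable vertex at a time (ascending complexity,
#' then ascending vertex index), recomputing the affected neighbors'
#' complexity after each removal, until the region's shape no longer changes.
#' Center and complex vertices are never removed, so the component count and
#' the loops of the region are preserved.
#'
#' @param region a \code{tc_region}.
#' @return object of class \code{tc_skeleton}: list with \code{mesh},
#'   \code{members} (remaining vertices) and the originating region size.
#' @export
skeletonize <- function(region) {
  mesh <- region$mesh
  inset <- logical(nrow(mesh$vertices))
  inset[region$members] <- TRUE
  h <- heap_new(max(64L, length(region$members)))
  stamp <- integer(nrow(mesh$vertices))
  push <- function(i) {
    stamp[i] <<- stamp[i] + 1L
    # min-index priority: weight constant, tie index -i (ascending index)
    heap_push(h, 0, -i, i, stamp[i])
  }
  for (i in region$members) push(i)
  repeat {
    top <- heap_pop(h)
    if (is.null(top)) break
    i <- top$id
    if (!inset[i] || top$stamp != stamp[i]) next
    if (!peel_candidate(mesh, inset, i)) next
    inset[i] <- FALSE
    for (nb in mesh$adj[[i]]) if (inset[nb]) push(nb)
  }
  structure(list(mesh = mesh, members = which(inset),
                 input_size = length(region$members)),
            class = "tc_skeleton")
}

#' @export
print.tc_skeleton <- function(x, ...) {
  cat(sprintf("tc_skeleton: %d vertices (from a %d-vertex region)\n",
              length(x$members), x$input_size))
  invisible(x)
}

# degree of members within the member-induced graph
skeleton_degrees <- function(mesh, members) {
  inset <- logical(nrow(mesh$vertices))
  inset[members] <- TRUE
  vapply(members, function(i) sum(inset[mesh$adj[[i]]]), 0L)
}

#' Prune a skeleton to closed rings
#'
#' Iteratively deletes vertices with at most one skeleton neighbor (open
#' branches peel from their endpoints inward), then drops rings shorter than
#' \code{min_ring} (the small redundant rings the interactive workflow would
#' remove by hand).
#'
#' @param skeleton a \code{tc_skeleton}.
#' @param min_ring minimum ring length kept (default 8).
#' @return a \code{tc_skeleton} whose \code{rings} field lists the closed
#'   vertex cycles (2-regular components).
#' @export
prune_skeleton <- function(skeleton, min_ring = 8L) {
  mesh <- skeleton$mesh
  members <- skeleton$members
  # Alternate endpoint deletion with re-peeling: removing a branch can expose
  # chord apexes that were locked (two membership runs) while the branch was
  # attached; re-peeling collapses them onto the ring.
  repeat {
    before <- members
    repeat {
      if (length(members) == 0L) break
      deg <- skeleton_degrees(mesh, members)
      drop <- members[deg <= 1L]
      if (length(drop) == 0L) break
      members <- setdiff(members, drop)
    }
    if (length(members)) {
      members <- skeletonize(vertex_region(mesh, members))$members
    }
    if (identical(members, before)) break
  }
  # split into components; keep rings of sufficient length
  lab <- subset_components(mesh$adj, members)
  comps <- if (length(lab)) split(as.integer(names(lab)), lab) else list()
  rings <- list()
  keep <- integer(0)
  for (comp in comps) {
    if (length(comp) < min_ring) next
    keep <- c(keep, comp)
    deg <- skeleton_degrees(mesh, comp)
    if (all(deg == 2L)) {
      rings[[length(rings) + 1L]] <- walk_cycle(mesh, comp)
    } else {
      rings[[length(rings) + 1L]] <- sort(comp)  # non-simple component
      attr(rings[[length(rings)]], "simple") <- FALSE
    }
  }
  out <- structure(list(mesh = mesh, members = sort(keep),
                        input_size = skeleton$input_size, rings = rings),
                   class = "tc_skeleton")
  out
}

# order a 2-regular component into a cycle
walk_cycle <- function(mesh, comp) {
  inset <- logical(nrow(mesh$vertices))
  inset[comp] <- TRUE
  start <- min(comp)
  cyc <- start
  prev <- NA_integer_
  v <- start
  repeat {
    nb <- mesh$adj[[v]]
    nb <- nb[inset[nb]]
    nxt <- nb[is.na(prev) | nb != prev][1L]
    if (nxt == start) break
    cyc <- c(cyc, nxt)
    prev <- v
    v <- nxt
    if (length(cyc) > length(comp)) break
  }
  cyc
}

#' Separate the mesh along segmentation rings
#'
#' Cuts the mesh along every edge joining two skeleton vertices: triangle
#' adjacency is blocked across those edges and the connected components are
#' extracted as submeshes (ring vertices are duplicated into each side). The
#' largest component is labelled the base (gingiva/cast); every other
#' component is a tooth.
#'
#' @param mesh a \code{tc_mesh}.
#' @param skeleton a pruned \code{tc_skeleton} (or list of vertex rings).
#' @param min_tooth_triangles components smaller than this (other than the
#'   base) are cut-artifact fragments, not teeth (default 10).
#' @return list with \code{teeth} (list of \code{tc_mesh}), \code{base}
#'   (a \code{tc_mesh}), \code{components} (triangle-id sets),
#'   \code{fragments} (indices of sub-tooth-size components) and
#'   \code{vertex_maps} (original vertex id per submesh vertex).
#' @export
separate_teeth <- function(mesh, skeleton, min_tooth_triangles = 10L) {
  members <- if (inherits(skeleton, "tc_skeleton")) skeleton$members
             else sort(unique(unlist(skeleton)))
  if (length(members) == 0L) {
    sub <- list(mesh = mesh, vertex_map = seq_len(nrow(mesh$vertices)))
    return(list(teeth = list(), base = mesh,
                components = list(seq_len(nrow(mesh$triangles))),
                vertex_maps = list(sub$vertex_map)))
  }
  inset <- logical(nrow(mesh$vertices))
  inset[members] <- TRUE
  # blocked edges: both endpoints in the skeleton
  blocked <- inset[mesh$edges[, 1L]] & inset[mesh$edges[, 2L]]
  nt <- nrow(mesh$triangles)
  comp <- integer(nt)
  lab <- 0L
  stack <- integer(nt)
  for (s in seq_len(nt)) {
    if (comp[s] != 0L) next
    lab <- lab + 1L
    comp[s] <- lab
    stack[1L] <- s
    top <- 1L
    while (top > 0L) {
      t <- stack[top]
      top <- top - 1L
      for (eid in mesh$tri_edges[t, ]) {
        if (blocked[eid]) next
        for (t2 in mesh$edge_tris[[eid]]) {
          if (comp[t2] == 0L) {
            comp[t2] <- lab
            top <- top + 1L
            stack[top] <- t2
          }
        }
      }
    }
  }
  n_rings <- if (inherits(skeleton, "tc_skeleton")) length(skeleton$rings) else length(skeleton)
  if (lab < 2L) {
    stop("segmentation rings do not separate the surface")
  }
  comps <- split(seq_len(nt), comp)
  sizes <- vapply(comps, length, 0L)
  base_lab <- which.max(sizes)
  tooth_labs <- setdiff(which(sizes >= min_tooth_triangles), base_lab)
  frag_labs <- setdiff(seq_along(comps), c(base_lab, tooth_labs))
  submesh <- function(tids) {
    tri <- mesh$triangles[tids, , drop = FALSE]
    used <- sort(unique(as.vector(tri)))
    m <- tc_mesh(mesh$vertices[used, , drop = FALSE],
                 matrix(match(tri, used), ncol = 3L), validate = FALSE)
    list(mesh = m, vertex_map = used)
  }
  subs <- lapply(comps, submesh)
  teeth <- subs[tooth_labs]
  list(teeth = lapply(teeth, `[[`, "mesh"),
       base = subs[[base_lab]]$mesh,
       components = comps,
       fragments = frag_labs,
       vertex_maps = lapply(subs, `[[`, "vertex_map"),
       teeth_vertex_maps = lapply(teeth, `[[`, "vertex_map"),
       base_component = base_lab)
}
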