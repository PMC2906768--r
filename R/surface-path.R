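# Direction-traced straight "lines" over the mesh surface and spatial-polygon
# selection of enclosed triangles.

# Resolve a surface point specification: a vertex index, or a list
# list(pos = xyz, tri = triangle id). Returns list(pos, tris) where tris are
# carrier triangle candidates.
resolve_surface_point <- function(mesh, p) {
  if (is.numeric(p) && length(p) == 1L) {
    i <- as.integer(p)
    return(list(pos = mesh$vertices[i, ], tris = mesh$vt[[i]], vertex = i))
  }
  if (is.list(p) && !is.null(p$pos)) {
    tris <- if (!is.null(p$tri)) as.integer(p$tri) else stop("surface point needs a carrier triangle")
    return(list(pos = as.numeric(p$pos), tris = tris, vertex = NA_integer_))
  }
  stop("surface point must be a vertex index or list(pos=, tri=)")
}

# Exit point of the normal-section plane through `pos` with travel direction
# `dir` and normal `nrm`, across triangle `t`. Returns candidate exits:
# points on the triangle boundary strictly forward of pos.
triangle_exit_points <- function(mesh, t, pos, dir, nrm, tol) {
  tv <- mesh$triangles[t, ]
  P <- mesh$vertices[tv, , drop = FALSE]
  tn <- vec_cross(P[2L, ] - P[1L, ], P[3L, ] - P[1L, ])
  if (vec_norm(tn) == 0) return(NULL)
  tn <- tn / vec_norm(tn)
  # plane through pos spanned by dir and nrm: normal m = dir x nrm
  m <- vec_cross(dir, nrm)
  if (vec_norm(m) < tol) {
    # travel direction parallel to the vertex normal: fall back to the plane
    # containing dir and the triangle normal
    m <- vec_cross(dir, tn)
    if (vec_norm(m) < tol) return(NULL)
  }
  m <- m / vec_norm(m)
  # forward direction within the triangle plane
  fwd <- dir - sum(dir * tn) * tn
  if (vec_norm(fwd) < tol) return(NULL)
  fwd <- fwd / vec_norm(fwd)
  s <- as.vector((P - matrix(pos, 3L, 3L, byrow = TRUE)) %*% m)
  out <- list()
  for (k in 1:3) {
    k2 <- if (k == 3L) 1L else k + 1L
    a <- P[k, ]; b <- P[k2, ]
    sa <- s[k]; sb <- s[k2]
    pts <- NULL
    if (abs(sa) <= tol && abs(sb) <= tol) {
      pts <- rbind(a, b)           # plane contains the whole edge
    } else if (abs(sa) <= tol) {
      pts <- rbind(a)
    } else if (abs(sb) <= tol) {
      pts <- rbind(b)
    } else if (sa * sb < 0) {
      lam <- sa / (sa - sb)
      pts <- rbind(a + lam * (b - a))
    }
    if (!is.null(pts)) {
      for (r in seq_len(nrow(pts))) {
        x <- pts[r, ]
        adv <- sum((x - pos) * fwd)
        if (adv > tol) {
          out[[length(out) + 1L]] <- list(pos = x, edge = c(tv[k], tv[k2]),
                                          advance = adv, tri = t)
        }
      }
    }
  }
  out
}

#' Trace a straight surface "line" between two surface points
#'
#' Direction tracing: from the current point, the path advances by
#' intersecting the current carrier triangle with the normal-section plane
#' through the point spanned by the (re-aimed) direction to the destination
#' and the local surface normal; among candidate exit points, the one
#' minimizing the angle to the destination direction is chosen. On a flat
#' mesh the result is the exact Euclidean segment; on curved meshes it is an
#' approximate geodesic. Linear time in the output size.
#'
#' @param mesh a \code{tc_mesh}.
#' @param p_s,p_e surface points: vertex indices, or \code{list(pos=, tri=)}.
#' @return object of class \code{tc_surface_path}: list with \code{points}
#'   (matrix of path points), \code{carriers} (triangle id per segment),
#'   \code{crossed_edges} (2-column matrix of mesh edges crossed or traversed)
#'   and \code{length}.
#' @export
trace_line <- function(mesh, p_s, p_e) {
  scale <- mesh_mean_edge_length(mesh)
  tol <- 1e-12 * max(scale, 1)
  snap_tol <- 1e-9 * scale
  start <- resolve_surface_point(mesh, p_s)
  goal <- resolve_surface_point(mesh, p_e)
  normals <- vertex_normals(mesh)
  tnorm <- triangle_normals(mesh)$normals

  local_normal <- function(pt) {
    if (!is.na(pt$vertex)) return(normals[pt$vertex, ])
    colMeans(tnorm[pt$tris, , drop = FALSE])
  }

  pts <- matrix(start$pos, 1L, 3L)
  carriers <- integer(0)
  crossed <- matrix(integer(0), 0L, 2L)
  cur <- start
  max_steps <- 10L * nrow(mesh$triangles) + 10L
  for (step in seq_len(max_steps)) {
    common <- intersect(cur$tris, goal$tris)
    if (length(common)) {
      pts <- rbind(pts, goal$pos)
      carriers <- c(carriers, common[1L])
      path <- structure(list(points = pts, carriers = carriers,
                             crossed_edges = crossed,
                             length = sum(rows_norm(diff(pts)))),
                        class = "tc_surface_path")
      return(path)
    }
    dir <- goal$pos - cur$pos
    if (vec_norm(dir) < tol) stop("trace_line: degenerate direction")
    dir <- dir / vec_norm(dir)
    nrm <- local_normal(cur)
    best <- NULL
    best_ang <- Inf
    for (t in cur$tris) {
      cands <- triangle_exit_points(mesh, t, cur$pos, dir, nrm, tol)
      for (cd in cands) {
        stepv <- cd$pos - cur$pos
        ang <- acos(min(1, max(-1, sum(stepv * dir) / vec_norm(stepv))))
        # tie: prefer the farther advance (guarantees progress)
        if (ang < best_ang - 1e-12 ||
            (abs(ang - best_ang) <= 1e-12 && !is.null(best) && cd$advance > best$advance)) {
          best <- cd
          best_ang <- ang
        }
      }
    }
    if (is.null(best)) {
      stop("trace_line: trajectory left the mesh or stalled; partial path has ",
           nrow(pts), " points")
    }
    # snap to a mesh vertex when the exit point coincides with one
    ev <- best$edge
    d1 <- vec_norm(best$pos - mesh$vertices[ev[1L], ])
    d2 <- vec_norm(best$pos - mesh$vertices[ev[2L], ])
    if (min(d1, d2) <= snap_tol) {
      vtx <- if (d1 <= d2) ev[1L] else ev[2L]
      nxt <- list(pos = mesh$vertices[vtx, ], tris = mesh$vt[[vtx]], vertex = vtx)
    } else {
      # carrier triangles across the exited edge
      eid <- edge_lookup(mesh, ev[1L], ev[2L])
      tris <- mesh$edge_tris[[eid]]
      if (length(tris) == 1L && tris[1L] == best$tri) {
        stop("trace_line: trajectory exits the mesh through boundary edge ",
             ev[1L], "-", ev[2L], "; partial path has ", nrow(pts), " points")
      }
      nxt <- list(pos = best$pos, tris = tris, vertex = NA_integer_)
    }
    if (vec_norm(nxt$pos - cur$pos) <= tol && identical(sort(nxt$tris), sort(cur$tris))) {
      stop("trace_line: no progress (cycle) at step ", step)
    }
    pts <- rbind(pts, nxt$pos)
    carriers <- c(carriers, best$tri)
    crossed <- rbind(crossed, ev)
    cur <- nxt
  }
  stop("trace_line: step limit exceeded")
}

edge_lookup <- function(mesh, a, b) {
  lo <- min(a, b); hi <- max(a, b)
  which(mesh$edges[, 1L] == lo & mesh$edges[, 2L] == hi)[1L]
}

#' Select triangles enclosed by a spatial polygon of traced lines
#'
#' Traces the closed fence anchor_1 -> anchor_2 -> ... -> anchor_1 and
#' returns the connected set of triangles enclosed by it. Triangles crossed
#' by the fence are boundary ("fence") triangles and belong to neither side;
#' the enclosed side is found by flood fill from a seed triangle (default:
#' the triangle nearest the centroid of the anchors).
#'
#' @param mesh a \code{tc_mesh}.
#' @param anchors ordered vertex indices (>= 3) defining the polygon corners.
#' @param seed_triangle optional interior seed triangle id.
#' @return object of class \code{tc_polygon}: list with \code{paths},
#'   \code{enclosed} (triangle ids), \code{fence_triangles} and
#'   \code{enclosed_vertices}.
#' @export
select_polygon <- function(mesh, anchors, seed_triangle = NULL) {
  if (length(anchors) < 3L) stop("need at least 3 anchors")
  k <- length(anchors)
  paths <- vector("list", k)
  for (j in seq_len(k)) {
    j2 <- if (j == k) 1L else j + 1L
    paths[[j]] <- trace_line(mesh, anchors[j], anchors[j2])
  }
  # Blocked adjacency: mesh edges crossed or traversed by the fence, plus
  # edges between consecutive anchors/path vertices that lie along edges.
  blocked <- do.call(rbind, lapply(paths, function(p) p$crossed_edges))
  # Path segments that run along mesh edges (vertex-to-vertex) also block.
  for (p in paths) {
    n <- nrow(p$points)
    for (s in seq_len(n - 1L)) {
      a <- match_vertex(mesh, p$points[s, ])
      b <- match_vertex(mesh, p$points[s + 1L, ])
      if (!is.na(a) && !is.na(b) && b %in% mesh$adj[[a]]) {
        blocked <- rbind(blocked, c(a, b))
      }
    }
  }
  fence_tris <- sort(unique(unlist(lapply(paths, function(p) p$carriers))))
  # triangles merely touched at a vertex are not fences; carriers that the
  # path only enters/exits at edges still count as crossed
  blocked_eids <- unique(apply(blocked, 1L, function(e) edge_lookup(mesh, e[1L], e[2L])))

  # When the fence passes through a mesh vertex transversally (not along
  # edges), edge blocking alone leaks around that vertex: fence the vertex
  # star. Build the full cyclic point sequence across path junctions first.
  allpts <- do.call(rbind, lapply(paths, function(p) p$points[-nrow(p$points), , drop = FALSE]))
  npts <- nrow(allpts)
  vertex_star_fence <- integer(0)
  vids <- vapply(seq_len(npts), function(r) match_vertex(mesh, allpts[r, ]), 0L)
  for (r in seq_len(npts)) {
    v <- vids[r]
    if (is.na(v)) next
    rp <- if (r == 1L) npts else r - 1L
    rn <- if (r == npts) 1L else r + 1L
    along <- function(rr) {
      w <- vids[rr]
      !is.na(w) && (w %in% mesh$adj[[v]])
    }
    if (!(along(rp) && along(rn))) {
      vertex_star_fence <- c(vertex_star_fence, mesh$vt[[v]])
    }
  }

  # triangle adjacency across non-blocked interior edges
  nt <- nrow(mesh$triangles)
  tri_adj <- vector("list", nt)
  for (eid in seq_len(nrow(mesh$edges))) {
    ts <- mesh$edge_tris[[eid]]
    if (length(ts) == 2L && !(eid %in% blocked_eids)) {
      tri_adj[[ts[1L]]] <- c(tri_adj[[ts[1L]]], ts[2L])
      tri_adj[[ts[2L]]] <- c(tri_adj[[ts[2L]]], ts[1L])
    }
  }
  # Flood-fill components over all triangles (fence carriers participate:
  # a carrier crossed only along its edges still belongs to one side).
  hard_fence <- fence_tris[vapply(fence_tris, function(t) {
    # a carrier is a true fence triangle when the path passes through its
    # interior (some segment endpoint is not on its boundary edges/vertices)
    any(vapply(paths, function(p) {
      idx <- which(p$carriers == t)
      length(idx) > 0L && any(vapply(idx, function(s) {
        interior_point_in_triangle(mesh, t, p$points[s, ]) ||
          interior_point_in_triangle(mesh, t, p$points[s + 1L, ])
      }, TRUE))
    }, TRUE))
  }, TRUE)]
  hard_fence <- sort(unique(c(hard_fence, vertex_star_fence)))
  comp <- integer(nt)
  lab <- 0L
  for (s in seq_len(nt)) {
    if (comp[s] != 0L || s %in% hard_fence) next
    lab <- lab + 1L
    queue <- s
    comp[s] <- lab
    while (length(queue)) {
      t <- queue[[1L]]; queue <- queue[-1L]
      nb <- tri_adj[[t]]
      nb <- nb[!(nb %in% hard_fence) & comp[nb] == 0L]
      if (length(nb)) {
        comp[nb] <- lab
        queue <- c(queue, nb)
      }
    }
  }
  if (lab < 2L) stop("spatial polygon does not separate the surface")
  if (is.null(seed_triangle)) {
    ctr <- colMeans(mesh$vertices[anchors, , drop = FALSE])
    tc <- (mesh$vertices[mesh$triangles[, 1L], , drop = FALSE] +
             mesh$vertices[mesh$triangles[, 2L], , drop = FALSE] +
             mesh$vertices[mesh$triangles[, 3L], , drop = FALSE]) / 3
    d <- rows_norm(sweep(tc, 2L, ctr))
    ord <- order(d)
    seed_triangle <- ord[which(comp[ord] != 0L)[1L]]
  }
  if (comp[seed_triangle] == 0L) stop("seed triangle lies on the fence")
  enclosed <- which(comp == comp[seed_triangle])
  encl_v <- sort(unique(as.vector(mesh$triangles[enclosed, ])))
  structure(list(paths = paths, enclosed = enclosed,
                 fence_triangles = hard_fence,
                 enclosed_vertices = encl_v),
            class = "tc_polygon")
}

match_vertex <- function(mesh, pos, tol = NULL) {
  if (is.null(tol)) tol <- 1e-9 * mesh_mean_edge_length(mesh)
  d <- rows_norm(sweep(mesh$vertices, 2L, pos))
  i <- which.min(d)
  if (d[i] <= tol) i else NA_integer_
}

interior_point_in_triangle <- function(mesh, t, pos, rel_tol = 1e-7) {
  P <- mesh$vertices[mesh$triangles[t, ], , drop = FALSE]
  # barycentric coordinates
  v0 <- P[2L, ] - P[1L, ]; v1 <- P[3L, ] - P[1L, ]; v2 <- pos - P[1L, ]
  d00 <- sum(v0 * v0); d01 <- sum(v0 * v1); d11 <- sum(v1 * v1)
  d20 <- sum(v2 * v0); d21 <- sum(v2 * v1)
  den <- d00 * d11 - d01^2
  if (den == 0) return(FALSE)
  v <- (d11 * d20 - d01 * d21) / den
  w <- (d00 * d21 - d01 * d20) / den
  u <- 1 - v - w
  eps <- rel_tol
  u > eps && v > eps && w > eps
}
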