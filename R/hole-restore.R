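# Single-tooth shape restoration: occlusal plane, saddle-hole bridging,
# weight-rule spanning triangulation, 1-3 refinement with Delaunay
# relaxation, constrained k-harmonic reshaping, and blend control with
# interference checking.

#' Fit the occlusal reference plane
#'
#' Total-least-squares plane through the four cusp-tip reference points
#' (minimizes the sum of squared orthogonal distances).
#'
#' @param points 4 x 3 matrix of reference points (buccal cusp tips /
#'   mesiobuccal points in the dental workflow).
#' @param toward optional 3D point; the normal is oriented so this point has
#'   positive signed distance (the crown side). Default: positive z
#'   component.
#' @return object of class \code{tc_plane}: list with unit \code{normal},
#'   \code{offset} (plane is normal . x = offset), \code{points} and
#'   \code{residual}.
#' @export
fit_occlusal_plane <- function(points, toward = NULL) {
  points <- as.matrix(points)
  if (nrow(points) < 3L) stop("need at least 3 reference points")
  ctr <- colMeans(points)
  X <- sweep(points, 2L, ctr)
  sv <- svd(X)
  if (sv$d[2L] < 1e-12 * max(sv$d[1L], 1)) {
    stop("reference points are collinear or coincident")
  }
  normal <- sv$v[, 3L]
  if (!is.null(toward)) {
    if (sum((toward - ctr) * normal) < 0) normal <- -normal
  } else if (normal[3L] < 0 || (normal[3L] == 0 && normal[1L] < 0)) {
    normal <- -normal
  }
  offset <- sum(normal * ctr)
  res <- sum((X %*% normal)^2)
  structure(list(normal = normal, offset = offset, points = points,
                 residual = res), class = "tc_plane")
}

plane_signed_distance <- function(plane, pts) {
  as.vector(as.matrix(pts) %*% plane$normal) - plane$offset
}

#' Bridge a saddle hole into two subholes
#'
#' The bridge edge endpoints are the two hole-boundary vertices farthest
#' below the occlusal plane (deepest on the gingival side), one on each side
#' of the loop; the cyclic boundary is split at them into the two per-tooth
#' subloops, each closed by the shared bridge edge.
#'
#' @param mesh a \code{tc_mesh}.
#' @param loop integer vertex-index cycle (a boundary loop).
#' @param plane a \code{tc_plane} with the normal toward the crowns.
#' @return object of class \code{tc_subholes}: list with \code{loop1},
#'   \code{loop2} (vertex cycles, both containing the bridge endpoints) and
#'   \code{bridge} (the two endpoint ids).
#' @export
bridge_hole <- function(mesh, loop, plane) {
  n <- length(loop)
  if (n < 6L) stop("hole loop too short to bridge")
  d <- abs(plane_signed_distance(plane, mesh$vertices[loop, , drop = FALSE]))
  i1 <- which.max(d)
  # second endpoint: the farthest vertex such that both loop arcs between the
  # two endpoints dip strictly below both endpoint distances somewhere (the
  # loop truly crosses a saddle between two distance maxima)
  ord <- order(d, decreasing = TRUE)
  i2 <- NA_integer_
  for (cand in ord[-1L]) {
    gap1 <- (cand - i1) %% n
    gap2 <- (i1 - cand) %% n
    if (gap1 < 2L || gap2 < 2L) next
    arc1 <- loop_arc_positions(i1, cand, n)
    arc2 <- loop_arc_positions(cand, i1, n)
    lo <- min(d[i1], d[cand])
    if (min(d[arc1[-c(1L, length(arc1))]]) < lo &&
        min(d[arc2[-c(1L, length(arc2))]]) < lo) {
      i2 <- cand
      break
    }
  }
  if (is.na(i2)) stop("degenerate saddle: the two distance maxima are adjacent on the loop")
  arc1 <- loop[loop_arc_positions(i1, i2, n)]
  arc2 <- loop[loop_arc_positions(i2, i1, n)]
  structure(list(loop1 = arc1, loop2 = arc2,
                 bridge = c(loop[i1], loop[i2])),
            class = "tc_subholes")
}

# positions a..b inclusive walking forward cyclically
loop_arc_positions <- function(a, b, n) {
  if (b >= a) seq(a, b) else c(seq(a, n), seq_len(b))
}

#' Create a boundary-triangulation state
#'
#' Holds the working cyclic boundary, the per-vertex incident-triangle counts
#' and adjacent-angle sums, and the weight bookkeeping for the weight-rule
#' spanning triangulation. When the loop belongs to a mesh, the surrounding
#' mesh triangles seed the counts, angle sums and the projection test.
#'
#' @param loop_positions n x 3 matrix of boundary vertex positions in cyclic
#'   order.
#' @param mesh optional host \code{tc_mesh}.
#' @param loop_ids host vertex ids matching \code{loop_positions} rows
#'   (required with \code{mesh}).
#' @param alpha sharp-corner angle factor (default 1.2; corners with adjacent
#'   angle sum below alpha*pi are deprioritized).
#' @return an environment of class \code{tc_tri_state}.
#' @export
triangulation_state <- function(loop_positions, mesh = NULL, loop_ids = NULL,
                                alpha = 1.2) {
  pos <- as.matrix(loop_positions)
  n <- nrow(pos)
  if (n < 3L) stop("loop must have at least 3 vertices")
  st <- new.env(parent = emptyenv())
  st$pos <- pos
  st$n0 <- n
  st$alpha <- alpha
  st$nxt <- c(seq_len(n)[-1L], 1L)
  st$prv <- c(n, seq_len(n)[-n])
  st$alive <- rep(TRUE, n)
  st$n_alive <- n
  st$tri_count <- integer(n)
  st$ang_sum <- numeric(n)
  st$vtris <- vector("list", n)    # incident triangle corner positions
  st$vnorm <- matrix(NA_real_, n, 3L)  # cached tangent-plane normals
  st$patch_tris <- matrix(integer(0), 0L, 3L)
  st$stamp <- integer(n)
  ctr <- colMeans(pos)
  st$R_C <- max(rows_norm(sweep(pos, 2L, ctr)))
  # fallback normal: best-fit plane of the loop
  sv <- svd(sweep(pos, 2L, ctr))
  st$loop_normal <- sv$v[, 3L]
  if (!is.null(mesh)) {
    if (is.null(loop_ids) || length(loop_ids) != n) {
      stop("loop_ids must accompany mesh context")
    }
    st$R_C <- {
      mc <- colMeans(mesh$vertices)
      max(rows_norm(sweep(mesh$vertices, 2L, mc)))
    }
    for (li in seq_len(n)) {
      vid <- loop_ids[li]
      for (t in mesh$vt[[vid]]) {
        tvs <- mesh$triangles[t, ]
        corner <- which(tvs == vid)
        tvs <- tvs[c(corner, setdiff(1:3, corner))]
        P <- mesh$vertices[tvs, , drop = FALSE]
        st$vtris[[li]] <- rbind(st$vtris[[li]], P)
        st$tri_count[li] <- st$tri_count[li] + 1L
        st$ang_sum[li] <- st$ang_sum[li] + corner_angle(P[1L, ], P[2L, ], P[3L, ])
      }
    }
  }
  class(st) <- "tc_tri_state"
  st
}

# Tangent-plane normal at boundary vertex li: area-weighted average of the
# incident triangle normals, loop best-fit plane as fallback.
state_vertex_normal <- function(st, li) {
  M <- st$vtris[[li]]
  if (is.null(M)) return(st$loop_normal)
  if (!is.na(st$vnorm[li, 1L])) return(st$vnorm[li, ])
  k <- nrow(M) / 3L
  i1 <- 3L * (seq_len(k) - 1L) + 1L
  cr <- rows_cross(M[i1 + 1L, , drop = FALSE] - M[i1, , drop = FALSE],
                   M[i1 + 2L, , drop = FALSE] - M[i1, , drop = FALSE])
  acc <- colSums(cr)
  nn <- vec_norm(acc)
  out <- if (nn == 0) st$loop_normal else acc / nn
  st$vnorm[li, ] <- out
  out
}

# Projection non-intersection condition at vertex li, with the candidate
# triangle (positions capP, corner order: li first) hypothetically added:
# project every incident edge onto the tangent plane; no two may cross except
# at shared endpoints.
projection_ok <- function(st, li, candP) {
  oldM <- st$vtris[[li]]                   # (3k) x 3, rows grouped in triples
  if (is.null(oldM)) return(TRUE)
  nrm <- state_vertex_normal(st, li)
  fr <- tangent_frame(nrm)
  p0 <- st$pos[li, ]
  # project all old triangle corners at once; old edges are corner pairs
  # (1,2), (1,3), (2,3) of each stored triangle
  x <- oldM[, 1L] - p0[1L]; y <- oldM[, 2L] - p0[2L]; z <- oldM[, 3L] - p0[3L]
  U <- x * fr$u[1L] + y * fr$u[2L] + z * fr$u[3L]
  V <- x * fr$v[1L] + y * fr$v[2L] + z * fr$v[3L]
  k <- nrow(oldM) / 3L
  base <- 3L * (seq_len(k) - 1L)
  ia <- c(base + 1L, base + 1L, base + 2L)
  ib <- c(base + 2L, base + 3L, base + 3L)
  xc <- candP[, 1L] - p0[1L]; yc <- candP[, 2L] - p0[2L]; zc <- candP[, 3L] - p0[3L]
  cu <- xc * fr$u[1L] + yc * fr$u[2L] + zc * fr$u[3L]
  cv <- xc * fr$v[1L] + yc * fr$v[2L] + zc * fr$v[3L]
  scale <- max(sqrt((U[ib] - U[ia])^2 + (V[ib] - V[ia])^2), 1e-300)
  tol <- 1e-12 * scale
  # only crossings introduced by the candidate's edges count: a projected
  # 1-ring that already self-crosses is not the candidate's fault.
  # All (3 new) x (3k old) pairs in one vectorized call.
  e1 <- c(1L, 1L, 2L); e2 <- c(2L, 3L, 3L)
  m <- length(ia)
  rep_new <- rep(seq_len(3L), each = m)
  rep_old <- rep(seq_len(m), times = 3L)
  !segs_cross_pairs(cu[e1][rep_new], cv[e1][rep_new],
                    cu[e2][rep_new], cv[e2][rep_new],
                    U[ia][rep_old], V[ia][rep_old],
                    U[ib][rep_old], V[ib][rep_old], tol)
}

#' Weight of the candidate triangle at a boundary position
#'
#' The weight rule, in priority order: -Inf when the candidate violates the
#' projection non-intersection condition at any of its three vertices;
#' l_bigger = (|NeiT1(i)|/8) R_C when the apex already has more than 8
#' incident triangles (remove it first); l_less = -(pi/A(v_i)) R_C when the
#' apex's adjacent-angle sum is below alpha*pi (sharp corner, deprioritized);
#' otherwise minus the candidate's perimeter.
#'
#' @param st a \code{tc_tri_state}.
#' @param i boundary position (1-based index into the original loop order).
#' @param skip_projection disable the projection test (deadlock fallback).
#' @return numeric weight (possibly -Inf).
#' @export
triangle_weight <- function(st, i, skip_projection = FALSE) {
  j <- st$prv[i]; k <- st$nxt[i]
  pj <- st$pos[j, ]; pi_ <- st$pos[i, ]; pk <- st$pos[k, ]
  if (!skip_projection) {
    candJ <- rbind(pj, pi_, pk)
    candI <- rbind(pi_, pk, pj)
    candK <- rbind(pk, pj, pi_)
    if (!projection_ok(st, i, candI) || !projection_ok(st, j, candJ) ||
        !projection_ok(st, k, candK)) {
      return(-Inf)
    }
  }
  if (st$tri_count[i] > 8L) {
    return((st$tri_count[i] / 8) * st$R_C)
  }
  A <- st$ang_sum[i]
  if (A > 0 && A < st$alpha * pi) {
    return(-(pi / A) * st$R_C)
  }
  -(vec_norm(pj - pi_) + vec_norm(pi_ - pk) + vec_norm(pj - pk))
}

# Vectorized projection-free weights for a set of apexes (fallback rescan).
weights_no_projection <- function(st, alive) {
  j <- st$prv[alive]; k <- st$nxt[alive]
  P <- st$pos
  per <- sqrt(rowSums((P[j, , drop = FALSE] - P[alive, , drop = FALSE])^2)) +
    sqrt(rowSums((P[alive, , drop = FALSE] - P[k, , drop = FALSE])^2)) +
    sqrt(rowSums((P[j, , drop = FALSE] - P[k, , drop = FALSE])^2))
  w <- -per
  A <- st$ang_sum[alive]
  less <- A > 0 & A < st$alpha * pi
  w[less] <- -(pi / A[less]) * st$R_C
  big <- st$tri_count[alive] > 8L
  w[big] <- (st$tri_count[alive][big] / 8) * st$R_C
  w
}

# Insert the ear triangle at apex i and update the state.
state_clip <- function(st, i) {
  j <- st$prv[i]; k <- st$nxt[i]
  # loop edges run in the host triangles' own direction, so the patch
  # triangle must traverse them reversed: (k, i, j)
  P <- st$pos[c(k, i, j), , drop = FALSE]
  st$patch_tris <- rbind(st$patch_tris, c(k, i, j))
  for (ord in list(c(1L, 2L, 3L), c(2L, 3L, 1L), c(3L, 1L, 2L))) {
    v <- c(k, i, j)[ord[1L]]
    st$vtris[[v]] <- rbind(st$vtris[[v]], P[ord, , drop = FALSE])
    st$vnorm[v, 1L] <- NA_real_
    st$tri_count[v] <- st$tri_count[v] + 1L
    st$ang_sum[v] <- st$ang_sum[v] +
      corner_angle(P[ord[1L], ], P[ord[2L], ], P[ord[3L], ])
  }
  st$alive[i] <- FALSE
  st$n_alive <- st$n_alive - 1L
  st$nxt[j] <- k
  st$prv[k] <- j
  # Weights needing refresh: every apex whose triple involves j or k (their
  # incident-triangle sets changed, which the projection test reads), i.e.
  # the apexes prv(j), j, k, nxt(k).
  unique(c(st$prv[j], j, k, st$nxt[k]))
}

#' Spanning triangulation of a hole boundary
#'
#' Weight-rule advancing triangulation: each step clips the ear with the
#' maximum weight (ties broken by the lowest original boundary index), until
#' fewer than three boundary vertices remain. Produces exactly |B| - 2
#' triangles over exactly the boundary vertices. The default implementation
#' keeps the weights in a priority queue (O(N log N)); \code{method =
#' "rescan"} is the quadratic reference that rescans every weight each step
#' with the same tie rule, used for cross-checking.
#'
#' @param loop n x 3 position matrix, or integer vertex ids with \code{mesh}.
#' @param mesh optional host mesh (provides surrounding triangles for the
#'   angle sums and projection tests, and the bounding-sphere radius).
#' @param alpha sharp-corner factor (default 1.2).
#' @param method \code{"queue"} (default) or \code{"rescan"}.
#' @return a \code{tc_patch}: list with \code{vertices} (the loop positions),
#'   \code{triangles} (local indices, wound consistently with the host),
#'   \code{boundary} (all TRUE), \code{host_ids}, and \code{fallbacks} (count
#'   of deadlock fallbacks used).
#' @export
triangulate_boundary <- function(loop, mesh = NULL, alpha = 1.2,
                                 method = c("queue", "rescan")) {
  method <- match.arg(method)
  if (is.matrix(loop) || is.data.frame(loop)) {
    pos <- as.matrix(loop)
    ids <- rep(NA_integer_, nrow(pos))
    st <- triangulation_state(pos, alpha = alpha)
  } else {
    ids <- as.integer(loop)
    pos <- mesh$vertices[ids, , drop = FALSE]
    st <- triangulation_state(pos, mesh = mesh, loop_ids = ids, alpha = alpha)
  }
  n <- st$n0
  if (n == 3L) {
    return(new_patch(pos, matrix(c(3L, 2L, 1L), 1L), ids))
  }
  fallbacks <- 0L

  if (method == "rescan") {
    while (st$n_alive >= 3L) {
      alive <- which(st$alive)
      w <- vapply(alive, function(i) triangle_weight(st, i), 0)
      if (all(!is.finite(w))) {
        w <- weights_no_projection(st, alive)
        fallbacks <- fallbacks + 1L
      }
      best <- alive[which(w == max(w))]
      state_clip(st, min(best))
    }
  } else {
    h <- heap_new(2L * n)
    push_weight <- function(i) {
      st$stamp[i] <- st$stamp[i] + 1L
      heap_push(h, triangle_weight(st, i), -i, i, st$stamp[i])
    }
    for (i in seq_len(n)) push_weight(i)
    while (st$n_alive >= 3L) {
      top <- heap_pop(h)
      if (is.null(top)) {
        # all weights consumed: refill
        for (i in which(st$alive)) push_weight(i)
        next
      }
      if (!st$alive[top$id] || top$stamp != st$stamp[top$id]) next
      if (!is.finite(top$w)) {
        # deadlock: every remaining candidate fails the projection test once;
        # fall back to the least-perimeter finite choice ignoring it
        alive <- which(st$alive)
        w <- weights_no_projection(st, alive)
        best <- alive[which(w == max(w))]
        touched <- state_clip(st, min(best))
        fallbacks <- fallbacks + 1L
        for (i in touched) if (st$alive[i]) push_weight(i)
        next
      }
      touched <- state_clip(st, top$id)
      for (i in touched) if (st$alive[i]) push_weight(i)
    }
  }
  patch <- new_patch(pos, st$patch_tris, ids)
  patch$fallbacks <- fallbacks
  patch
}

new_patch <- function(vertices, triangles, host_ids,
                      boundary = NULL, stage = "min") {
  vertices <- as.matrix(vertices)
  dimnames(vertices) <- NULL
  if (is.null(boundary)) boundary <- rep(TRUE, nrow(vertices))
  structure(list(vertices = vertices,
                 triangles = matrix(as.integer(triangles), ncol = 3L),
                 boundary = boundary, host_ids = host_ids, stage = stage),
            class = "tc_patch")
}

#' @export
print.tc_patch <- function(x, ...) {
  cat(sprintf("tc_patch [%s]: %d vertices (%d boundary), %d triangles\n",
              x$stage, nrow(x$vertices), sum(x$boundary), nrow(x$triangles)))
  invisible(x)
}

# Mean edge length of host triangles within `rings` rings of the loop.
surround_edge_length <- function(mesh, loop_ids, rings = 2L) {
  near <- unique(unlist(lapply(loop_ids, function(i)
    neighborhood_members(mesh$adj, i, rings)), use.names = FALSE))
  tset <- unique(unlist(mesh$vt[near], use.names = FALSE))
  tri <- mesh$triangles[tset, , drop = FALSE]
  e <- rbind(tri[, 1:2], tri[, 2:3], tri[, c(3L, 1L)])
  mean(rows_norm(mesh$vertices[e[, 1L], , drop = FALSE] -
                   mesh$vertices[e[, 2L], , drop = FALSE]))
}

#' Refine a spanning patch toward the surrounding mesh density
#'
#' Triangles whose mean edge length exceeds \code{c_factor} times the target
#' edge length (the surrounding mesh's mean) are split 1-to-3 at their
#' centroid; after each splitting sweep the interior edges are relaxed by
#' Delaunay edge flips (opposite-angle sum above pi), boundary edges never
#' flipped; iterated to a fixpoint.
#'
#' @param patch a \code{tc_patch}.
#' @param target_edge target mean edge length; computed from \code{mesh}
#'   within 2 rings of the patch boundary when omitted.
#' @param mesh optional host mesh for the target density.
#' @param c_factor density tolerance factor (default 1.5).
#' @return refined \code{tc_patch} (stage "refine").
#' @export
refine_patch <- function(patch, target_edge = NULL, mesh = NULL,
                         c_factor = 1.5) {
  if (is.null(target_edge)) {
    if (is.null(mesh)) stop("need target_edge or a host mesh")
    target_edge <- surround_edge_length(mesh, patch$host_ids)
  }
  V <- patch$vertices
  Tm <- patch$triangles
  boundary <- patch$boundary
  host_ids <- patch$host_ids
  nb <- length(host_ids)
  # boundary edge set (consecutive boundary vertices in the original loop)
  bnd_pairs <- cbind(seq_len(nb), c(seq_len(nb)[-1L], 1L))
  bnd_key <- paste(pmin(bnd_pairs[, 1L], bnd_pairs[, 2L]),
                   pmax(bnd_pairs[, 1L], bnd_pairs[, 2L]))

  tri_mean_edge <- function(V, t) {
    (vec_norm(V[t[1L], ] - V[t[2L], ]) + vec_norm(V[t[2L], ] - V[t[3L], ]) +
       vec_norm(V[t[3L], ] - V[t[1L], ])) / 3
  }

  for (sweep_i in seq_len(60L)) {
    men <- apply(Tm, 1L, function(t) tri_mean_edge(V, t))
    big <- which(men > c_factor * target_edge)
    # guard: only split when every new centroid edge stays above the target
    # scale (sqrt(2) |c - v| > target), otherwise splitting cannot terminate
    # on long thin triangles -- those are handled by the edge flips instead
    if (length(big)) {
      ok <- vapply(big, function(t) {
        tv <- Tm[t, ]
        ctr <- colMeans(V[tv, , drop = FALSE])
        all(sqrt(2) * rows_norm(V[tv, , drop = FALSE] -
                                  matrix(ctr, 3L, 3L, byrow = TRUE)) > target_edge)
      }, TRUE)
      big <- big[ok]
    }
    if (length(big) == 0L) break
    for (t in big) {
      tv <- Tm[t, ]
      ctr <- colMeans(V[tv, , drop = FALSE])
      V <- rbind(V, ctr)
      cid <- nrow(V)
      boundary <- c(boundary, FALSE)
      Tm[t, ] <- c(tv[1L], tv[2L], cid)
      Tm <- rbind(Tm, c(tv[2L], tv[3L], cid), c(tv[3L], tv[1L], cid))
    }
    # Delaunay relaxation: sweep all interior edges, flipping where the
    # opposite-angle sum exceeds pi; triangles touched in a sweep are locked
    # until the next sweep. Repeat to fixpoint.
    for (relax in seq_len(60L)) {
      nt <- nrow(Tm)
      ek <- rbind(Tm[, 1:2], Tm[, 2:3], Tm[, c(3L, 1L)])
      lo <- pmin(ek[, 1L], ek[, 2L]); hi <- pmax(ek[, 1L], ek[, 2L])
      key <- (as.numeric(lo) - 1) * nrow(V) + hi
      tid <- rep(seq_len(nt), 3L)
      ord <- order(key)
      key_s <- key[ord]; tid_s <- tid[ord]
      dup <- which(key_s[-1L] == key_s[-length(key_s)])
      edge_all_keys <- unique(key)
      bnd_num <- (as.numeric(pmin(bnd_pairs[, 1L], bnd_pairs[, 2L])) - 1) *
        nrow(V) + pmax(bnd_pairs[, 1L], bnd_pairs[, 2L])
      touched <- logical(nt)
      flips <- 0L
      for (di in dup) {
        ts <- c(tid_s[di], tid_s[di + 1L])
        if (touched[ts[1L]] || touched[ts[2L]]) next
        if (key_s[di] %in% bnd_num) next
        kk <- key_s[di]
        hi_v <- as.integer(kk %% nrow(V))
        if (hi_v == 0L) hi_v <- nrow(V)
        lo_v <- as.integer((kk - hi_v) / nrow(V)) + 1L
        ab <- c(lo_v, hi_v)
        t1 <- Tm[ts[1L], ]; t2 <- Tm[ts[2L], ]
        c1 <- setdiff(t1, ab); c2 <- setdiff(t2, ab)
        if (length(c1) != 1L || length(c2) != 1L || c1 == c2) next
        ang1 <- corner_angle(V[c1, ], V[ab[1L], ], V[ab[2L], ])
        ang2 <- corner_angle(V[c2, ], V[ab[1L], ], V[ab[2L], ])
        if (ang1 + ang2 <= pi + 1e-9) next
        cd_key <- (as.numeric(min(c1, c2)) - 1) * nrow(V) + max(c1, c2)
        if (cd_key %in% edge_all_keys) next
        dir1 <- directed_edge_in(t1, ab)
        a <- dir1[1L]; b <- dir1[2L]
        Tm[ts[1L], ] <- c(a, c2, c1)
        Tm[ts[2L], ] <- c(c2, b, c1)
        touched[ts] <- TRUE
        flips <- flips + 1L
      }
      if (flips == 0L) break
    }
  }
  out <- new_patch(V, Tm, host_ids, boundary = boundary, stage = "refine")
  out
}

# returns edge (a,b) as traversed by triangle t
directed_edge_in <- function(t, ab) {
  for (k in 1:3) {
    k2 <- if (k == 3L) 1L else k + 1L
    if (t[k] == ab[1L] && t[k2] == ab[2L]) return(c(ab[1L], ab[2L]))
    if (t[k] == ab[2L] && t[k2] == ab[1L]) return(c(ab[2L], ab[1L]))
  }
  stop("edge not in triangle")
}

# Glue one or more patches into the hole-bearing host mesh. Returns the glued
# vertex matrix, triangle matrix, per-patch vertex index maps, and the free
# (patch-interior) glued ids.
glue_patches <- function(mesh, patches) {
  V <- mesh$vertices
  Tm <- mesh$triangles
  maps <- list()
  free <- integer(0)
  for (pi_ in seq_along(patches)) {
    p <- patches[[pi_]]
    nvp <- nrow(p$vertices)
    map <- integer(nvp)
    for (v in seq_len(nvp)) {
      if (p$boundary[v]) {
        map[v] <- p$host_ids[v]
      } else {
        V <- rbind(V, p$vertices[v, ])
        map[v] <- nrow(V)
        free <- c(free, nrow(V))
      }
    }
    Tm <- rbind(Tm, matrix(map[p$triangles], ncol = 3L))
    maps[[pi_]] <- map
  }
  list(vertices = V, triangles = Tm, maps = maps, free = free)
}

# Cotangent Laplacian per the discrete rule Delta(v_i) =
# (2/Area(v_i)) sum cot-weights (v_i - v_j), Area = full 1-ring area sum.
cot_laplacian_matrix <- function(vertices, triangles) {
  nv <- nrow(vertices)
  p1 <- vertices[triangles[, 1L], , drop = FALSE]
  p2 <- vertices[triangles[, 2L], , drop = FALSE]
  p3 <- vertices[triangles[, 3L], , drop = FALSE]
  ang1 <- acos(pmin(1, pmax(-1, rowSums((p2 - p1) * (p3 - p1)) /
                              (rows_norm(p2 - p1) * rows_norm(p3 - p1)))))
  ang2 <- acos(pmin(1, pmax(-1, rowSums((p1 - p2) * (p3 - p2)) /
                              (rows_norm(p1 - p2) * rows_norm(p3 - p2)))))
  ang3 <- pi - ang1 - ang2
  areas <- rows_norm(rows_cross(p2 - p1, p3 - p1)) / 2
  ii <- c(triangles[, 1L], triangles[, 2L], triangles[, 3L])
  jj <- c(triangles[, 2L], triangles[, 3L], triangles[, 1L])
  ww <- c(cot(ang3), cot(ang1), cot(ang2))
  # symmetric accumulation of cot(alpha)+cot(beta) on both directions
  W <- Matrix::sparseMatrix(i = c(ii, jj), j = c(jj, ii), x = c(ww, ww),
                            dims = c(nv, nv))
  dsum <- Matrix::rowSums(W)
  ring_area <- as.vector(Matrix::sparseMatrix(
    i = ii, j = rep(1L, length(ii)), x = rep(areas, 3L), dims = c(nv, 1L)))
  scale <- 2 / pmax(ring_area, 1e-300)
  L <- Matrix::Diagonal(x = scale) %*% (Matrix::Diagonal(x = dsum) - W)
  L
}

#' Reshape patches by constrained k-harmonic fairing
#'
#' Glues the refined patches into the host mesh and solves the discrete
#' k-harmonic system (k-th power of the cotangent Laplacian equal to zero at
#' the free interior vertices, all other vertices pinned; the pinned collar
#' provides the C^(k-1) boundary continuity) for the interior positions.
#' k = 1 yields a membrane (area minimizer), k = 2 a thin plate (bending
#' minimizer, the dental default), k = 3 a curvature-variation minimizer.
#'
#' @param mesh hole-bearing host \code{tc_mesh}.
#' @param patches a \code{tc_patch} or list of them (stage "refine").
#' @param k harmonicity order, 1..3 (default 2).
#' @return list of deformed patches (stage "deform"), same connectivity, or a
#'   single patch if a single patch was supplied.
#' @export
reshape_patch <- function(mesh, patches, k = 2L) {
  single <- inherits(patches, "tc_patch")
  if (single) patches <- list(patches)
  if (!k %in% 1:3) stop("harmonicity order k must be 1, 2 or 3")
  gl <- glue_patches(mesh, patches)
  if (length(gl$free) == 0L) {
    out <- lapply(patches, function(p) { p$stage <- "deform"; p })
    return(if (single) out[[1L]] else out)
  }
  L <- cot_laplacian_matrix(gl$vertices, gl$triangles)
  Lk <- L
  if (k >= 2L) for (p in seq_len(k - 1L)) Lk <- Lk %*% L
  free <- gl$free
  A <- Lk[free, free, drop = FALSE]
  B <- Lk[free, -free, drop = FALSE]
  xc <- gl$vertices[-free, , drop = FALSE]
  rhs <- -as.matrix(B %*% xc)
  sol <- as.matrix(Matrix::solve(A, rhs))
  resid <- max(abs(A %*% sol - rhs))
  bbox <- vec_norm(apply(gl$vertices, 2L, max) - apply(gl$vertices, 2L, min))
  if (!is.finite(resid) || resid > 1e-6 * bbox) {
    stop("k-harmonic solve failed (singular or ill-conditioned system)")
  }
  newV <- gl$vertices
  newV[free, ] <- sol
  out <- vector("list", length(patches))
  for (pi_ in seq_along(patches)) {
    p <- patches[[pi_]]
    map <- gl$maps[[pi_]]
    p$vertices <- newV[map, , drop = FALSE]
    p$stage <- "deform"
    out[[pi_]] <- p
  }
  if (single) out[[1L]] else out
}

#' Blend the refined and deformed patch stages
#'
#' P_final = P_refine + lambda (P_deform - P_refine), vertexwise, with
#' 0 < lambda <= 1. Boundary vertices are identical in both stages and stay
#' fixed.
#'
#' @param refine,deform patches with identical connectivity (stages "refine"
#'   and "deform").
#' @param lambda blend parameter in (0, 1].
#' @return blended \code{tc_patch} (stage "final").
#' @export
blend_patch <- function(refine, deform, lambda) {
  if (!(lambda > 0 && lambda <= 1)) stop("lambda must lie in (0, 1]")
  if (!identical(dim(refine$vertices), dim(deform$vertices))) {
    stop("stage connectivity mismatch")
  }
  out <- deform
  out$vertices <- refine$vertices + lambda * (deform$vertices - refine$vertices)
  out$stage <- "final"
  out
}

# --- triangle-triangle intersection ---------------------------------------

tri_tri_intersect <- function(A, B, tol = 1e-12) {
  # A, B: 3x3 matrices (rows = corners). Plane-based interval test.
  nB <- vec_cross(B[2L, ] - B[1L, ], B[3L, ] - B[1L, ])
  dA <- as.vector((A - matrix(B[1L, ], 3L, 3L, byrow = TRUE)) %*% nB)
  scale <- max(rows_norm(A), rows_norm(B), 1e-300)
  eps <- tol * scale * max(vec_norm(nB), 1e-300)
  if (all(dA > eps) || all(dA < -eps)) return(FALSE)
  nA <- vec_cross(A[2L, ] - A[1L, ], A[3L, ] - A[1L, ])
  dB <- as.vector((B - matrix(A[1L, ], 3L, 3L, byrow = TRUE)) %*% nA)
  epsA <- tol * scale * max(vec_norm(nA), 1e-300)
  if (all(dB > epsA) || all(dB < -epsA)) return(FALSE)
  coplanar <- all(abs(dA) <= eps)
  if (coplanar) return(coplanar_tris_overlap(A, B, tol * scale))
  # segment clipping both ways is robust and simple at this problem size
  seg_hits_tri(A, B, eps) || seg_hits_tri(B, A, epsA)
}

seg_hits_tri <- function(S, Tt, eps) {
  n <- vec_cross(Tt[2L, ] - Tt[1L, ], Tt[3L, ] - Tt[1L, ])
  for (k in 1:3) {
    k2 <- if (k == 3L) 1L else k + 1L
    a <- S[k, ]; b <- S[k2, ]
    da <- sum((a - Tt[1L, ]) * n)
    db <- sum((b - Tt[1L, ]) * n)
    if ((da > eps && db > eps) || (da < -eps && db < -eps)) next
    if (abs(da - db) <= eps) next
    t <- da / (da - db)
    if (t < 0 || t > 1) next
    x <- a + t * (b - a)
    if (point_in_tri_3d(x, Tt, eps)) return(TRUE)
  }
  FALSE
}

point_in_tri_3d <- function(x, Tt, eps) {
  v0 <- Tt[2L, ] - Tt[1L, ]; v1 <- Tt[3L, ] - Tt[1L, ]; v2 <- x - Tt[1L, ]
  d00 <- sum(v0 * v0); d01 <- sum(v0 * v1); d11 <- sum(v1 * v1)
  d20 <- sum(v2 * v0); d21 <- sum(v2 * v1)
  den <- d00 * d11 - d01^2
  if (den <= 0) return(FALSE)
  v <- (d11 * d20 - d01 * d21) / den
  w <- (d00 * d21 - d01 * d20) / den
  u <- 1 - v - w
  e <- eps / max(sqrt(den), 1e-300)
  u >= -e && v >= -e && w >= -e
}

coplanar_tris_overlap <- function(A, B, tol) {
  n <- vec_cross(A[2L, ] - A[1L, ], A[3L, ] - A[1L, ])
  fr <- tangent_frame(n)
  to2d <- function(P) cbind(as.vector((P - matrix(A[1L, ], nrow(P), 3L, byrow = TRUE)) %*% fr$u),
                            as.vector((P - matrix(A[1L, ], nrow(P), 3L, byrow = TRUE)) %*% fr$v))
  A2 <- to2d(A); B2 <- to2d(B)
  for (i in 1:3) {
    i2 <- if (i == 3L) 1L else i + 1L
    for (j in 1:3) {
      j2 <- if (j == 3L) 1L else j + 1L
      if (segments_cross_2d(A2[i, ], A2[i2, ], B2[j, ], B2[j2, ], tol)) return(TRUE)
    }
  }
  point_in_tri_2d(B2[1L, ], A2) || point_in_tri_2d(A2[1L, ], B2)
}

point_in_tri_2d <- function(p, Tt) {
  s <- numeric(3)
  for (k in 1:3) {
    k2 <- if (k == 3L) 1L else k + 1L
    d <- Tt[k2, ] - Tt[k, ]
    s[k] <- d[1L] * (p[2L] - Tt[k, 2L]) - d[2L] * (p[1L] - Tt[k, 1L])
  }
  all(s > 0) || all(s < 0)
}

#' Do two patch meshes interfere?
#'
#' True iff some triangle of \code{a} intersects some triangle of \code{b},
#' excluding pairs that share a vertex (coincident positions within
#' tolerance). Axis-aligned bounding boxes prefilter the pairs.
#'
#' @param a,b \code{tc_patch} or \code{tc_mesh} objects (anything with
#'   \code{vertices} and \code{triangles}).
#' @param tol relative tolerance of the intersection predicate.
#' @return list with \code{intersects} (logical) and \code{witness} (pair of
#'   triangle indices or NULL).
#' @export
patches_intersect <- function(a, b, tol = 1e-12) {
  TA <- lapply(seq_len(nrow(a$triangles)), function(t)
    a$vertices[a$triangles[t, ], , drop = FALSE])
  TB <- lapply(seq_len(nrow(b$triangles)), function(t)
    b$vertices[b$triangles[t, ], , drop = FALSE])
  boxA <- t(vapply(TA, function(P) c(apply(P, 2L, min), apply(P, 2L, max)), numeric(6)))
  boxB <- t(vapply(TB, function(P) c(apply(P, 2L, min), apply(P, 2L, max)), numeric(6)))
  scale <- max(abs(boxA), abs(boxB), 1)
  pad <- 10 * tol * scale
  shares_vertex <- function(P, Q) {
    for (x in 1:3) for (y in 1:3) {
      if (vec_norm(P[x, ] - Q[y, ]) <= 1e-9 * scale) return(TRUE)
    }
    FALSE
  }
  for (i in seq_along(TA)) {
    hit <- which(boxB[, 1L] <= boxA[i, 4L] + pad & boxB[, 4L] >= boxA[i, 1L] - pad &
                   boxB[, 2L] <= boxA[i, 5L] + pad & boxB[, 5L] >= boxA[i, 2L] - pad &
                   boxB[, 3L] <= boxA[i, 6L] + pad & boxB[, 6L] >= boxA[i, 3L] - pad)
    for (j in hit) {
      if (shares_vertex(TA[[i]], TB[[j]])) next
      if (tri_tri_intersect(TA[[i]], TB[[j]], tol)) {
        return(list(intersects = TRUE, witness = c(i, j)))
      }
    }
  }
  list(intersects = FALSE, witness = NULL)
}

#' Restore a saddle hole with two per-tooth patches
#'
#' Full restoration pipeline for one fusion-region hole: bridge the loop into
#' two subholes using the occlusal plane, span each with the weight-rule
#' triangulation, refine to the surrounding density, reshape with the
#' constrained k-harmonic system, then lower the deformation degree lambda
#' from \code{lambda_max} in steps of \code{tau} until the two final patches
#' do not interfere (error if lambda would fall below 0.8).
#'
#' @param mesh hole-bearing \code{tc_mesh}.
#' @param loop boundary loop (integer vertex cycle).
#' @param plane occlusal \code{tc_plane}.
#' @param k harmonicity order (default 2, thin-plate).
#' @param lambda_max initial blend (default 1.0).
#' @param tau adjustment step (must be <= 0.01).
#' @param c_factor refinement density factor.
#' @return list with \code{mesh} (restored, stitched), \code{patches} (the
#'   two final patches), \code{stages} (per-subhole min/refine/deform
#'   patches), \code{lambda}, and \code{subholes}.
#' @export
restore_hole <- function(mesh, loop, plane, k = 2L, lambda_max = 1.0,
                         tau = 0.01, c_factor = 1.5) {
  if (tau > 0.01) stop("adjustment step tau should not be bigger than 0.01")
  if (!(lambda_max > 0 && lambda_max <= 1)) stop("lambda_max must lie in (0, 1]")
  sub <- bridge_hole(mesh, loop, plane)
  p1_min <- triangulate_boundary(sub$loop1, mesh = mesh)
  p2_min <- triangulate_boundary(sub$loop2, mesh = mesh)
  target <- surround_edge_length(mesh, loop)
  p1_ref <- refine_patch(p1_min, target_edge = target, c_factor = c_factor)
  p2_ref <- refine_patch(p2_min, target_edge = target, c_factor = c_factor)
  def <- reshape_patch(mesh, list(p1_ref, p2_ref), k = k)
  lambda <- lambda_max
  final1 <- final2 <- NULL
  repeat {
    f1 <- blend_patch(p1_ref, def[[1L]], lambda)
    f2 <- blend_patch(p2_ref, def[[2L]], lambda)
    if (!patches_intersect(f1, f2)$intersects) {
      final1 <- f1; final2 <- f2
      break
    }
    lambda <- lambda - tau
    if (lambda < 0.8 - 1e-12) {
      stop("patch interference persists at the lambda floor (0.8); ",
           "inspect the deformation stages")
    }
  }
  restored <- stitch_patches(mesh, list(final1, final2))
  list(mesh = restored, patches = list(final1, final2),
       stages = list(list(min = p1_min, refine = p1_ref, deform = def[[1L]]),
                     list(min = p2_min, refine = p2_ref, deform = def[[2L]])),
       lambda = lambda, subholes = sub)
}

#' Stitch patches into the host mesh
#'
#' @param mesh hole-bearing host mesh.
#' @param patches list of final patches (with host boundary ids).
#' @return a watertight \code{tc_mesh} when the host minus its holes was
#'   closed.
#' @export
stitch_patches <- function(mesh, patches) {
  gl <- glue_patches(mesh, patches)
  tc_mesh(gl$vertices, gl$triangles)
}
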