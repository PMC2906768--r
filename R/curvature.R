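# Per-vertex differential analysis: cotangent-weighted normals, local-frame
# quadric fitting, principal curvatures, inverse-distance curvature smoothing,
# and the Laplace-Beltrami (Meyer) baseline estimator.

# Cotangent weights, Meyer mixed areas and 1-ring triangle area sums.
cotangent_weights <- function(mesh) {
  tri <- mesh$triangles
  V <- mesh$vertices
  nv <- nrow(V)
  p1 <- V[tri[, 1L], , drop = FALSE]
  p2 <- V[tri[, 2L], , drop = FALSE]
  p3 <- V[tri[, 3L], , drop = FALSE]
  ang1 <- acos(pmin(1, pmax(-1, rowSums((p2 - p1) * (p3 - p1)) /
                              (rows_norm(p2 - p1) * rows_norm(p3 - p1)))))
  ang2 <- acos(pmin(1, pmax(-1, rowSums((p1 - p2) * (p3 - p2)) /
                              (rows_norm(p1 - p2) * rows_norm(p3 - p2)))))
  ang3 <- pi - ang1 - ang2
  areas <- rows_norm(rows_cross(p2 - p1, p3 - p1)) / 2

  # cot weight of edge (i,j) accumulates the cotangent of the opposite angle
  ei <- c(tri[, 1L], tri[, 2L], tri[, 3L])
  ej <- c(tri[, 2L], tri[, 3L], tri[, 1L])
  opp <- c(cot(ang3), cot(ang1), cot(ang2))
  nvv <- as.numeric(nv)
  key <- (pmin(ei, ej) - 1) * nvv + pmax(ei, ej)
  ekey <- (mesh$edges[, 1L] - 1) * nvv + mesh$edges[, 2L]
  eid <- match(key, ekey)
  cotsum <- as.vector(tapply(opp, factor(eid, levels = seq_len(nrow(mesh$edges))),
                             sum, default = 0))
  cotsum[is.na(cotsum)] <- 0

  # Meyer mixed area per vertex
  amixed <- numeric(nv)
  ring_area <- numeric(nv)
  corner_ang <- cbind(ang1, ang2, ang3)
  for (c0 in 1:3) {
    vids <- tri[, c0]
    ring_area <- ring_area + as.vector(tapply(areas, factor(vids, levels = seq_len(nv)), sum, default = 0))
  }
  ring_area[is.na(ring_area)] <- 0
  obtuse <- corner_ang > pi / 2
  any_obtuse <- obtuse[, 1L] | obtuse[, 2L] | obtuse[, 3L]
  contrib <- matrix(0, nrow(tri), 3L)
  for (c0 in 1:3) {
    others <- setdiff(1:3, c0)
    # Voronoi area at corner c0: (|e1|^2 cot(opp1) + |e2|^2 cot(opp2)) / 8
    e1 <- V[tri[, others[1L]], , drop = FALSE] - V[tri[, c0], , drop = FALSE]
    e2 <- V[tri[, others[2L]], , drop = FALSE] - V[tri[, c0], , drop = FALSE]
    vor <- (rowSums(e1 * e1) * cot(corner_ang[, others[2L]]) +
              rowSums(e2 * e2) * cot(corner_ang[, others[1L]])) / 8
    contrib[, c0] <- ifelse(!any_obtuse, vor,
                            ifelse(obtuse[, c0], areas / 2, areas / 4))
  }
  for (c0 in 1:3) {
    vids <- tri[, c0]
    amixed <- amixed + as.vector(tapply(contrib[, c0],
                                        factor(vids, levels = seq_len(nv)),
                                        sum, default = 0))
  }
  amixed[is.na(amixed)] <- 0
  list(edges = mesh$edges, cot = cotsum, a_mixed = amixed,
       ring_area = ring_area, corner_angles = corner_ang, tri_areas = areas)
}

#' Per-vertex unit normals
#'
#' Cotangent-weighted normal direction, normalized to unit length (the
#' leading area constant is irrelevant after normalization) and aligned with
#' the consistent outward side of the mesh; the area-weighted face-normal
#' average is the fallback wherever the cotangent sum degenerates (flat or
#' saddle cancellation, boundary vertices).
#'
#' @param mesh a \code{tc_mesh}.
#' @param i optional single vertex index; default all vertices.
#' @return n x 3 matrix of unit normals (or a single 3-vector if \code{i}
#'   given).
#' @export
vertex_normals <- function(mesh, i = NULL) {
  V <- mesh$vertices
  nv <- nrow(V)
  tn <- triangle_normals(mesh)
  # area-weighted face-normal average: orientation reference
  acc <- matrix(0, nv, 3L)
  w <- tn$areas
  for (c0 in 1:3) {
    vids <- mesh$triangles[, c0]
    acc[, 1L] <- acc[, 1L] + as.vector(tapply(w * tn$normals[, 1L], factor(vids, levels = seq_len(nv)), sum, default = 0))
    acc[, 2L] <- acc[, 2L] + as.vector(tapply(w * tn$normals[, 2L], factor(vids, levels = seq_len(nv)), sum, default = 0))
    acc[, 3L] <- acc[, 3L] + as.vector(tapply(w * tn$normals[, 3L], factor(vids, levels = seq_len(nv)), sum, default = 0))
  }
  acc[is.na(acc)] <- 0

  cw <- cotangent_weights(mesh)
  diffs <- V[cw$edges[, 1L], , drop = FALSE] - V[cw$edges[, 2L], , drop = FALSE]
  cotd <- cw$cot * diffs
  ksum <- matrix(0, nv, 3L)
  for (col in 1:3) {
    s1 <- tapply(cotd[, col], factor(cw$edges[, 1L], levels = seq_len(nv)), sum, default = 0)
    s2 <- tapply(-cotd[, col], factor(cw$edges[, 2L], levels = seq_len(nv)), sum, default = 0)
    ksum[, col] <- as.vector(s1) + as.vector(s2)
  }
  ksum[is.na(ksum)] <- 0

  boundary_v <- unique(as.vector(mesh$edges[mesh$edge_count == 1L, ]))
  out <- matrix(0, nv, 3L)
  scale <- mesh_mean_edge_length(mesh)
  for (vi in seq_len(nv)) {
    k <- ksum[vi, ]
    a <- acc[vi, ]
    use_fallback <- vi %in% boundary_v ||
      vec_norm(k) < 1e-8 * scale || sum(k * a) == 0
    n <- if (use_fallback) a else {
      kk <- k / vec_norm(k)
      if (sum(kk * a) < 0) -kk else kk
    }
    nn <- vec_norm(n)
    out[vi, ] <- if (nn == 0) c(0, 0, 1) else n / nn
  }
  if (!is.null(i)) return(out[i, ])
  out
}

#' Weighted local quadric fit at a vertex
#'
#' Fits the degree-2 height function phi(u, v) = sum a_ks u^k v^s
#' (0 <= k+s <= 2, six coefficients) over the k nearest n-ring neighbors of
#' the vertex, expressed in the vertex's local tangent frame, by weighted
#' least squares with weights exp(-d_j / max_j d_j) where d_j is the
#' neighbor's distance from the vertex.
#'
#' @param mesh a \code{tc_mesh}.
#' @param i vertex index.
#' @param k neighbor count (16..20 recommended; default 18).
#' @param normals optional precomputed vertex normal matrix.
#' @return list with \code{coef} (a00, a10, a01, a20, a11, a02),
#'   \code{k_used}, weighted residual \code{delta}, and the \code{frame}.
#' @export
fit_local_quadric <- function(mesh, i, k = 18L, normals = NULL) {
  if (is.null(normals)) normals <- vertex_normals(mesh)
  fr <- tangent_frame(normals[i, ])
  adj <- mesh$adj
  n_ring <- 1L
  cand <- setdiff(neighborhood_members(adj, i, n_ring), i)
  while (length(cand) < k && n_ring < 8L) {
    n_ring <- n_ring + 1L
    cand <- setdiff(neighborhood_members(adj, i, n_ring), i)
  }
  if (length(cand) < 6L) stop("fewer than 6 neighbors available for quadric fit")
  p0 <- mesh$vertices[i, ]
  rel <- sweep(mesh$vertices[cand, , drop = FALSE], 2L, p0)
  d <- rows_norm(rel)
  sel <- order(d)[seq_len(min(k, length(cand)))]

  for (attempt in 0:3) {
    use <- cand[sel]
    rel_u <- sweep(mesh$vertices[use, , drop = FALSE], 2L, p0)
    uu <- as.vector(rel_u %*% fr$u)
    vv <- as.vector(rel_u %*% fr$v)
    ph <- as.vector(rel_u %*% fr$n)
    dj <- rows_norm(rel_u)
    w <- exp(-dj / max(dj))
    X <- cbind(1, uu, vv, uu^2, uu * vv, vv^2)
    Xw <- X * sqrt(w)
    yw <- ph * sqrt(w)
    qrX <- qr(Xw)
    if (qrX$rank == 6L) {
      a <- qr.coef(qrX, yw)
      resid <- sum(w * (as.vector(X %*% a) - ph)^2)
      return(list(coef = as.vector(a), k_used = length(use), delta = resid,
                  frame = fr, neighbors = use))
    }
    # degenerate configuration: enlarge the ring and retry
    n_ring <- n_ring + 1L
    cand <- setdiff(neighborhood_members(adj, i, n_ring), i)
    rel <- sweep(mesh$vertices[cand, , drop = FALSE], 2L, p0)
    d <- rows_norm(rel)
    sel <- order(d)[seq_len(min(k + 4L * (attempt + 1L), length(cand)))]
  }
  stop("rank-deficient quadric fit at vertex ", i)
}

# Curvatures of the fitted quadric at (0, 0) from its fundamental forms,
# sign convention: convex toward the outward normal is positive (hills
# kappa_min > 0, valleys kappa_min < 0).
quadric_curvatures <- function(a) {
  a10 <- a[2L]; a01 <- a[3L]; a20 <- a[4L]; a11 <- a[5L]; a02 <- a[6L]
  E <- 1 + a10^2; FF <- a10 * a01; G <- 1 + a01^2
  W <- sqrt(1 + a10^2 + a01^2)
  L <- 2 * a20 / W; M <- a11 / W; N <- 2 * a02 / W
  den <- E * G - FF^2
  kG <- (L * N - M^2) / den
  kH <- -(E * N - 2 * FF * M + G * L) / (2 * den)  # negated: outward-normal height
  c(kH = kH, kG = kG)
}

#' Principal curvatures at one vertex (quadric estimator)
#'
#' @param mesh a \code{tc_mesh}.
#' @param i vertex index.
#' @param k neighbor count (default 18).
#' @param normals optional precomputed normals.
#' @return named vector (kappa_min, kappa_max, kappa_H, kappa_G).
#' @export
principal_curvatures <- function(mesh, i, k = 18L, normals = NULL) {
  fit <- fit_local_quadric(mesh, i, k = k, normals = normals)
  kk <- quadric_curvatures(fit$coef)
  disc <- kk[["kH"]]^2 - kk[["kG"]]
  if (disc < -1e-9) stop("negative principal-curvature discriminant at vertex ", i)
  s <- sqrt(max(disc, 0))
  c(kappa_min = kk[["kH"]] - s, kappa_max = kk[["kH"]] + s,
    kappa_H = kk[["kH"]], kappa_G = kk[["kG"]])
}

#' Curvature field over all vertices
#'
#' Runs the quadric estimator (or the Meyer baseline) at every vertex.
#'
#' @param mesh a \code{tc_mesh}.
#' @param k neighbor count for the quadric estimator.
#' @param estimator \code{"quadric"} (default) or \code{"meyer"}.
#' @param smooth_passes number of inverse-distance smoothing passes applied
#'   to every channel after estimation (default 0; the feature-extraction
#'   pipeline uses 1).
#' @return object of class \code{tc_curvature}: data.frame with columns
#'   kappa_min, kappa_max, kappa_H, kappa_G plus attributes \code{estimator}
#'   and \code{smoothed}.
#' @export
curvature_field <- function(mesh, k = 18L, estimator = c("quadric", "meyer"),
                            smooth_passes = 0L) {
  estimator <- match.arg(estimator)
  nv <- nrow(mesh$vertices)
  out <- matrix(NA_real_, nv, 4L,
                dimnames = list(NULL, c("kappa_min", "kappa_max", "kappa_H", "kappa_G")))
  if (estimator == "quadric") {
    normals <- vertex_normals(mesh)
    for (i in seq_len(nv)) {
      out[i, ] <- principal_curvatures(mesh, i, k = k, normals = normals)
    }
  } else {
    cw <- cotangent_weights(mesh)
    normals <- vertex_normals(mesh)
    boundary_v <- unique(as.vector(mesh$edges[mesh$edge_count == 1L, ]))
    for (i in seq_len(nv)) {
      if (i %in% boundary_v) next
      mk <- meyer_vertex(mesh, i, cw, normals)
      disc <- max(mk[["kappa_H"]]^2 - mk[["kappa_G"]], 0)
      s <- sqrt(disc)
      out[i, ] <- c(mk[["kappa_H"]] - s, mk[["kappa_H"]] + s,
                    mk[["kappa_H"]], mk[["kappa_G"]])
    }
  }
  field <- structure(as.data.frame(out), estimator = estimator,
                     smoothed = FALSE, class = c("tc_curvature", "data.frame"))
  if (smooth_passes > 0L) field <- smooth_curvature(mesh, field, passes = smooth_passes)
  field
}

#' Inverse-distance curvature smoothing
#'
#' Replaces each vertex value by the inverse-distance-weighted average of its
#' 1-ring neighbor values (weights 1/||v_i - v_j||, normalized per vertex to
#' sum to 1; the center's own value is excluded by default, as printed in the
#' defining rule).
#'
#' @param mesh a \code{tc_mesh}.
#' @param field a \code{tc_curvature} (all channels smoothed) or numeric
#'   vector (one channel).
#' @param passes number of passes (default 1).
#' @param include_center include the center vertex in the stencil
#'   (default FALSE).
#' @return smoothed field of the same type, \code{smoothed} attribute set.
#' @export
smooth_curvature <- function(mesh, field, passes = 1L, include_center = FALSE) {
  adj <- mesh$adj
  V <- mesh$vertices
  nv <- nrow(V)
  wlist <- vector("list", nv)
  for (i in seq_len(nv)) {
    nb <- adj[[i]]
    d <- rows_norm(sweep(V[nb, , drop = FALSE], 2L, V[i, ]))
    w <- ifelse(d == 0, 1e12, 1 / pmax(d, 1e-300))
    w <- pmin(w, 1e12)
    if (include_center) {
      nb <- c(i, nb)
      w <- c(max(w), w)
    }
    wlist[[i]] <- list(nb = nb, w = w / sum(w))
  }
  one_pass <- function(x) {
    vapply(seq_len(nv), function(i) sum(wlist[[i]]$w * x[wlist[[i]]$nb]), 0)
  }
  smooth_vec <- function(x) {
    for (p in seq_len(passes)) x <- one_pass(x)
    x
  }
  if (is.numeric(field)) return(smooth_vec(field))
  out <- field
  for (col in names(field)) out[[col]] <- smooth_vec(field[[col]])
  attr(out, "smoothed") <- TRUE
  out
}

meyer_vertex <- function(mesh, i, cw, normals) {
  eidx <- which(cw$edges[, 1L] == i | cw$edges[, 2L] == i)
  e <- cw$edges[eidx, , drop = FALSE]
  other <- ifelse(e[, 1L] == i, e[, 2L], e[, 1L])
  diffs <- sweep(-mesh$vertices[other, , drop = FALSE], 2L, -mesh$vertices[i, ])
  K <- colSums(cw$cot[eidx] * diffs) / (2 * cw$a_mixed[i])
  kH <- sum(K * normals[i, ]) / 2
  # angle deficit
  tris <- mesh$vt[[i]]
  angs <- vapply(tris, function(t) {
    corner <- which(mesh$triangles[t, ] == i)
    cw$corner_angles[t, corner]
  }, 0)
  kG <- (2 * pi - sum(angs)) / cw$a_mixed[i]
  c(kappa_H = kH, kappa_G = kG)
}

#' Meyer operator baseline at one interior vertex
#'
#' Mean curvature from the cotangent Laplace-Beltrami formula with Meyer
#' mixed areas (obtuse-triangle special case included), Gaussian curvature
#' from the angle deficit over the mixed area. Used as the comparison
#' baseline for the quadric estimator's noise robustness.
#'
#' @param mesh a \code{tc_mesh}.
#' @param i interior vertex index.
#' @return named vector (kappa_H, kappa_G).
#' @export
meyer_curvature <- function(mesh, i) {
  boundary_v <- unique(as.vector(mesh$edges[mesh$edge_count == 1L, ]))
  if (i %in% boundary_v) stop("Meyer baseline undefined at boundary vertex ", i)
  cw <- cotangent_weights(mesh)
  normals <- vertex_normals(mesh)
  meyer_vertex(mesh, i, cw, normals)
}
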