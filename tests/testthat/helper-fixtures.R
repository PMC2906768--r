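# Shared fixtures, built in code.

# Unit cube as 12-triangle soup (binary STL content written on demand).
cube_soup <- function() {
  v <- rbind(
    c(0, 0, 0), c(1, 0, 0), c(1, 1, 0), c(0, 1, 0),
    c(0, 0, 1), c(1, 0, 1), c(1, 1, 1), c(0, 1, 1))
  quads <- list(c(1, 4, 3, 2),  # bottom (z=0), outward -z
                c(5, 6, 7, 8),  # top
                c(1, 2, 6, 5),  # y=0
                c(2, 3, 7, 6),  # x=1
                c(3, 4, 8, 7),  # y=1
                c(4, 1, 5, 8))  # x=0
  tri <- do.call(rbind, lapply(quads, function(q)
    rbind(q[c(1, 2, 3)], q[c(1, 3, 4)])))
  list(vertices = v, triangles = tri)
}

cube_mesh <- function() {
  cs <- cube_soup()
  tc_mesh(cs$vertices, cs$triangles)
}

# Fan mesh: center vertex 1 surrounded by m ring vertices on a circle,
# heights from f(u, v); triangulated as a closed fan (boundary = ring).
fan_mesh <- function(m = 8, radius = 1, f = function(u, v) 0 * u) {
  th <- 2 * pi * (seq_len(m) - 1) / m
  u <- radius * cos(th)
  v <- radius * sin(th)
  verts <- rbind(c(0, 0, f(0, 0)), cbind(u, v, f(u, v)))
  tri <- cbind(1L, 1L + seq_len(m), 1L + c(seq_len(m)[-1L], 1L))
  tc_mesh(verts, tri)
}

# Quadric sample mesh: center at origin plus two rings on z = f(u, v),
# fan-triangulated; used for estimator exactness checks.
quadric_patch_mesh <- function(f, m = 10, r1 = 0.4, r2 = 0.8) {
  th1 <- 2 * pi * (seq_len(m) - 1) / m
  th2 <- 2 * pi * (seq_len(m) - 0.5) / m
  u <- c(r1 * cos(th1), r2 * cos(th2))
  v <- c(r1 * sin(th1), r2 * sin(th2))
  verts <- rbind(c(0, 0, f(0, 0)), cbind(u, v, f(u, v)))
  inner <- 1L + seq_len(m)
  outer <- 1L + m + seq_len(m)
  tri <- cbind(1L, inner, c(inner[-1L], inner[1L]))
  for (j in seq_len(m)) {
    j2 <- if (j == m) 1L else j + 1L
    tri <- rbind(tri,
                 c(inner[j], outer[j], inner[j2]),
                 c(inner[j2], outer[j], outer[j2]))
  }
  tc_mesh(verts, tri)
}

# Betti numbers (b0, b1) of the subcomplex induced by a vertex subset:
# vertices + edges + triangles entirely inside the subset.
region_betti <- function(mesh, members) {
  if (length(members) == 0L) return(c(b0 = 0L, b1 = 0L))
  inset <- logical(nrow(mesh$vertices))
  inset[members] <- TRUE
  nE <- sum(inset[mesh$edges[, 1L]] & inset[mesh$edges[, 2L]])
  tri <- mesh$triangles
  nF <- sum(inset[tri[, 1L]] & inset[tri[, 2L]] & inset[tri[, 3L]])
  lab <- toothcarve:::subset_components(mesh$adj, members)
  b0 <- max(lab)
  chi <- length(members) - nE + nF
  c(b0 = b0, b1 = b0 - chi)
}

rows_dist <- function(M, p) sqrt(rowSums(sweep(M, 2L, p)^2))

# Brute-force n-ring via BFS on the vertex adjacency graph.
bfs_ring <- function(mesh, i, n) {
  members <- i
  frontier <- i
  for (s in seq_len(n)) {
    nxt <- setdiff(unique(unlist(mesh$adj[frontier])), members)
    members <- c(members, nxt)
    frontier <- nxt
  }
  sort(members)
}

# Jagged non-planar closed loop: circle with sinusoidal height jitter.
jagged_loop <- function(n, radius = 10, seed = 1) {
  set.seed(seed)
  th <- 2 * pi * (seq_len(n) - 1) / n
  r <- radius * (1 + 0.06 * sin(7 * th) + 0.02 * stats::runif(n, -1, 1))
  z <- 1.2 * sin(3 * th) + 0.2 * stats::rnorm(n)
  cbind(r * cos(th), r * sin(th), z)
}

# Sphere with a cap removed: returns the open mesh and its boundary loop.
sphere_with_cap_hole <- function(subdiv = 3, cap_z = 0.85) {
  s <- make_icosphere(subdiv)
  drop_v <- which(s$vertices[, 3L] > cap_z)
  tri <- s$triangles
  keep <- !(tri[, 1L] %in% drop_v | tri[, 2L] %in% drop_v | tri[, 3L] %in% drop_v)
  used <- sort(unique(as.vector(tri[keep, ])))
  m <- tc_mesh(s$vertices[used, , drop = FALSE],
               matrix(match(tri[keep, ], used), ncol = 3L))
  loops <- boundary_loops(m)
  stopifnot(length(loops) == 1L)
  list(mesh = m, loop = loops[[1L]])
}

# --- small 2D helpers used above -------------------------------------------
vec3_cross_z <- function(a, b) a[1L] * b[2L] - a[2L] * b[1L]

tris_overlap_2d <- function(A, B) {
  # strict interior overlap of 2D triangles: any edge pair crossing or one
  # triangle's centroid strictly inside the other
  cross <- function(o, a, b) (a[1L] - o[1L]) * (b[2L] - o[2L]) -
    (a[2L] - o[2L]) * (b[1L] - o[1L])
  seg_int <- function(p1, p2, q1, q2) {
    d1 <- cross(q1, q2, p1); d2 <- cross(q1, q2, p2)
    d3 <- cross(p1, p2, q1); d4 <- cross(p1, p2, q2)
    ((d1 > 1e-12 && d2 < -1e-12) || (d1 < -1e-12 && d2 > 1e-12)) &&
      ((d3 > 1e-12 && d4 < -1e-12) || (d3 < -1e-12 && d4 > 1e-12))
  }
  inside <- function(p, Tt) {
    s <- c(cross(Tt[1L, ], Tt[2L, ], p), cross(Tt[2L, ], Tt[3L, ], p),
           cross(Tt[3L, ], Tt[1L, ], p))
    all(s > 1e-12) || all(s < -1e-12)
  }
  for (i in 1:3) {
    for (j in 1:3) {
      if (seg_int(A[i, ], A[if (i == 3) 1 else i + 1, ],
                  B[j, ], B[if (j == 3) 1 else j + 1, ])) return(TRUE)
    }
  }
  inside(colMeans(A), B) || inside(colMeans(B), A)
}

new_patch_for_test <- function(vertices, triangles) {
  toothcarve:::new_patch(vertices, triangles, rep(NA_integer_, nrow(vertices)))
}

# 1-ring triangle area sums per vertex (thin-plate energy weights)
ring_area_of <- function(V, Tm) {
  a <- V[Tm[, 1L], , drop = FALSE]
  b <- V[Tm[, 2L], , drop = FALSE]
  cc <- V[Tm[, 3L], , drop = FALSE]
  cr <- cbind((b[,2]-a[,2])*(cc[,3]-a[,3])-(b[,3]-a[,3])*(cc[,2]-a[,2]),
              (b[,3]-a[,3])*(cc[,1]-a[,1])-(b[,1]-a[,1])*(cc[,3]-a[,3]),
              (b[,1]-a[,1])*(cc[,2]-a[,2])-(b[,2]-a[,2])*(cc[,1]-a[,1]))
  areas <- sqrt(rowSums(cr^2)) / 2
  out <- numeric(nrow(V))
  for (c0 in 1:3) {
    s <- tapply(areas, factor(Tm[, c0], levels = seq_len(nrow(V))), sum, default = 0)
    out <- out + as.vector(s)
  }
  out[is.na(out)] <- 0
  out
}
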