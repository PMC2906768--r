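# oracle: best-fit plane by coarse search over normal directions + Nelder-Mead
# refinement of the orthogonal-residual objective
oracle_plane_residual <- function(points) {
  obj <- function(par) {
    th <- par[1L]; phi <- par[2L]
    n <- c(sin(th) * cos(phi), sin(th) * sin(phi), cos(th))
    d <- as.vector(points %*% n)
    sum((d - mean(d))^2)
  }
  grid <- expand.grid(th = seq(0.01, pi, length.out = 25),
                      phi = seq(0, 2 * pi, length.out = 25))
  vals <- apply(grid, 1L, obj)
  start <- as.numeric(grid[which.min(vals), ])
  opt <- stats::optim(start, obj, control = list(reltol = 1e-14, maxit = 2000))
  opt$value
}

test_that("occlusal plane is the total-least-squares plane", {
  pts <- rbind(c(0, 0, 1), c(1, 0, 1), c(0, 1, 1), c(1, 1, 1))
  pl <- fit_occlusal_plane(pts)
  expect_equal(pl$residual, 0, tolerance = 1e-12)
  expect_equal(abs(pl$normal[3L]), 1, tolerance = 1e-12)

  eps <- 0.05
  pts2 <- rbind(c(0, 0, eps), c(0, 1, -eps), c(1, 0, -eps), c(1, 1, eps))
  pl2 <- fit_occlusal_plane(pts2)
  expect_equal(abs(pl2$normal[3L]), 1, tolerance = 1e-12)  # z = 0 by symmetry
  expect_equal(pl2$offset, 0, tolerance = 1e-12)

  set.seed(3)
  for (rep_i in 1:5) {
    pts3 <- matrix(stats::rnorm(12), 4L, 3L)
    pl3 <- fit_occlusal_plane(pts3)
    expect_equal(pl3$residual, oracle_plane_residual(pts3), tolerance = 1e-9)
  }
  expect_error(fit_occlusal_plane(rbind(c(0, 0, 0), c(1, 1, 1), c(2, 2, 2), c(3, 3, 3))),
               "collinear")
})

test_that("saddle-hole bridging finds the two farthest points and splits arcs", {
  # fan over z = x*y: boundary is the unit circle sampled at 8 points
  m <- fan_mesh(8, 1, f = function(u, v) u * v)
  loop <- boundary_loops(m)[[1L]]
  plane <- structure(list(normal = c(0, 0, 1), offset = -10, points = NULL,
                          residual = 0), class = "tc_plane")
  sub <- bridge_hole(m, loop, plane)
  # farthest from z = -10 are the two z = +0.5 points at 45 and 225 degrees
  bz <- m$vertices[sub$bridge, 3L]
  expect_equal(bz, c(0.5, 0.5), tolerance = 1e-12)
  expect_equal(length(sub$loop1) + length(sub$loop2), length(loop) + 2L)
  # symmetric saddle: mirror-image subloops
  expect_lte(abs(length(sub$loop1) - length(sub$loop2)), 1L)
  expect_error(bridge_hole(m, loop[1:5], plane), "too short")
})

test_that("triangle weights follow the printed priority cases", {
  th <- 2 * pi * (0:5) / 6
  hexagon <- cbind(cos(th), sin(th), 0)
  # place three consecutive vertices as a unit equilateral triangle
  pos <- rbind(c(0, 0, 0), c(1, 0, 0), c(0.5, sqrt(3) / 2, 0),
               c(1.5, 2, 0), c(0.5, 3, 0), c(-1, 1.5, 0))
  st <- triangulation_state(pos)
  # apex 2 between 1 and 3: all edges length 1, no incident triangles yet
  expect_equal(triangle_weight(st, 2L), -3, tolerance = 1e-12)

  st$tri_count[2L] <- 9L
  st$R_C <- 5
  expect_equal(triangle_weight(st, 2L), (9 / 8) * 5, tolerance = 1e-12)
  st$tri_count[2L] <- 0L

  # sharp corner: 0 < A < alpha*pi gives the l_less deprioritization
  st$ang_sum[2L] <- pi / 2
  expect_equal(triangle_weight(st, 2L), -(pi / (pi / 2)) * 5, tolerance = 1e-12)
  st$ang_sum[2L] <- 0

  # existing spoke at vertex 2 crossing the would-be edge 1-3 => -Inf
  # (spoke (1,0,0)->(0,0.3,0) crosses the new edge (0,0,0)->(0.5,0.866,0))
  st$vtris[[2L]] <- rbind(pos[2L, ], c(0, 0.3, 0), c(1.5, 1, 0))
  st$vnorm[2L, 1L] <- NA_real_
  st$tri_count[2L] <- 1L
  expect_identical(triangle_weight(st, 2L), -Inf)
})

test_that("spanning triangulation yields exactly |B|-2 triangles", {
  tri1 <- triangulate_boundary(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0)))
  expect_equal(nrow(tri1$triangles), 1L)

  lp <- jagged_loop(241)
  p <- triangulate_boundary(lp)
  expect_equal(nrow(p$triangles), 239L)
  expect_equal(nrow(p$vertices), 241L)
  expect_setequal(as.vector(p$triangles), 1:241)

  lp4 <- jagged_loop(437, seed = 2)
  p4 <- triangulate_boundary(lp4)
  expect_equal(nrow(p4$triangles), 435L)
})

test_that("planar convex polygon triangulates without overlap, one-sided normals", {
  th <- 2 * pi * (0:9) / 10
  decagon <- cbind(cos(th), sin(th), 0)
  p <- triangulate_boundary(decagon)
  expect_equal(nrow(p$triangles), 8L)
  # all normals on one side
  zs <- apply(p$triangles, 1L, function(t) {
    a <- p$vertices[t[1L], ]; b <- p$vertices[t[2L], ]; cc <- p$vertices[t[3L], ]
    sign(vec3_cross_z(b - a, cc - a))
  })
  expect_true(all(zs == zs[1L]))
  # exhaustive pairwise overlap check in the plane
  for (i in seq_len(nrow(p$triangles) - 1L)) {
    for (j in seq((i + 1L), nrow(p$triangles))) {
      expect_false(tris_overlap_2d(p$vertices[p$triangles[i, ], 1:2],
                                   p$vertices[p$triangles[j, ], 1:2]))
    }
  }
})

test_that("queue triangulation is triangle-for-triangle identical to the rescan reference", {
  set.seed(99)
  for (rep_i in 1:10) {
    n <- sample(10:60, 1L)
    th <- sort(stats::runif(n, 0, 2 * pi))
    lp <- cbind(cos(th) * (3 + stats::runif(n, -0.4, 0.4)),
                sin(th) * (3 + stats::runif(n, -0.4, 0.4)),
                0.6 * stats::rnorm(n))
    pq <- triangulate_boundary(lp, method = "queue")
    pr <- triangulate_boundary(lp, method = "rescan")
    expect_identical(pq$triangles, pr$triangles)
  }
})

test_that("1-3 refinement matches the surrounding density and the split rule", {
  # one big triangle, target chosen to allow exactly one split sweep
  tri <- rbind(c(0, 0, 0), c(4, 0, 0), c(2, 3, 0))
  p <- new_patch_for_test(tri, matrix(c(1L, 2L, 3L), 1L))
  r <- refine_patch(p, target_edge = 1.9)
  expect_equal(nrow(r$triangles), 3L)
  expect_equal(nrow(r$vertices), 4L)
  expect_equal(r$vertices[4L, ], colMeans(tri), tolerance = 1e-12)

  # already dense: unchanged
  r2 <- refine_patch(p, target_edge = 10)
  expect_equal(nrow(r2$triangles), 1L)

  sw <- sphere_with_cap_hole(3, 0.85)
  pm <- triangulate_boundary(sw$loop, mesh = sw$mesh)
  pr <- refine_patch(pm, mesh = sw$mesh)
  surround <- toothcarve:::surround_edge_length(sw$mesh, sw$loop)
  e <- rbind(pr$triangles[, 1:2], pr$triangles[, 2:3], pr$triangles[, c(3L, 1L)])
  mean_edge <- mean(sqrt(rowSums((pr$vertices[e[, 1L], ] - pr$vertices[e[, 2L], ])^2)))
  expect_lt(mean_edge, 1.5 * surround)
  expect_gt(mean_edge, surround / 1.5)
})

test_that("k-harmonic reshaping: membrane flatness, linear precision, thin-plate sphere", {
  g <- make_grid_mesh(15, 15)
  ctr <- 8L * 15L + 8L
  ch <- cut_hole(g, bfs_ring(g, ctr, 2L))
  m <- ch$mesh; loop <- ch$loops[[1L]]
  p <- refine_patch(triangulate_boundary(loop, mesh = m), mesh = m)
  pd <- reshape_patch(m, p, k = 1L)
  expect_lt(max(abs(pd$vertices[, 3L])), 1e-8)

  L <- toothcarve:::cot_laplacian_matrix(g$vertices, g$triangles)
  interior <- setdiff(seq_len(225L), unique(as.vector(g$edges[g$edge_count == 1L, ])))
  expect_lt(max(abs(as.matrix(L %*% g$vertices)[interior, ])), 1e-9)

  sw <- sphere_with_cap_hole(3, 0.85)
  pr <- refine_patch(triangulate_boundary(sw$loop, mesh = sw$mesh), mesh = sw$mesh)
  pd2 <- reshape_patch(sw$mesh, pr, k = 2L)
  int <- pd2$vertices[!pd2$boundary, , drop = FALSE]
  rms <- sqrt(mean((sqrt(rowSums(int^2)) - 1)^2))
  expect_lt(rms, 0.02)

  # reshaping reduces the discrete thin-plate energy (area-weighted squared
  # Laplacian, weights frozen at the refined geometry) relative to P^refine
  gl_r <- toothcarve:::glue_patches(sw$mesh, list(pr))
  gl_d <- toothcarve:::glue_patches(sw$mesh, list(pd2))
  Ls <- toothcarve:::cot_laplacian_matrix(gl_r$vertices, gl_r$triangles)
  areas <- ring_area_of(gl_r$vertices, gl_r$triangles)
  energy <- function(V) {
    lap <- as.matrix(Ls %*% V)
    sum(areas * rowSums(lap^2))
  }
  expect_lt(energy(gl_d$vertices), energy(gl_r$vertices))

  expect_error(reshape_patch(sw$mesh, pr, k = 5L), "1, 2 or 3")

  # boundary vertices stay exactly on the original loop positions
  expect_equal(pd2$vertices[pd2$boundary, ],
               sw$mesh$vertices[pd2$host_ids, ], tolerance = 1e-12)
})

test_that("blend endpoints and midpoint follow the affine rule", {
  sw <- sphere_with_cap_hole(2, 0.8)
  pr <- refine_patch(triangulate_boundary(sw$loop, mesh = sw$mesh), mesh = sw$mesh)
  pd <- reshape_patch(sw$mesh, pr, k = 2L)
  expect_identical(blend_patch(pr, pd, 1)$vertices, pd$vertices)
  expect_lt(max(abs(blend_patch(pr, pd, 1e-12)$vertices - pr$vertices)), 1e-9)
  mid <- blend_patch(pr, pd, 0.5)$vertices
  expect_equal(mid, (pr$vertices + pd$vertices) / 2, tolerance = 1e-12)
  expect_error(blend_patch(pr, pd, 0), "lambda")
  expect_error(blend_patch(pr, pd, 1.2), "lambda")
})

# Independent clipping oracle for triangle intersection: every edge of one
# triangle tested against the other's plane and barycentric interior, plus
# the symmetric case; written from the definitions, no shared code paths.
oracle_tri_tri <- function(A, B) {
  edge_hits <- function(S, Tt) {
    n <- c(Tt[2, 2] * Tt[3, 3] - Tt[2, 3] * Tt[3, 2], 0, 0)  # placeholder
    u <- Tt[2, ] - Tt[1, ]; v <- Tt[3, ] - Tt[1, ]
    n <- c(u[2] * v[3] - u[3] * v[2], u[3] * v[1] - u[1] * v[3],
           u[1] * v[2] - u[2] * v[1])
    for (k in 1:3) {
      a <- S[k, ]; b <- S[if (k == 3) 1 else k + 1, ]
      da <- sum((a - Tt[1, ]) * n); db <- sum((b - Tt[1, ]) * n)
      if (da * db > 0) next
      if (da == db) next
      t <- da / (da - db)
      x <- a + t * (b - a)
      w <- x - Tt[1, ]
      uu <- sum(u * u); vv <- sum(v * v); uv <- sum(u * v)
      wu <- sum(w * u); wv <- sum(w * v)
      den <- uv^2 - uu * vv
      s1 <- (uv * wv - vv * wu) / den
      t1 <- (uv * wu - uu * wv) / den
      if (s1 >= -1e-12 && t1 >= -1e-12 && s1 + t1 <= 1 + 1e-12) return(TRUE)
    }
    FALSE
  }
  edge_hits(A, B) || edge_hits(B, A)
}

test_that("triangle interference test matches the clipping oracle", {
  A <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0))
  Bfar <- A; Bfar[, 3L] <- 1
  expect_false(toothcarve:::tri_tri_intersect(A, Bfar))
  Bperp <- rbind(c(0.2, 0.2, -0.5), c(0.3, 0.2, 0.5), c(0.25, 0.4, 0.2))
  expect_true(toothcarve:::tri_tri_intersect(A, Bperp))

  set.seed(21)
  n_agree <- 0L
  for (rep_i in 1:300) {
    A <- matrix(stats::runif(9, -1, 1), 3L, 3L)
    B <- matrix(stats::runif(9, -1, 1), 3L, 3L)
    got <- toothcarve:::tri_tri_intersect(A, B)
    want <- oracle_tri_tri(A, B)
    expect_equal(got, want)
    n_agree <- n_agree + as.integer(got == want)
  }
  expect_equal(n_agree, 300L)
})

test_that("patches_intersect prefilters by box and excludes shared-vertex pairs", {
  A <- list(vertices = rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0)),
            triangles = matrix(c(1L, 2L, 3L), 1L))
  B <- list(vertices = rbind(c(0, 0, 0), c(-1, 0, 0.5), c(0, -1, -0.5)),
            triangles = matrix(c(1L, 2L, 3L), 1L))
  # shares vertex (0,0,0): excluded
  expect_false(patches_intersect(A, B)$intersects)
  Bi <- list(vertices = rbind(c(0.2, 0.2, -0.5), c(0.3, 0.2, 0.5), c(0.25, 0.4, 0.2)),
             triangles = matrix(c(1L, 2L, 3L), 1L))
  out <- patches_intersect(A, Bi)
  expect_true(out$intersects)
  expect_equal(out$witness, c(1L, 1L))
})

test_that("restore_hole on a spherical cap: watertight, lambda stays 1", {
  sw <- sphere_with_cap_hole(3, 0.85)
  plane <- structure(list(normal = c(1, 0, 0), offset = 0, points = NULL,
                          residual = 0), class = "tc_plane")
  res <- restore_hole(sw$mesh, sw$loop, plane, k = 2L)
  expect_equal(res$lambda, 1.0)
  expect_length(boundary_loops(res$mesh), 0L)
  expect_equal(euler_characteristic(res$mesh), 2L)
  # subpatch boundary vertices coincide with the original subloop positions
  for (i in 1:2) {
    p <- res$patches[[i]]
    expect_equal(p$vertices[p$boundary, ],
                 sw$mesh$vertices[p$host_ids, ], tolerance = 1e-12)
  }
})

test_that("restore_hole on the two-cusp phantom saddle: watertight, lambda in [0.8, 1]", {
  ph <- make_dental_phantom(n_cusps = 2L, fused_pairs = list(c(1L, 2L)))
  m <- ph$mesh
  chi0 <- euler_characteristic(m)
  ch <- cut_hole(m, ph$fusion_regions[[1L]])
  expect_length(ch$loops, 1L)
  tippos <- m$vertices[vapply(ph$cusp_centers, function(cx)
    which.max(ifelse((m$vertices[, 1L] - cx)^2 + m$vertices[, 2L]^2 < 4,
                     m$vertices[, 3L], -Inf)), 0L), ]
  occ <- rbind(tippos[1L, ] + c(0, 0.5, 0), tippos[1L, ] - c(0, 0.5, 0),
               tippos[2L, ] + c(0, 0.5, 0), tippos[2L, ] - c(0, 0.5, 0))
  plane <- fit_occlusal_plane(occ, toward = c(0, 0, 100))
  res <- restore_hole(ch$mesh, ch$loops[[1L]], plane, k = 2L)
  expect_true(res$lambda >= 0.8 && res$lambda <= 1.0)
  expect_length(boundary_loops(res$mesh), 0L)
  expect_equal(euler_characteristic(res$mesh), chi0)
  expect_false(patches_intersect(res$patches[[1L]], res$patches[[2L]])$intersects)
  expect_error(restore_hole(ch$mesh, ch$loops[[1L]], plane, tau = 0.02), "tau")
})

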