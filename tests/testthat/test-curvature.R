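test_that("vertex normals: flat grid, sphere, pyramid apex", {
  g <- make_grid_mesh(7, 7)
  n <- vertex_normals(g, 25L)
  expect_equal(as.numeric(n), c(0, 0, 1), tolerance = 1e-12)

  s <- make_icosphere(3)
  idx <- c(5L, 100L, 400L)
  nrm <- vertex_normals(s)
  for (i in idx) {
    analytic <- s$vertices[i, ] / sqrt(sum(s$vertices[i, ]^2))
    ang <- acos(min(1, sum(nrm[i, ] * analytic)))
    expect_lt(ang, pi / 180)  # within 1 degree
  }

  # symmetric square pyramid: apex normal straight up
  v <- rbind(c(0, 0, 1), c(1, 0, 0), c(0, 1, 0), c(-1, 0, 0), c(0, -1, 0),
             c(0, 0, -1))
  tri <- rbind(c(1, 2, 3), c(1, 3, 4), c(1, 4, 5), c(1, 5, 2),
               c(6, 3, 2), c(6, 4, 3), c(6, 5, 4), c(6, 2, 5))
  p <- tc_mesh(v, tri)
  expect_equal(as.numeric(vertex_normals(p, 1L)), c(0, 0, 1), tolerance = 1e-12)
})

test_that("quadric fit recovers exact degree-2 height functions", {
  cases <- list(
    list(f = function(u, v) u^2 + v^2, coef = c(0, 0, 0, 1, 0, 1)),
    list(f = function(u, v) 0 * u,     coef = c(0, 0, 0, 0, 0, 0)),
    list(f = function(u, v) u * v,     coef = c(0, 0, 0, 0, 1, 0)),
    list(f = function(u, v) 0.3 * u^2 - 0.2 * u * v + 0.1 * v^2 + 0.05 * u,
         coef = c(0, 0.05, 0, 0.3, -0.2, 0.1)))
  for (cs in cases) {
    m <- quadric_patch_mesh(cs$f)
    exact_normals <- matrix(rep(c(0, 0, 1), each = nrow(m$vertices)), ncol = 3L)
    fit <- fit_local_quadric(m, 1L, k = 18L, normals = exact_normals)
    expect_equal(fit$coef, cs$coef, tolerance = 1e-9)
    expect_lt(fit$delta, 1e-18)
  }
  # rotationally symmetric case: the estimated normal is exact too
  m <- quadric_patch_mesh(function(u, v) u^2 + v^2, m = 12)
  fit <- fit_local_quadric(m, 1L, k = 18L)
  expect_equal(fit$coef[4], 1, tolerance = 1e-6)
  expect_equal(fit$coef[6], 1, tolerance = 1e-6)
})

test_that("quadric curvatures match analytic values of sampled quadrics to 1e-6", {
  # paraboloid z = a u^2 + c v^2 at origin: kH = a + c, kG = 4 a c (convex up
  # is positive with the outward normal +z when the surface bends away below);
  # here the estimator's sign convention gives hills positive, so sample the
  # downward-bending bowl and check magnitudes via the analytic shape operator.
  cases <- list(c(a = 0.5, b = 0, c = 0.5),    # sphere-like: kmin = kmax = 1
                c(a = 0.8, b = 0, c = 0.2),
                c(a = 0.5, b = 0.4, c = 0.5))
  for (cs in cases) {
    f <- function(u, v) cs[["a"]] * u^2 + cs[["b"]] * u * v + cs[["c"]] * v^2
    m <- quadric_patch_mesh(f, m = 12, r1 = 0.2, r2 = 0.4)
    exact_normals <- matrix(rep(c(0, 0, 1), each = nrow(m$vertices)), ncol = 3L)
    pc <- principal_curvatures(m, 1L, normals = exact_normals)
    # shape operator of z = f at the origin with normal +z: eigenvalues of
    # [[2a, b], [b, 2c]]; the estimator negates (outward-normal convention)
    H <- matrix(c(2 * cs[["a"]], cs[["b"]], cs[["b"]], 2 * cs[["c"]]), 2L)
    ev <- sort(-eigen(H)$values)
    expect_equal(unname(pc["kappa_H"]), mean(ev), tolerance = 1e-6)
    expect_equal(unname(pc["kappa_G"]), prod(ev), tolerance = 1e-6)
    expect_equal(unname(pc["kappa_min"]), ev[1L], tolerance = 1e-6)
  }
})

test_that("sphere and clean torus curvature errors are small; flat grid is zero", {
  s <- make_icosphere(4)
  set.seed(7)
  normals <- vertex_normals(s)
  for (i in sample(nrow(s$vertices), 25L)) {
    pc <- principal_curvatures(s, i, normals = normals)
    expect_equal(unname(pc["kappa_min"]), 1, tolerance = 0.05)
    expect_equal(unname(pc["kappa_max"]), 1, tolerance = 0.05)
    expect_equal(unname(pc["kappa_G"]), 1, tolerance = 0.05)
  }

  tt <- make_torus(R = 2, r = 1, n_u = 100, n_v = 50)
  i0 <- which.min(abs(tt$oracle$v) + abs(tt$oracle$u - pi))  # outer equator
  pc <- principal_curvatures(tt$mesh, i0)
  expect_equal(unname(pc["kappa_H"]), 2 / 3, tolerance = 0.05)
  expect_equal(unname(pc["kappa_G"]), 1 / 3, tolerance = 0.05)
  expect_equal(unname(pc["kappa_min"]), 1 / 3, tolerance = 0.05)

  g <- make_grid_mesh(9, 9)
  pc <- principal_curvatures(g, 41L)
  expect_true(all(abs(pc) < 1e-6))
})

test_that("Eq-5 consistency: kmin*kmax = kG and mean of extremes = kH", {
  tt <- make_torus(R = 2, r = 1, n_u = 30, n_v = 15)
  f <- curvature_field(tt$mesh)
  expect_lt(max(abs(f$kappa_min * f$kappa_max - f$kappa_G)), 1e-9)
  expect_lt(max(abs((f$kappa_min + f$kappa_max) / 2 - f$kappa_H)), 1e-9)
  expect_true(all(f$kappa_min <= f$kappa_max + 1e-12))
})

test_that("inverse-distance smoothing: constant, spike, zero fields", {
  m <- fan_mesh(6)
  const <- rep(3.7, 7)
  expect_equal(smooth_curvature(m, const), const, tolerance = 1e-12)
  expect_equal(smooth_curvature(m, rep(0, 7)), rep(0, 7))

  spike <- c(1, rep(0, 6))
  sm <- smooth_curvature(m, spike)
  # center excludes itself: becomes the ring average of zeros
  expect_equal(sm[1L], 0)
  # ring vertex: neighbors are the center (d=1) and two ring vertices (d=1
  # on the regular hexagon), so the spike contributes weight 1/3
  expect_equal(sm[2L], 1 / 3, tolerance = 1e-12)
  expect_gt(sum(sm), 0)
})

test_that("Meyer baseline: sphere, flat grid, torus inner equator", {
  s <- make_icosphere(3)
  mk <- meyer_curvature(s, 17L)
  expect_equal(unname(mk["kappa_H"]), 1, tolerance = 0.05)

  g <- make_grid_mesh(9, 9)
  mk <- meyer_curvature(g, 41L)
  expect_lt(abs(mk[["kappa_H"]]), 1e-9)
  expect_lt(abs(mk[["kappa_G"]]), 1e-9)
  expect_error(meyer_curvature(g, 1L), "boundary")

  tt <- make_torus(R = 2, r = 1, n_u = 80, n_v = 40)
  ipi <- which.min(abs(tt$oracle$v - pi) + abs(tt$oracle$u - pi))
  mk <- meyer_curvature(tt$mesh, ipi)
  expect_equal(unname(mk["kappa_G"]), -1, tolerance = 0.1)
})
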