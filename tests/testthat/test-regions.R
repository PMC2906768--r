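# Brute-force evaluation of the morphology definitions, used as oracle.
bf_dilate <- function(mesh, members, n) {
  sort(unique(unlist(lapply(members, function(j) bfs_ring(mesh, j, n)))))
}
bf_erode <- function(mesh, members, n) {
  all_v <- seq_len(nrow(mesh$vertices))
  keep <- vapply(all_v, function(k) all(bfs_ring(mesh, k, n) %in% members), TRUE)
  all_v[keep]
}

test_that("thresholding selects the analytic negative-curvature side of the torus", {
  tt <- make_torus(R = 2, r = 1, n_u = 40, n_v = 20)
  f <- curvature_field(tt$mesh)
  reg <- threshold_region(tt$mesh, f, t = 0)
  sel <- reg$members
  expect_gt(length(sel), 0)
  # exclude the tolerance band around the parabolic circles
  sel <- sel[abs(tt$oracle$kappa_G[sel]) >= 0.05]
  expect_true(all(tt$oracle$kappa_G[sel] < 0))

  g <- make_grid_mesh(6, 6)
  fg <- curvature_field(g)
  expect_length(threshold_region(g, fg, t = -0.1)$members, 0L)
  expect_length(threshold_region(g, fg, t = Inf)$members, 36L)
})

test_that("small components are removed by strict size comparison", {
  m <- make_grid_mesh(12, 12)
  blob <- bfs_ring(m, 66L, 3L)  # 37-vertex hex disk, away from the corner
  blob3 <- c(1L, 2L, 13L)
  stopifnot(length(intersect(blob, blob3)) == 0)
  reg <- vertex_region(m, c(blob, blob3))
  out <- remove_small_components(reg, 10L)
  expect_setequal(out$members, blob)
  expect_equal(remove_small_components(reg, 1L)$members, reg$members)

  sizes <- vapply(region_components(reg), length, 0L)
  expect_setequal(sizes, c(length(blob), 3L))
  # strict less-than: a size-10 component survives min_vertices = 10
  reg10 <- vertex_region(m, bfs_ring(m, 78L, 2L)[1:10])
  expect_length(remove_small_components(reg10, 10L)$members, 10L)
  expect_length(remove_small_components(reg10, 11L)$members, 0L)
})

test_that("dilate and erode match the set definitions", {
  m <- make_grid_mesh(8, 8)
  i <- 28L
  d1 <- region_dilate(vertex_region(m, i), 1L)
  expect_equal(d1$members, bfs_ring(m, i, 1L))  # closed 1-ring incl. center

  all_reg <- vertex_region(m, seq_len(64L))
  expect_equal(region_erode(all_reg, 2L)$members, bf_erode(m, 1:64, 2L))

  # singleton with any outside neighbor erodes to empty
  expect_length(region_erode(vertex_region(m, i), 1L)$members, 0L)
})

test_that("opening removes spurs, closing fills pinholes", {
  m <- make_grid_mesh(10, 10)
  blob <- bfs_ring(m, 45L, 2L)
  spur <- c(48L, 49L)  # thin 1-wide tail attached to the blob
  reg <- vertex_region(m, union(blob, spur))
  opened <- region_open(reg, 1L)
  expect_false(any(spur[2L] %in% opened$members))
  expect_true(45L %in% opened$members)

  ring3 <- bfs_ring(m, 45L, 3L)
  pin <- vertex_region(m, setdiff(ring3, 45L))  # pinhole at the center
  closed <- region_close(pin, 1L)
  expect_true(45L %in% closed$members)
})

test_that("morphology laws hold on random regions (phantom mesh)", {
  tt <- make_torus(R = 2, r = 1, n_u = 50, n_v = 25)  # 1250 vertices
  m <- tt$mesh
  nv <- nrow(m$vertices)
  set.seed(42)
  for (rep_i in 1:100) {
    seeds <- sample(nv, sample(1:4, 1L))
    members <- unique(unlist(lapply(seeds, function(s)
      bfs_ring(m, s, sample(1:3, 1L)))))
    if (stats::runif(1) < 0.3) members <- sample(nv, sample(10:120, 1L))
    reg <- vertex_region(m, members)
    er <- region_erode(reg, 1L)
    di <- region_dilate(reg, 1L)
    op <- region_open(reg, 1L)
    cl <- region_close(reg, 1L)
    # extensivity / anti-extensivity
    expect_true(all(er$members %in% members))
    expect_true(all(members %in% di$members))
    expect_true(all(op$members %in% members))
    expect_true(all(members %in% cl$members))
    # idempotence
    expect_equal(region_open(op, 1L)$members, op$members)
    expect_equal(region_close(cl, 1L)$members, cl$members)
  }
})

test_that("monotonicity and brute-force equivalence on a small mesh", {
  m <- make_grid_mesh(10, 10)  # 100 vertices
  set.seed(11)
  for (rep_i in 1:20) {
    A <- sample(100L, 25L)
    B <- union(A, sample(100L, 15L))
    for (op in list(region_dilate, region_erode, region_open, region_close)) {
      outA <- op(vertex_region(m, A), 1L)$members
      outB <- op(vertex_region(m, B), 1L)$members
      expect_true(all(outA %in% outB))
    }
    n <- sample(1:2, 1L)
    expect_equal(region_dilate(vertex_region(m, A), n)$members,
                 bf_dilate(m, A, n))
    expect_equal(region_erode(vertex_region(m, A), n)$members,
                 bf_erode(m, A, n))
  }
})
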