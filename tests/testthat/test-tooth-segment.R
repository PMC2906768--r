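# annulus band fixture: rows lo..hi of a grid cylinder (vertex (iu, iv) has
# index (iu-1)*n_v + iv)
cyl_band <- function(mesh, n_u, n_v, lo, hi) {
  idx <- as.vector(outer((seq_len(n_u) - 1L) * n_v, lo:hi, `+`))
  sort(idx)
}

test_that("vertex complexity counts membership runs around the ordered ring", {
  m <- make_grid_mesh(7, 7)
  center <- 25L  # interior, valence 6
  ring <- toothcarve:::ordered_one_ring(m, center)
  expect_length(ring, 6L)

  # all neighbors members: CP = 0, center vertex
  reg_all <- vertex_region(m, c(center, ring))
  expect_equal(vertex_complexity(reg_all, center), 0L)
  cls <- classify_region(reg_all)
  expect_true(center %in% cls$centers)

  # alternating membership 1,0,1,0,1,0 -> CP = 6 (complex)
  reg_alt <- vertex_region(m, c(center, ring[c(1L, 3L, 5L)]))
  expect_equal(vertex_complexity(reg_alt, center), 6L)
  expect_true(center %in% classify_region(reg_alt)$complex)

  # one contiguous arc 1,1,1,0,0,0 -> CP = 2
  reg_arc <- vertex_region(m, c(center, ring[1:3]))
  expect_equal(vertex_complexity(reg_arc, center), 2L)

  expect_error(vertex_complexity(reg_arc, ring[5L]), "not in the region")
})

test_that("classification on a solid hex disk follows the candidate rule", {
  m <- make_grid_mesh(11, 11)
  disk <- bfs_ring(m, 61L, 3L)   # 37-vertex hex disk
  reg <- vertex_region(m, disk)
  cls <- classify_region(reg)
  expect_setequal(cls$centers, bfs_ring(m, 61L, 2L))  # full-1-ring members
  # satellites = member neighbors of centers (here: the whole disk)
  expect_true(all(cls$candidates %in% setdiff(disk, bfs_ring(m, 61L, 2L))))
  # the invariant F_D = F_S minus (complex union centers)
  expect_setequal(cls$candidates,
                  setdiff(cls$satellites, union(cls$complex, cls$centers)))
  expect_length(classify_region(vertex_region(m, integer(0)))$candidates, 0L)
})

test_that("a width-one taut ring is a peeling fixpoint with no candidates", {
  m <- make_cylinder_mesh(30L, 7L)
  ring <- cyl_band(m, 30L, 7L, 4L, 4L)
  reg <- vertex_region(m, ring)
  cls <- classify_region(reg)
  expect_length(cls$centers, 0L)
  expect_length(cls$candidates, 0L)
  sk <- skeletonize(reg)
  expect_setequal(sk$members, ring)
})

test_that("an annulus band peels to a single closed ring with the band's winding", {
  n_u <- 36L; n_v <- 9L
  m <- make_cylinder_mesh(n_u, n_v)
  band <- cyl_band(m, n_u, n_v, 3L, 6L)  # 4 rows wide
  reg <- vertex_region(m, band)
  b_before <- region_betti(m, band)
  expect_equal(unname(b_before), c(1L, 1L))

  sk <- skeletonize(reg)
  b_after <- region_betti(m, sk$members)
  expect_equal(unname(b_after), c(1L, 1L))   # topology preserved

  pr <- prune_skeleton(sk, min_ring = 8L)
  expect_length(pr$rings, 1L)
  deg <- toothcarve:::skeleton_degrees(m, pr$members)
  expect_true(all(deg == 2L))                 # 2-regular
  # winding: the ordered ring advances once around the cylinder axis
  cyc <- pr$rings[[1L]]
  th <- atan2(m$vertices[cyc, 2L], m$vertices[cyc, 1L])
  dth <- diff(c(th, th[1L]))
  dth <- ifelse(dth > pi, dth - 2 * pi, ifelse(dth < -pi, dth + 2 * pi, dth))
  expect_equal(abs(sum(dth)), 2 * pi, tolerance = 1e-9)
})

test_that("solid disk peels to a small residual with no candidates", {
  m <- make_grid_mesh(12, 12)
  disk <- bfs_ring(m, 66L, 3L)
  sk <- skeletonize(vertex_region(m, disk))
  expect_lt(length(sk$members), 10L)  # small residual cluster
  reg_after <- vertex_region(m, sk$members)
  expect_length(classify_region(reg_after)$candidates, 0L)
  b <- region_betti(m, sk$members)
  expect_equal(unname(b), c(1L, 0L))          # still one piece, no loop
})

test_that("peeling strictly shrinks and preserves component count on random regions", {
  m <- make_cylinder_mesh(24L, 8L)
  set.seed(13)
  for (rep_i in 1:10) {
    seeds <- sample(nrow(m$vertices), 3L)
    members <- unique(unlist(lapply(seeds, function(s) bfs_ring(m, s, 2L))))
    reg <- vertex_region(m, members)
    sk <- skeletonize(reg)
    expect_lte(length(sk$members), length(members))
    b0_before <- region_betti(m, members)["b0"]
    b_after <- region_betti(m, sk$members)
    expect_equal(b_after[["b0"]], b0_before[["b0"]])
    expect_equal(b_after[["b1"]], region_betti(m, members)[["b1"]])
  }
})

test_that("pruning removes branches and small rings", {
  n_u <- 36L; n_v <- 9L
  m <- make_cylinder_mesh(n_u, n_v)
  ring <- cyl_band(m, n_u, n_v, 4L, 4L)
  idx <- function(iu, iv) (iu - 1L) * n_v + iv
  tail_vs <- c(idx(5L, 5L), idx(5L, 6L), idx(5L, 7L))  # open tail off the ring
  sk <- structure(list(mesh = m, members = sort(c(ring, tail_vs)),
                       input_size = length(ring) + 3L), class = "tc_skeleton")
  pr <- prune_skeleton(sk, min_ring = 8L)
  expect_setequal(pr$members, ring)

  # a pure open path vanishes entirely
  path_sk <- structure(list(mesh = m, members = idx(10:20, 3L),
                            input_size = 11L), class = "tc_skeleton")
  expect_length(prune_skeleton(path_sk)$members, 0L)

  # small ring dropped by min_ring: hexagon rim around a grid vertex
  g <- make_grid_mesh(9, 9)
  hexrim <- setdiff(bfs_ring(g, 41L, 1L), 41L)
  both <- structure(list(mesh = g, members = hexrim, input_size = 6L),
                    class = "tc_skeleton")
  expect_length(prune_skeleton(both, min_ring = 10L)$members, 0L)
  expect_length(prune_skeleton(both, min_ring = 6L)$rings, 1L)
})

test_that("separation cuts the surface along the rings", {
  n_u <- 30L; n_v <- 9L
  m <- make_cylinder_mesh(n_u, n_v)
  ring <- cyl_band(m, n_u, n_v, 5L, 5L)
  sk <- structure(list(mesh = m, members = ring, input_size = length(ring),
                       rings = list(ring)), class = "tc_skeleton")
  sep <- separate_teeth(m, sk)
  expect_length(sep$teeth, 1L)
  # the cut duplicates ring vertices into both sides
  tooth <- sep$teeth[[1L]]
  tooth_loops <- boundary_loops(tooth)
  expect_true(any(vapply(tooth_loops, length, 0L) == length(ring)))

  # no rings: identity
  sep0 <- separate_teeth(m, structure(list(mesh = m, members = integer(0),
                                           input_size = 0L, rings = list()),
                                      class = "tc_skeleton"))
  expect_length(sep0$teeth, 0L)
  expect_equal(nrow(sep0$base$vertices), nrow(m$vertices))

  # a non-separating cycle (torus meridian) raises an error
  tt <- make_torus(2, 1, 24L, 12L)
  meridian <- ((1L:12L))  # iu = 1 column: indices 1..12
  skm <- structure(list(mesh = tt$mesh, members = meridian,
                        input_size = 12L, rings = list(meridian)),
                   class = "tc_skeleton")
  expect_error(separate_teeth(tt$mesh, skm), "separate")
})
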