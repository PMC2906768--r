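#' Analytic torus mesh with curvature oracle
#'
#' Samples the torus (x, y, z) = ((R + r cos v) cos u, (R + r cos v) sin u,
#' r sin v) on an n_u x n_v parameter grid and splits the quads into
#' triangles. The closed-form principal curvatures of the torus, 1/r and
#' cos v / (R + r cos v) (convex positive, outward normal), are returned per
#' vertex as an oracle for the curvature estimators.
#'
#' @param R wheel radius (> r).
#' @param r tube radius (> 0).
#' @param n_u,n_v sampling counts (>= 3).
#' @return list with \code{mesh} (a watertight genus-1 \code{tc_mesh}) and
#'   \code{oracle}: data.frame of per-vertex u, v, kappa_H, kappa_G,
#'   kappa_min, kappa_max.
#' @export
make_torus <- function(R = 2, r = 1, n_u = 60L, n_v = 30L) {
  stopifnot(R > r, r > 0, n_u >= 3L, n_v >= 3L)
  u <- rep(2 * pi * (seq_len(n_u) - 1L) / n_u, each = n_v)
  v <- rep(2 * pi * (seq_len(n_v) - 1L) / n_v, times = n_u)
  verts <- cbind((R + r * cos(v)) * cos(u),
                 (R + r * cos(v)) * sin(u),
                 r * sin(v))
  idx <- function(iu, iv) ((iu - 1L) %% n_u) * n_v + ((iv - 1L) %% n_v) + 1L
  iu <- rep(seq_len(n_u), each = n_v)
  iv <- rep(seq_len(n_v), times = n_u)
  a <- idx(iu, iv); b <- idx(iu + 1L, iv)
  cc <- idx(iu + 1L, iv + 1L); d <- idx(iu, iv + 1L)
  # Outward orientation: (a, b, c) and (a, c, d).
  tri <- rbind(cbind(a, b, cc), cbind(a, cc, d))
  mesh <- tc_mesh(verts, tri)
  k1 <- rep(1 / r, length(v))
  k2 <- cos(v) / (R + r * cos(v))
  oracle <- data.frame(u = u, v = v,
                       kappa_min = pmin(k1, k2), kappa_max = pmax(k1, k2),
                       kappa_H = (k1 + k2) / 2, kappa_G = k1 * k2)
  list(mesh = mesh, oracle = oracle)
}

#' Add Gaussian vertex noise along the normals
#'
#' Each vertex is displaced along its vertex normal by a zero-mean Gaussian
#' with standard deviation \code{h} times the mean edge length. Along-normal
#' displacement is used because tangential noise is invisible to curvature at
#' first order; \code{h} is thereby a resolution-relative noise level.
#'
#' @param mesh a \code{tc_mesh}.
#' @param h noise level (>= 0), in units of mean edge length.
#' @param seed RNG seed for reproducibility.
#' @return a \code{tc_mesh} with displaced vertices (same connectivity).
#' @export
add_noise <- function(mesh, h, seed = 1L) {
  stopifnot(h >= 0)
  if (h == 0) return(mesh)
  nrm <- vertex_normals(mesh)
  scale <- h * mesh_mean_edge_length(mesh)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  set.seed(seed)
  d <- stats::rnorm(nrow(mesh$vertices), sd = scale)
  if (!is.null(old)) assign(".Random.seed", old, globalenv())
  v <- mesh$vertices + d * nrm
  m2 <- mesh
  m2$vertices <- v
  m2
}

#' Flat grid mesh
#'
#' Rectangular z = 0 grid with unit-square cells split along one diagonal, so
#' interior vertices have valence 6 (hexagonal-like connectivity).
#'
#' @param nx,ny vertex counts along x and y.
#' @param dx grid spacing.
#' @param z optional height function f(x, y) evaluated at the grid nodes.
#' @return a \code{tc_mesh}; vertex (ix, iy) has index (iy-1)*nx + ix.
#' @export
make_grid_mesh <- function(nx, ny, dx = 1, z = NULL) {
  x <- rep((seq_len(nx) - 1L) * dx, times = ny)
  y <- rep((seq_len(ny) - 1L) * dx, each = nx)
  zz <- if (is.null(z)) numeric(length(x)) else z(x, y)
  idx <- function(ix, iy) (iy - 1L) * nx + ix
  ix <- rep(seq_len(nx - 1L), times = ny - 1L)
  iy <- rep(seq_len(ny - 1L), each = nx - 1L)
  a <- idx(ix, iy); b <- idx(ix + 1L, iy)
  cc <- idx(ix + 1L, iy + 1L); d <- idx(ix, iy + 1L)
  tri <- rbind(cbind(a, b, cc), cbind(a, cc, d))
  tc_mesh(cbind(x, y, zz), tri)
}

#' Cylinder grid mesh (open tube)
#'
#' A grid wrapped around in u; useful as an annulus-band fixture for the
#' skeletonization tests (the band winds once around the axis).
#'
#' @param n_u circumferential vertex count.
#' @param n_v axial vertex count (rows).
#' @param radius cylinder radius.
#' @param height total axial height.
#' @return a \code{tc_mesh} with two boundary loops; vertex (iu, iv) has
#'   index (iu-1)*n_v + iv.
#' @export
make_cylinder_mesh <- function(n_u = 40L, n_v = 9L, radius = 3, height = 4) {
  u <- rep(2 * pi * (seq_len(n_u) - 1L) / n_u, each = n_v)
  zz <- rep(seq(0, height, length.out = n_v), times = n_u)
  verts <- cbind(radius * cos(u), radius * sin(u), zz)
  idx <- function(iu, iv) ((iu - 1L) %% n_u) * n_v + iv
  iu <- rep(seq_len(n_u), each = n_v - 1L)
  iv <- rep(seq_len(n_v - 1L), times = n_u)
  a <- idx(iu, iv); b <- idx(iu + 1L, iv)
  cc <- idx(iu + 1L, iv + 1L); d <- idx(iu, iv + 1L)
  tri <- rbind(cbind(a, b, cc), cbind(a, cc, d))
  tc_mesh(verts, tri)
}

#' Icosphere mesh
#'
#' Subdivided icosahedron projected to the sphere; near-uniform valence,
#' suitable for curvature benchmarks.
#'
#' @param subdivisions refinement level (0 = icosahedron, each level
#'   quadruples the face count).
#' @param radius sphere radius.
#' @return a watertight \code{tc_mesh}.
#' @export
make_icosphere <- function(subdivisions = 3L, radius = 1) {
  phi <- (1 + sqrt(5)) / 2
  v <- rbind(
    c(-1, phi, 0), c(1, phi, 0), c(-1, -phi, 0), c(1, -phi, 0),
    c(0, -1, phi), c(0, 1, phi), c(0, -1, -phi), c(0, 1, -phi),
    c(phi, 0, -1), c(phi, 0, 1), c(-phi, 0, -1), c(-phi, 0, 1))
  v <- v / rows_norm(v)
  f <- rbind(
    c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
    c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
    c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
    c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
  for (s in seq_len(subdivisions)) {
    mid_cache <- new.env(parent = emptyenv())
    midpoint <- function(i, j) {
      key <- paste(min(i, j), max(i, j))
      got <- mid_cache[[key]]
      if (!is.null(got)) return(got)
      p <- v[i, ] + v[j, ]
      p <- p / vec_norm(p)
      v <<- rbind(v, p)
      id <- nrow(v)
      mid_cache[[key]] <- id
      id
    }
    nf <- matrix(0L, nrow(f) * 4L, 3L)
    for (t in seq_len(nrow(f))) {
      a <- f[t, 1L]; b <- f[t, 2L]; cc <- f[t, 3L]
      ab <- midpoint(a, b); bc <- midpoint(b, cc); ca <- midpoint(cc, a)
      nf[(t - 1L) * 4L + 1:4, ] <- rbind(c(a, ab, ca), c(b, bc, ab),
                                         c(cc, ca, bc), c(ab, bc, ca))
    }
    f <- nf
  }
  tc_mesh(v * radius, f)
}

#' Procedural multi-cusp dental phantom
#'
#' Heightfield-over-base emulation of a scanned dental cast segment: a row of
#' cusp-like Gaussian bumps ("teeth") on a flat gingiva plane, each encircled
#' by an annular blending groove (the tooth / soft-tissue valley), with an
#' optional raised fusion ridge joining designated cusp pairs the way fused
#' adjacent teeth appear in scans. The heightfield is closed by vertical
#' walls and a flat bottom into a watertight mesh.
#'
#' Ground-truth labels are returned for testing: conservative per-cusp vertex
#' cores (inside 80 percent of the groove radius), per-adjacent-pair valley
#' floor sets, and per-fused-pair fusion bands (the region a user would select
#' and remove before restoration).
#'
#' @param n_cusps number of cusps in the row (>= 2).
#' @param fused_pairs list of integer pairs (adjacent cusp indices) joined by
#'   a fusion ridge; default none.
#' @param cusp_height cusp height in model units (mm), default 6.
#' @param cusp_sigma cusp Gaussian width, default 2.2.
#' @param groove_radius radius of the blending groove circle around each
#'   cusp, default 4.2.
#' @param groove_depth groove depth, default 1.2.
#' @param groove_sigma groove cross-section width, default 0.55.
#' @param ridge_height fusion ridge height over the base, default 2.2.
#' @param spacing center-to-center cusp distance, default 2.35 x groove
#'   radius (grooves stay disjoint).
#' @param resolution grid spacing, default 0.35.
#' @param base_depth depth of the flat bottom below the gingiva plane.
#' @param margin flat border width beyond the outer grooves.
#' @return list with \code{mesh}, \code{top_ids} (vertex ids of the
#'   heightfield part), \code{cusp_centers}, \code{cusp_cores} (list of vertex
#'   sets), \code{valley_sets} (list, one per adjacent pair), and
#'   \code{fusion_regions} (list, one per fused pair).
#' @export
make_dental_phantom <- function(n_cusps = 4L, fused_pairs = list(),
                                cusp_height = 6, cusp_sigma = 2.2,
                                groove_radius = 4.2, groove_depth = 1.2,
                                groove_sigma = 0.55, ridge_height = 2.2,
                                spacing = 2.35 * groove_radius,
                                resolution = 0.35, base_depth = 3,
                                margin = 2.5) {
  stopifnot(n_cusps >= 2L)
  centers_x <- (seq_len(n_cusps) - (n_cusps + 1) / 2) * spacing
  half_w <- (n_cusps - 1) / 2 * spacing + groove_radius + margin
  half_h <- groove_radius + margin
  nx <- as.integer(round(2 * half_w / resolution)) + 1L
  ny <- as.integer(round(2 * half_h / resolution)) + 1L

  fused <- vapply(fused_pairs, function(p) as.integer(min(p)), 0L)  # pair (i, i+1) keyed by i

  height_fun <- function(x, y) {
    z <- numeric(length(x))
    for (cx in centers_x) {
      r2 <- (x - cx)^2 + y^2
      z <- z + cusp_height * exp(-r2 / (2 * cusp_sigma^2))
    }
    for (i in fused) {
      cx1 <- centers_x[i]; cx2 <- centers_x[i + 1L]
      # ridge along the segment between the two cusp centers
      t <- pmin(1, pmax(0, (x - cx1) / (cx2 - cx1)))
      px <- cx1 + t * (cx2 - cx1)
      d2 <- (x - px)^2 + y^2
      bump <- ridge_height * exp(-d2 / (2 * (0.45 * cusp_sigma)^2))
      # smooth maximum: avoids a sharp crease where ridge meets cusp flank
      z <- 0.5 * (z + bump + sqrt((z - bump)^2 + 0.25))
    }
    for (cx in centers_x) {
      r <- sqrt((x - cx)^2 + y^2)
      z <- z - groove_depth * exp(-(r - groove_radius)^2 / (2 * groove_sigma^2))
    }
    z
  }

  xs <- seq(-half_w, half_w, length.out = nx)
  ys <- seq(-half_h, half_h, length.out = ny)
  x <- rep(xs, times = ny)
  y <- rep(ys, each = nx)
  z <- height_fun(x, y)

  idx <- function(ix, iy) (iy - 1L) * nx + ix
  ix <- rep(seq_len(nx - 1L), times = ny - 1L)
  iy <- rep(seq_len(ny - 1L), each = nx - 1L)
  a <- idx(ix, iy); b <- idx(ix + 1L, iy)
  cc <- idx(ix + 1L, iy + 1L); d <- idx(ix, iy + 1L)
  top_tri <- rbind(cbind(a, b, cc), cbind(a, cc, d))  # wound with +z outward

  verts <- cbind(x, y, z)
  n_top <- nrow(verts)

  # Rim (counter-clockwise seen from +z) and its copy at the bottom plane.
  rim <- c(idx(seq_len(nx), 1L),
           idx(nx, seq(2L, ny)),
           idx(seq(nx - 1L, 1L), ny),
           idx(1L, seq(ny - 1L, 2L)))
  nr <- length(rim)
  bot_rim_ids <- n_top + seq_len(nr)
  bverts <- cbind(verts[rim, 1L], verts[rim, 2L], -base_depth)
  center_id <- n_top + nr + 1L
  verts <- rbind(verts, bverts, c(0, 0, -base_depth))

  wall_tri <- NULL
  for (k in seq_len(nr)) {
    k2 <- if (k == nr) 1L else k + 1L
    t1 <- c(rim[k], bot_rim_ids[k], bot_rim_ids[k2])
    t2 <- c(rim[k], bot_rim_ids[k2], rim[k2])
    wall_tri <- rbind(wall_tri, t1, t2)
  }
  bot_tri <- cbind(center_id, bot_rim_ids[c(seq(2L, nr), 1L)], bot_rim_ids)

  mesh <- tc_mesh(verts, rbind(top_tri, wall_tri, bot_tri))

  # Ground truth (top vertices only; tc_mesh keeps vertex order).
  r_cusp <- lapply(centers_x, function(cx) sqrt((x - cx)^2 + y^2))
  cusp_cores <- lapply(r_cusp, function(r) which(r < 0.8 * groove_radius))
  # valley floor between adjacent cusps: for a fused pair, the crest line of
  # the saddle col; otherwise the merged groove trench arcs between the teeth
  valley_sets <- list()
  for (i in seq_len(n_cusps - 1L)) {
    midx <- (centers_x[i] + centers_x[i + 1L]) / 2
    gap <- spacing - 2 * groove_radius
    on_groove <- abs(r_cusp[[i]] - groove_radius) < 0.8 * groove_sigma |
      abs(r_cusp[[i + 1L]] - groove_radius) < 0.8 * groove_sigma
    ylim <- if (i %in% fused) 0.45 * cusp_sigma else 2 * cusp_sigma
    sel <- which((on_groove & abs(x - midx) < gap / 2 + 2 * groove_sigma &
                    abs(y) < 2 * cusp_sigma) |
                   (abs(x - midx) < pmax(gap / 2 - groove_sigma, 1.2 * resolution) &
                      abs(y) < ylim))
    valley_sets[[i]] <- sel
  }
  fusion_regions <- lapply(fused, function(i) {
    midx <- (centers_x[i] + centers_x[i + 1L]) / 2
    gap <- spacing - 2 * groove_radius
    which(abs(x - midx) < gap / 2 + groove_sigma &
            abs(y) < 2.4 * cusp_sigma)
  })

  list(mesh = mesh, top_ids = seq_len(n_top), cusp_centers = centers_x,
       cusp_cores = cusp_cores, valley_sets = valley_sets,
       fusion_regions = fusion_regions,
       groove_radius = groove_radius, resolution = resolution)
}

#' Cut a hole by deleting a vertex region's triangles
#'
#' Removes every triangle whose three vertices all lie in the region and
#' returns the resulting new boundary loops (the holes).
#'
#' @param mesh a \code{tc_mesh}.
#' @param region integer vertex index vector or a \code{tc_region}.
#' @return list with \code{mesh} (hole-bearing mesh; vertex indices
#'   preserved), \code{loops} (new boundary loops) and \code{removed}
#'   (deleted triangle ids of the input mesh).
#' @export
cut_hole <- function(mesh, region) {
  members <- region_members(region)
  if (length(members) == 0L) {
    return(list(mesh = mesh, loops = list(), removed = integer(0)))
  }
  inset <- logical(nrow(mesh$vertices))
  inset[members] <- TRUE
  tri <- mesh$triangles
  rm_tri <- which(inset[tri[, 1L]] & inset[tri[, 2L]] & inset[tri[, 3L]])
  if (length(rm_tri) == 0L) {
    return(list(mesh = mesh, loops = list(), removed = integer(0)))
  }
  old_loops <- boundary_loops(mesh)
  keep <- tri[-rm_tri, , drop = FALSE]
  # Keep vertex numbering: rebuild without dropping isolated vertices would
  # break tc_mesh's invariant, so track the index map.
  used <- sort(unique(as.vector(keep)))
  cut <- tc_mesh(mesh$vertices[used, , drop = FALSE],
                 matrix(match(keep, used), ncol = 3L))
  # components check
  comp <- subset_components(cut$adj, seq_len(nrow(cut$vertices)))
  if (max(comp) > 1L) stop("hole cutting disconnected the mesh")
  new_loops <- boundary_loops(cut)
  # Loops are reported in the cut mesh's own indexing; vertex_map maps cut
  # indices back to the input mesh. Pre-existing boundary loops are excluded.
  old_sets <- lapply(old_loops, sort)
  is_new <- vapply(new_loops, function(l) {
    s <- sort(used[l])
    !any(vapply(old_sets, function(o) identical(o, s), TRUE))
  }, TRUE)
  list(mesh = cut, loops = new_loops[is_new], removed = rm_tri,
       vertex_map = used)
}
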