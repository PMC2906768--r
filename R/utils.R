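# Small numeric helpers shared across modules.

vec_cross <- function(a, b) {
  c(a[2L] * b[3L] - a[3L] * b[2L],
    a[3L] * b[1L] - a[1L] * b[3L],
    a[1L] * b[2L] - a[2L] * b[1L])
}

vec_norm <- function(a) sqrt(sum(a * a))

vec_normalize <- function(a) {
  n <- vec_norm(a)
  if (n == 0) stop("cannot normalize a zero vector")
  a / n
}

# Row-wise cross products / norms for n x 3 matrices.
rows_cross <- function(a, b) {
  cbind(a[, 2L] * b[, 3L] - a[, 3L] * b[, 2L],
        a[, 3L] * b[, 1L] - a[, 1L] * b[, 3L],
        a[, 1L] * b[, 2L] - a[, 2L] * b[, 1L])
}

rows_norm <- function(a) sqrt(rowSums(a * a))

# Angle at corner p formed by rays to q and r, in [0, pi].
corner_angle <- function(p, q, r) {
  u <- q - p
  v <- r - p
  nu <- vec_norm(u)
  nv <- vec_norm(v)
  if (nu == 0 || nv == 0) return(0)
  cosang <- sum(u * v) / (nu * nv)
  acos(min(1, max(-1, cosang)))
}

cot <- function(x) cos(x) / sin(x)

# 2D segment intersection test with shared-endpoint exclusion; segments given
# as 2-vectors. Returns TRUE when the open interiors intersect or the segments
# overlap collinearly, at tolerance `tol` (absolute, caller scales it).
segments_cross_2d <- function(p1, p2, q1, q2, tol = 1e-12) {
  shared <- function(a, b) vec_norm2d(a - b) <= tol
  d1 <- p2 - p1
  d2 <- q2 - q1
  denom <- d1[1L] * d2[2L] - d1[2L] * d2[1L]
  r <- q1 - p1
  if (abs(denom) <= tol * (vec_norm2d(d1) * vec_norm2d(d2) + tol)) {
    # Parallel: crossing only when collinear and overlapping over more than a
    # point; the identical segment (a shared mesh edge) is not a crossing.
    identical_seg <- (shared(p1, q1) && shared(p2, q2)) ||
      (shared(p1, q2) && shared(p2, q1))
    if (identical_seg) return(FALSE)
    cr <- r[1L] * d1[2L] - r[2L] * d1[1L]
    if (abs(cr) > tol * (vec_norm2d(d1) + 1)) return(FALSE)
    l1 <- sum(d1 * d1)
    if (l1 == 0) return(FALSE)
    t1 <- sum((q1 - p1) * d1) / l1
    t2 <- sum((q2 - p1) * d1) / l1
    lo <- min(t1, t2); hi <- max(t1, t2)
    eps <- tol / sqrt(l1)
    return(min(hi, 1) - max(lo, 0) > eps)
  }
  # Shared endpoints do not count as crossings.
  if (shared(p1, q1) || shared(p1, q2) || shared(p2, q1) || shared(p2, q2)) {
    return(FALSE)
  }
  t <- (r[1L] * d2[2L] - r[2L] * d2[1L]) / denom
  u <- (r[1L] * d1[2L] - r[2L] * d1[1L]) / denom
  eps <- tol / (vec_norm2d(d1) + tol)
  epu <- tol / (vec_norm2d(d2) + tol)
  t > eps && t < 1 - eps && u > epu && u < 1 - epu
}

vec_norm2d <- function(a) sqrt(a[1L]^2 + a[2L]^2)

# Pairwise-vectorized version of segments_cross_2d: row i of (P1x, P1y, P2x,
# P2y) against row i of (Q1x, Q1y, Q2x, Q2y). Returns TRUE if any pair
# crosses under the same rules.
segs_cross_pairs <- function(p1x, p1y, p2x, p2y, q1x, q1y, q2x, q2y, tol) {
  d1x <- p2x - p1x; d1y <- p2y - p1y
  d2x <- q2x - q1x; d2y <- q2y - q1y
  rx <- q1x - p1x; ry <- q1y - p1y
  n1sq <- d1x * d1x + d1y * d1y
  n2sq <- d2x * d2x + d2y * d2y
  denom <- d1x * d2y - d1y * d2x
  par <- denom * denom <= tol * tol * (n1sq * n2sq + tol)
  tol2 <- tol * tol
  s11 <- (p1x - q1x)^2 + (p1y - q1y)^2 <= tol2
  s12 <- (p1x - q2x)^2 + (p1y - q2y)^2 <= tol2
  s21 <- (p2x - q1x)^2 + (p2y - q1y)^2 <= tol2
  s22 <- (p2x - q2x)^2 + (p2y - q2y)^2 <= tol2
  out <- logical(length(d1x))
  if (!all(par)) {
    tt <- (rx * d2y - ry * d2x) / denom
    uu <- (rx * d1y - ry * d1x) / denom
    eps <- tol / (sqrt(n1sq) + tol)
    epu <- tol / (sqrt(n2sq) + tol)
    sh <- s11 | s12 | s21 | s22
    out <- !par & !sh & tt > eps & tt < 1 - eps & uu > epu & uu < 1 - epu
    if (any(out)) return(TRUE)
  }
  if (any(par)) {
    pp <- which(par)
    ident <- (s11[pp] & s22[pp]) | (s12[pp] & s21[pp])
    cr <- rx[pp] * d1y[pp] - ry[pp] * d1x[pp]
    l1 <- n1sq[pp]
    coll <- abs(cr) <= tol * (sqrt(l1) + 1)
    t1 <- (rx[pp] * d1x[pp] + ry[pp] * d1y[pp]) / pmax(l1, 1e-300)
    t2 <- ((q2x[pp] - p1x[pp]) * d1x[pp] + (q2y[pp] - p1y[pp]) * d1y[pp]) /
      pmax(l1, 1e-300)
    lo <- pmin(t1, t2); hi <- pmax(t1, t2)
    eps <- tol / pmax(sqrt(l1), 1e-300)
    if (any(!ident & coll & l1 > 0 & (pmin(hi, 1) - pmax(lo, 0) > eps))) {
      return(TRUE)
    }
  }
  FALSE
}

# Deterministic orthonormal tangent frame for a unit normal: u from the global
# axis least parallel to the normal (lowest index on ties), v = n x u.
tangent_frame <- function(normal) {
  n <- vec_normalize(normal)
  ax <- diag(3)
  dots <- abs(as.vector(ax %*% n))
  e <- ax[, which.min(dots)]
  u <- vec_normalize(e - sum(e * n) * n)
  v <- vec_cross(n, u)
  list(u = u, v = v, n = n)
}

# Binary max-heap of (weight desc, index asc) pairs with lazy deletion.
# Entries carry an id and a stamp; pop skips entries whose stamp is stale.
heap_new <- function(capacity = 64L) {
  env <- new.env(parent = emptyenv())
  env$w <- numeric(capacity)
  env$idx <- integer(capacity)
  env$id <- integer(capacity)
  env$stamp <- integer(capacity)
  env$n <- 0L
  env
}

heap_push <- function(h, weight, tie_index, id, stamp) {
  n <- h$n + 1L
  if (n > length(h$w)) {
    grow <- length(h$w) * 2L
    length(h$w) <- grow; length(h$idx) <- grow
    length(h$id) <- grow; length(h$stamp) <- grow
  }
  w <- h$w; idx <- h$idx; ids <- h$id; stp <- h$stamp
  w[n] <- weight; idx[n] <- tie_index; ids[n] <- id; stp[n] <- stamp
  i <- n
  while (i > 1L) {
    p <- i %/% 2L
    # parent lower priority: smaller weight, or equal weight and larger tie
    if (w[p] < w[i] || (w[p] == w[i] && idx[p] > idx[i])) {
      tw <- w[p]; w[p] <- w[i]; w[i] <- tw
      ti <- idx[p]; idx[p] <- idx[i]; idx[i] <- ti
      td <- ids[p]; ids[p] <- ids[i]; ids[i] <- td
      ts <- stp[p]; stp[p] <- stp[i]; stp[i] <- ts
      i <- p
    } else break
  }
  h$w <- w; h$idx <- idx; h$id <- ids; h$stamp <- stp; h$n <- n
  invisible(h)
}

heap_pop <- function(h) {
  n <- h$n
  if (n == 0L) return(NULL)
  w <- h$w; idx <- h$idx; ids <- h$id; stp <- h$stamp
  out <- list(w = w[1L], idx = idx[1L], id = ids[1L], stamp = stp[1L])
  w[1L] <- w[n]; idx[1L] <- idx[n]; ids[1L] <- ids[n]; stp[1L] <- stp[n]
  n <- n - 1L
  i <- 1L
  repeat {
    l <- 2L * i; r <- l + 1L
    big <- i
    if (l <= n && (w[big] < w[l] || (w[big] == w[l] && idx[big] > idx[l]))) big <- l
    if (r <= n && (w[big] < w[r] || (w[big] == w[r] && idx[big] > idx[r]))) big <- r
    if (big == i) break
    tw <- w[big]; w[big] <- w[i]; w[i] <- tw
    ti <- idx[big]; idx[big] <- idx[i]; idx[i] <- ti
    td <- ids[big]; ids[big] <- ids[i]; ids[i] <- td
    ts <- stp[big]; stp[big] <- stp[i]; stp[i] <- ts
    i <- big
  }
  h$w <- w; h$idx <- idx; h$id <- ids; h$stamp <- stp; h$n <- n
  out
}

# Connected components of an induced vertex subset under a mesh adjacency
# list. Returns an integer component label per member (names = vertex index).
subset_components <- function(adj, members) {
  if (length(members) == 0L) return(integer(0))
  members <- sort(unique(members))
  inset <- logical(length(adj))
  inset[members] <- TRUE
  comp <- integer(length(adj))
  lab <- 0L
  stack <- integer(length(members))
  for (s in members) {
    if (comp[s] != 0L) next
    lab <- lab + 1L
    comp[s] <- lab
    stack[1L] <- s
    top <- 1L
    while (top > 0L) {
      v <- stack[top]
      top <- top - 1L
      nb <- adj[[v]]
      nb <- nb[inset[nb] & comp[nb] == 0L]
      for (w in nb) {
        comp[w] <- lab
        top <- top + 1L
        stack[top] <- w
      }
    }
  }
  out <- comp[members]
  names(out) <- members
  out
}
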