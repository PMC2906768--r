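# Feature-region extraction and vertex-set mathematical morphology.

#' Vertex region
#'
#' A subset of mesh vertex indices (the feature region F'), carrying its
#' connected-component structure under mesh-edge adjacency.
#'
#' @param mesh a \code{tc_mesh}.
#' @param members integer vertex indices.
#' @return object of class \code{tc_region}.
#' @export
vertex_region <- function(mesh, members) {
  members <- sort(unique(as.integer(members)))
  if (length(members) && (min(members) < 1L || max(members) > nrow(mesh$vertices))) {
    stop("region members out of range")
  }
  structure(list(mesh = mesh, members = members), class = "tc_region")
}

region_members <- function(region) {
  if (inherits(region, "tc_region")) region$members else as.integer(region)
}

#' @export
print.tc_region <- function(x, ...) {
  comps <- region_components(x)
  cat(sprintf("tc_region: %d vertices in %d component(s)\n",
              length(x$members), length(comps)))
  invisible(x)
}

#' Connected components of a region
#'
#' Two member vertices are adjacent iff a mesh edge joins them.
#'
#' @param region a \code{tc_region}.
#' @return list of integer vertex-index vectors.
#' @export
region_components <- function(region) {
  lab <- subset_components(region$mesh$adj, region$members)
  if (length(lab) == 0L) return(list())
  unname(lapply(split(as.integer(names(lab)), lab), sort))
}

#' Threshold a curvature field into a feature region
#'
#' Selects vertices whose minimum curvature falls below a threshold: the
#' valley-shaped fusion and blending regions of a dental model have
#' kappa_min < 0 while cusps have kappa_min > 0.
#'
#' @param mesh a \code{tc_mesh}.
#' @param field a \code{tc_curvature} (or numeric kappa_min vector).
#' @param t absolute curvature threshold; if \code{NULL} (default), the
#'   empirical quantile \code{quantile_level} of kappa_min is used (scale-free
#'   across mesh resolutions).
#' @param quantile_level quantile for the default threshold (default 0.15).
#' @return a \code{tc_region} with F' = \{i : kappa_min(v_i) < t\}.
#' @export
threshold_region <- function(mesh, field, t = NULL, quantile_level = 0.15) {
  kmin <- if (is.numeric(field)) field else field$kappa_min
  if (is.null(t)) t <- stats::quantile(kmin, quantile_level, na.rm = TRUE)
  vertex_region(mesh, which(!is.na(kmin) & kmin < t))
}

#' Remove small connected components from a region
#'
#' Components with fewer than \code{min_vertices} members are deleted
#' (strict less-than).
#'
#' @param region a \code{tc_region}.
#' @param min_vertices minimum component size to keep.
#' @return a \code{tc_region}.
#' @export
remove_small_components <- function(region, min_vertices) {
  comps <- region_components(region)
  keep <- comps[vapply(comps, length, 0L) >= min_vertices]
  vertex_region(region$mesh, unlist(keep, use.names = FALSE))
}

#' Morphological dilation of a vertex region
#'
#' dilation_n(F') = \{k : exists j in F' with k in NeiV^n(j)\} -- the union of
#' the (center-inclusive) n-ring neighborhoods of the members.
#'
#' @param region a \code{tc_region}.
#' @param n ring order (>= 1).
#' @return a \code{tc_region}.
#' @export
region_dilate <- function(region, n = 1L) {
  stopifnot(n >= 1L)
  adj <- region$mesh$adj
  members <- region$members
  out <- members
  frontier <- members
  for (step in seq_len(n)) {
    nb <- unique(unlist(adj[frontier], use.names = FALSE))
    frontier <- setdiff(nb, out)
    if (length(frontier) == 0L) break
    out <- c(out, frontier)
  }
  vertex_region(region$mesh, out)
}

#' Morphological erosion of a vertex region
#'
#' erosion_n(F') = \{k : NeiV^n(k) is contained in F'\}.
#'
#' @inheritParams region_dilate
#' @return a \code{tc_region}.
#' @export
region_erode <- function(region, n = 1L) {
  stopifnot(n >= 1L)
  mesh <- region$mesh
  inset <- logical(nrow(mesh$vertices))
  inset[region$members] <- TRUE
  # k survives iff its whole n-ring is inside; equivalently, k is not within
  # n rings of any non-member, so erode = complement(dilate(complement)).
  outside <- which(!inset)
  if (length(outside) == 0L) return(region)
  grown <- outside
  frontier <- outside
  for (step in seq_len(n)) {
    nb <- unique(unlist(mesh$adj[frontier], use.names = FALSE))
    frontier <- setdiff(nb, grown)
    if (length(frontier) == 0L) break
    grown <- c(grown, frontier)
  }
  vertex_region(mesh, setdiff(region$members, grown))
}

#' Morphological opening (erosion then dilation)
#'
#' Removes thin spurs and branches while retaining the region core.
#'
#' @inheritParams region_dilate
#' @return a \code{tc_region}.
#' @export
region_open <- function(region, n = 1L) {
  region_dilate(region_erode(region, n), n)
}

#' Morphological closing (dilation then erosion)
#'
#' Fills pinholes and smooths the region boundary.
#'
#' @inheritParams region_dilate
#' @return a \code{tc_region}.
#' @export
region_close <- function(region, n = 1L) {
  region_erode(region_dilate(region, n), n)
}

#' Apply a morphology schedule
#'
#' @param region a \code{tc_region}.
#' @param schedule character vector of steps \code{"op:n"} with op one of
#'   dilate/erode/open/close; default \code{c("close:1","open:1","close:1",
#'   "open:1")} (close-open applied twice filters small holes and spurs).
#' @return a \code{tc_region}.
#' @export
region_morphology <- function(region,
                              schedule = c("close:1", "open:1", "close:1", "open:1")) {
  for (step in schedule) {
    parts <- strsplit(step, ":", fixed = TRUE)[[1L]]
    op <- parts[1L]
    n <- if (length(parts) > 1L) as.integer(parts[2L]) else 1L
    region <- switch(op,
                     dilate = region_dilate(region, n),
                     erode = region_erode(region, n),
                     open = region_open(region, n),
                     close = region_close(region, n),
                     stop("unknown morphology op: ", op))
  }
  region
}
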