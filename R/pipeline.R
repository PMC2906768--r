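# End-to-end single-tooth modeling pipeline: feature analysis, fusion-region
# removal and restoration, segmentation-boundary extraction, separation.

#' Pipeline configuration
#'
#' Collects and validates every tunable of the modeling scheme.
#'
#' @param k_neighbors quadric-fit neighbor count (16..20; default 18).
#' @param smooth_passes curvature smoothing passes (default 1).
#' @param threshold_quantile kappa_min quantile for feature extraction
#'   (default 0.15); ignored when \code{threshold} given.
#' @param threshold absolute kappa_min threshold (optional).
#' @param min_component minimum feature-component size kept (default 30).
#' @param morph_schedule morphology schedule (see
#'   \code{\link{region_morphology}}).
#' @param alpha triangulation sharp-corner factor (default 1.2).
#' @param k_order harmonicity order for reshaping (1..3, default 2).
#' @param lambda_max initial deformation degree (default 1.0).
#' @param tau lambda adjustment step (must be <= 0.01).
#' @param c_factor refinement density factor (default 1.5).
#' @param min_ring minimum segmentation ring length (default 8).
#' @param min_tooth_triangles separated components below this size are
#'   reported as fragments, not teeth (default 10).
#' @param seed RNG seed recorded in reports.
#' @return validated config list of class \code{tc_config}.
#' @export
pipeline_config <- function(k_neighbors = 18L, smooth_passes = 1L,
                            threshold_quantile = 0.15, threshold = NULL,
                            min_component = 30L,
                            morph_schedule = c("close:1", "open:1", "close:1", "open:1"),
                            alpha = 1.2, k_order = 2L, lambda_max = 1.0,
                            tau = 0.01, c_factor = 1.5, min_ring = 8L,
                            min_tooth_triangles = 10L, seed = 1L) {
  if (tau > 0.01) stop("tau should not be bigger than 0.01")
  if (!k_order %in% 1:3) stop("k_order must be 1, 2 or 3")
  if (!(lambda_max > 0 && lambda_max <= 1)) stop("lambda_max must lie in (0, 1]")
  if (k_neighbors < 6L) stop("k_neighbors must be at least 6")
  if (threshold_quantile <= 0 || threshold_quantile >= 1) {
    stop("threshold_quantile must lie in (0, 1)")
  }
  structure(list(k_neighbors = as.integer(k_neighbors),
                 smooth_passes = as.integer(smooth_passes),
                 threshold_quantile = threshold_quantile,
                 threshold = threshold,
                 min_component = as.integer(min_component),
                 morph_schedule = morph_schedule, alpha = alpha,
                 k_order = as.integer(k_order), lambda_max = lambda_max,
                 tau = tau, c_factor = c_factor,
                 min_ring = as.integer(min_ring),
                 min_tooth_triangles = as.integer(min_tooth_triangles),
                 seed = as.integer(seed)),
            class = "tc_config")
}

#' Run the single-tooth modeling pipeline
#'
#' Executes the five-step scheme on a dental mesh: (1) curvature analysis,
#' (2) fusion-region selection and removal, (3) per-hole shape restoration,
#' (4) re-analysis and blending-region extraction, (5) skeleton-based
#' segmentation and separation. Fusion regions are supplied programmatically
#' (vertex-index lists, e.g. a phantom's ground truth or the result of
#' \code{\link{select_polygon}}), replacing the interactive picking of the
#' clinical workflow.
#'
#' @param mesh a watertight \code{tc_mesh}.
#' @param occlusal_points 4 x 3 matrix of occlusal reference points.
#' @param fusion_regions list of integer vertex-index vectors to remove and
#'   restore (may be empty).
#' @param config a \code{tc_config}.
#' @return list with \code{mesh} (restored), \code{teeth}, \code{base},
#'   \code{rings}, \code{report} (JSON-able summary: per-stage counts,
#'   lambdas, ring lengths), \code{separation}, and \code{vertex_map} (input
#'   vertex id for each surviving work-mesh vertex id within its range).
#' @export
run_pipeline <- function(mesh, occlusal_points, fusion_regions = list(),
                         config = pipeline_config()) {
  if (!inherits(config, "tc_config")) stop("config must come from pipeline_config()")
  report <- list(seed = config$seed,
                 input = list(vertices = nrow(mesh$vertices),
                              triangles = nrow(mesh$triangles)))
  plane <- fit_occlusal_plane(occlusal_points)

  # stage 2-3: remove the fusion regions (one combined cut keeps the vertex
  # indexing consistent), then restore each resulting saddle hole
  work <- mesh
  lambdas <- numeric(0)
  holes <- 0L
  vertex_map <- seq_len(nrow(mesh$vertices))
  if (length(fusion_regions)) {
    cutres <- cut_hole(mesh, unique(unlist(fusion_regions)))
    work <- cutres$mesh
    vertex_map <- cutres$vertex_map
    for (loop in cutres$loops) {
      res <- restore_hole(work, loop, plane, k = config$k_order,
                          lambda_max = config$lambda_max, tau = config$tau,
                          c_factor = config$c_factor)
      # stitching appends patch vertices at the end: earlier loop ids stay valid
      work <- res$mesh
      lambdas <- c(lambdas, res$lambda)
      holes <- holes + 1L
    }
  }
  report$restoration <- list(holes_restored = holes, lambdas = lambdas)

  # stage 4: re-analysis and blending-region extraction
  field <- curvature_field(work, k = config$k_neighbors,
                           smooth_passes = config$smooth_passes)
  region <- threshold_region(work, field, t = config$threshold,
                             quantile_level = config$threshold_quantile)
  region <- remove_small_components(region, config$min_component)
  region <- region_morphology(region, config$morph_schedule)
  region <- remove_small_components(region, config$min_component)
  report$region <- list(vertices = length(region$members),
                        components = length(region_components(region)))

  # stage 5: skeletonize, prune, separate
  skel <- skeletonize(region)
  skel <- prune_skeleton(skel, min_ring = config$min_ring)
  report$skeleton <- list(vertices = length(skel$members),
                          rings = length(skel$rings),
                          ring_lengths = vapply(skel$rings, length, 0L))
  if (length(skel$rings) == 0L) {
    report$teeth <- list(count = 0L)
    return(list(mesh = work, teeth = list(), base = work, rings = list(),
                report = report, region = region, vertex_map = vertex_map))
  }
  sep <- separate_teeth(work, skel,
                        min_tooth_triangles = config$min_tooth_triangles)
  report$teeth <- list(count = length(sep$teeth),
                       sizes = vapply(sep$teeth, function(m) nrow(m$vertices), 0L),
                       fragments = length(sep$fragments))
  # vertex_map: for work-mesh vertex ids no greater than its length, the
  # corresponding input-mesh vertex id (patch vertices added later have none)
  list(mesh = work, teeth = sep$teeth, base = sep$base, rings = skel$rings,
       report = report, region = region, separation = sep,
       vertex_map = vertex_map)
}
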