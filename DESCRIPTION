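Package: toothcarve
Title: Single-Tooth Modeling for 3D Dental Meshes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Geometry-processing toolkit for separating individual teeth from
    scanned 3D dental cast meshes. Provides per-vertex principal-curvature
    estimation by weighted local quadric fitting, vertex-set mathematical
    morphology for feature-region cleanup, direction-traced surface paths and
    spatial-polygon selection, saddle-hole restoration (occlusal-plane guided
    subhole bridging, weight-rule spanning triangulation, 1-3 refinement with
    Delaunay relaxation, constrained k-harmonic reshaping and blend control
    with interference checking), and skeleton-based segmentation-boundary
    extraction. Includes synthetic torus and multi-cusp dental phantoms with
    analytic curvature oracles, and readers/writers for STL, OBJ and PLY.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Matrix,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
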