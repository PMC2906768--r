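---
title: "Single-tooth modeling: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Single-tooth modeling: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(toothcarve)
```

This vignette explains the models and algorithms behind `toothcarve`, the
assumptions they make, the tunable parameters and their defaults, what the
synthetic phantoms do and do not emulate, and the design choices taken where
the method left room for interpretation. Every empirical statement here is
one the package's own test suite or acceptance script computes.

## The problem

A scanned dental cast is one watertight 2-manifold triangle mesh (model
units are millimetres; clinically useful scans carry tens of thousands of
triangles). Adjacent teeth are frequently fused in the scan, and the tooth /
soft-tissue boundary is not represented. Producing per-tooth closed meshes
requires (i) finding the fused and blending regions, (ii) removing the
fusion regions and restoring each tooth's missing interproximal surface, and
(iii) cutting along the blending boundary.

The anatomical signal is differential: fusion and blending regions are
valley-shaped (minimum principal curvature κ_min < 0), cusps and incisal
edges are hills (κ_min > 0).

## Curvature estimation

At each vertex the surface is modeled as a degree-2 height function over the
tangent plane, φ(u, v) = a₀₀ + a₁₀u + a₀₁v + a₂₀u² + a₁₁uv + a₀₂v², fitted
by weighted least squares over the k nearest n-ring neighbors (n grown until
at least k candidates exist). The weight of neighbor j is exp(−d_j / max d),
d_j its distance from the vertex. Mean and Gaussian curvature come from the
first and second fundamental forms of the fitted patch at the origin;
κ_min/κ_max follow from κ_H ∓ √(κ_H² − κ_G), with a tiny negative radicand
(> −10⁻⁹) clamped to zero and anything worse treated as a failed fit.

Parameters and conventions:

* **k (neighbor count), default 18.** Between 16 and 20 the estimate is
  stable; 6 is the algebraic minimum (six coefficients).
* **Tangent frame.** The φ-axis is the cotangent-weighted vertex normal.
  Because the result is normalized to a unit direction, the leading area
  constant of the discrete normal formula is irrelevant; the printed
  coefficient differs from the operator literature by a factor of 2 and we
  simply normalize. The cotangent direction flips toward the surface on
  concave vertices, so it is sign-aligned with the area-weighted face-normal
  average, which also serves as the fallback at boundary vertices and where
  the cotangent sum cancels. The in-plane axes (u, v) are built
  deterministically from the global axis least parallel to the normal —
  curvatures are frame-invariant, so the choice only fixes reproducibility.
* **Sign convention.** Normals point outward; convex features (cusps) then
  get κ_min > 0 and valleys κ_min < 0. Equivalently the second fundamental
  form is taken with respect to the inward normal, which negates κ_H and
  leaves κ_G unchanged.
* **Degenerate neighborhoods.** Rank-deficient normal equations trigger ring
  enlargement and retry (three attempts) before erroring.

The curvature field can be smoothed by inverse-distance averaging over the
1-ring (weights 1/‖v_i − v_j‖). As printed, those weights do not sum to one
and the stencil excludes the center; we normalize per vertex — otherwise a
constant field would be rescaled, which contradicts the smoothing purpose —
and keep the center excluded by default (a switch includes it). One pass is
the default.

A Laplace–Beltrami baseline (cotangent formula with Meyer mixed areas,
obtuse-triangle special case; Gaussian curvature from the angle deficit) is
included for comparison. On the analytic torus (R = 2, r = 1) with seeded
Gaussian vertex noise, the quadric estimator's mean absolute κ_H error is
strictly below the baseline's at noise levels h ∈ {0.1, 0.5, 1.0} averaged
over five seeds — the package's noise-robustness test.

**Noise convention.** The level h is dimensionless: each vertex is displaced
along its normal by a zero-mean Gaussian with standard deviation h × (mean
edge length). Along-normal displacement is chosen because tangential noise
is invisible to curvature at first order. The robustness comparison is
formulated relatively (quadric vs. baseline), so it is invariant to this
scale convention.

## Feature regions and morphology

The feature region F′ is the vertex set with κ_min below a threshold.
The threshold is exposed both as an absolute value (1/mm) and as an
empirical quantile of the κ_min distribution (default quantile 0.15,
scale-free across resolutions). Components smaller than `min_component`
(default 30 vertices, strict less-than) are dropped. The four morphology
operators act on vertex sets through n-ring neighborhoods: dilation is the
union of member neighborhoods, erosion keeps vertices whose whole
neighborhood is inside, opening is erosion-then-dilation (removes spurs),
closing is dilation-then-erosion (fills pinholes) — the composition order is
fixed by the operators' stated purposes. The default schedule applies
close(1), open(1) twice. These operators satisfy the standard lattice laws
(anti-extensivity/extensivity, monotonicity, idempotence of open/close),
property-tested against brute-force set evaluation.

## Surface paths and polygon selection

Interactive region picking is replaced by programmatic selection: a straight
"line" between two surface points is traced by intersecting the current
carrier triangle with the normal-section plane through the current point
spanned by the direction to the destination and the local normal, choosing
among candidate exits the one minimizing the angle to the destination
direction (ties: the farther advance, guaranteeing progress). On a flat mesh
the trace reproduces the Euclidean segment to machine precision; on a sphere
it approximates the great circle (within 3% in the tests). Exact vertex hits
are snapped to the vertex and continued through its star. A closed fence of
such lines separates the surface; enclosed triangles are found by flood fill
from a seed (default: nearest the anchors' centroid) with adjacency blocked
across crossed edges. Where the fence passes through a mesh vertex
transversally, the vertex star is fenced too — edge blocking alone would
leak around the vertex.

## Hole restoration

Removing a fusion region leaves a saddle-shaped hole whose boundary belongs
to two teeth. Filling it as one patch averages the two teeth's shapes; the
method instead:

1. **Bridges** the loop at the two boundary vertices farthest (in absolute
   distance) from the occlusal plane — the deepest points on the buccal and
   lingual sides — provided both loop arcs between them dip strictly below
   both endpoints (a genuine saddle; otherwise an error). The occlusal plane
   is the total-least-squares plane of four cusp-tip reference points.
2. **Spans** each subloop with the weight-rule advancing triangulation. Ear
   candidates are consecutive boundary triples; the weight, in priority
   order: −∞ if any of the candidate's edges crosses an existing edge when
   the 1-ring is projected onto the vertex tangent plane; (|NeiT¹|/8)·R_C
   (positive, clipped first) if the apex already has more than 8 incident
   triangles; −(π/A)·R_C (strongly negative) if the apex's adjacent-angle
   sum A is below α·π with α = 1.2; otherwise minus the perimeter. R_C is
   the bounding-sphere radius. A_sum in the sharp-corner weight is read as
   the apex's adjacent-angle sum — the only nearby quantity that makes the
   weight well-defined; adjacent angles count all current incident
   triangles, surrounding mesh and patch alike. Weights live in a priority
   queue (ties: lowest original boundary index); clipping an ear refreshes
   the weights of every apex whose triple involves the two surviving
   neighbors, because the projection test reads their incident-triangle
   sets — the queue then agrees triangle-for-triangle with a quadratic
   rescan reference, which the tests assert on random loops. If every
   remaining candidate fails the projection test, one clip is taken by
   least perimeter ignoring it (logged in the patch), preventing deadlock.
   The result spans exactly the |B| boundary vertices with |B| − 2
   triangles.
3. **Refines** the spanning patch by 1→3 centroid splits of triangles whose
   mean edge length exceeds c × the surrounding mesh's mean (c = 1.5,
   "surrounding" = triangles within 2 rings of the loop), relaxing interior
   edges by Delaunay flips (opposite-angle sum above π; boundary edges never
   flipped) after each sweep. A split is only taken when all three new
   centroid edges would stay above the target length: without that guard a
   long thin triangle can be split forever, since the children inherit its
   long edges; the flips, not the splits, are what shorten those.
4. **Reshapes** the refined patches by the discrete k-harmonic system: the
   cotangent Laplacian with the printed 2/Area(v) scaling (Area = full
   1-ring triangle area sum; a positive diagonal rescaling that leaves the
   k = 1 solution set unchanged and defines the printed operator verbatim
   for k ≥ 2) is assembled on the host mesh with both patches glued in, its
   k-th power's rows at the free interior vertices are set to zero, and all
   other vertices are pinned — the pinned collar supplies the C^(k−1)
   boundary data. k = 1 gives a membrane, k = 2 (the dental default) a thin
   plate, k = 3 a curvature-variation minimizer; k outside 1..3 is an
   error. Both subhole patches are solved in one system so each sees the
   other's boundary. The sparse solve is a direct factorization; residuals
   above 10⁻⁶ × bounding-box diagonal abort.
5. **Blends**: P_final = P_refine + λ(P_deform − P_refine), starting at
   λ = 1 and stepping down by τ (τ ≤ 0.01 enforced) until the two final
   patches do not intersect — triangle–triangle interference excludes pairs
   sharing a vertex (the bridge edge) — and erroring if λ would fall below
   0.8. The restored patches are stitched back; if the input minus the hole
   was closed, the result is watertight with unchanged genus (tested by
   Euler characteristic).

## Segmentation-boundary extraction

After restoration, curvature is re-analyzed and the blending region
extracted. The vertex complexity CP(i) is the cyclic sum of absolute
successive differences of the 0/1 region-membership indicator around the
vertex's ordered 1-ring, wrap-around term included (the ring is cyclic, and
without the wrap CP would depend on the arbitrary start). For mesh-boundary
vertices the 1-ring is an open chain whose ends are not adjacent; the
indicator is padded with non-members there, otherwise a member at each chain
end would masquerade as one run and its removal could disconnect the region.
CP is twice the number of membership runs: CP = 0 with a full member ring
marks a center vertex, CP ≥ 4 a complex vertex.

**Peeling rule.** Centers (their removal would open a ring inside the
region) and complex vertices (their removal would break connectivity) are
never removed. The removable set as literally printed — current neighbors of
center vertices only — provably stalls on any region that is nowhere three
vertices wide: a two-wide band has no centers, hence no satellites, hence no
candidates, contradicting the width-one skeleton the procedure is meant to
reach. The package therefore peels *boundary-simple* vertices: not a center,
exactly one membership run (CP = 2), and at least two member neighbors. Such
a vertex's member neighbors form a contiguous, mutually connected arc, so
its removal retracts the region without changing its component count or its
loops (verified by Betti-number tests); run-of-one vertices are branch
endpoints left to the pruning stage. Removal order is ascending complexity,
then ascending vertex index, with the affected neighbors' status recomputed
after every removal.

**Pruning** alternates two steps to a fixpoint: iterative deletion of
vertices with at most one skeleton neighbor (open branches peel inward from
their endpoints — the skeletons of non-target regions such as ridges are
open branches, so they disappear without interaction), and a re-peel, since
removing a branch can expose chord vertices that were locked while the
branch was attached. Components shorter than `min_ring` (default 8,
automating the interactive removal of small redundant rings) are dropped.
On an annulus-band fixture the result is a single 2-regular closed ring with
the band's winding number.

**Separation** cuts the mesh along every edge joining two skeleton vertices:
triangle adjacency is blocked across those edges and connected components
are extracted, duplicating ring vertices into each side (teeth keep their
cervical margin). This also handles θ-shaped skeletons — two tooth rings
joined by the interdental valley line — where cutting along the whole graph
still yields one component per tooth. The largest component is taken to be
the cast base; components below `min_tooth_triangles` (default 10) are cut
artifacts reported as fragments, not teeth.

## Synthetic phantoms

* **Torus** (wheel R = 2, tube r = 1 by default), sampled on an n_u × n_v
  grid, with closed-form per-vertex curvatures as oracle.
* **Dental phantom**: a heightfield row of Gaussian cusps (height 6 mm,
  width 2.2 mm) on a flat gingiva plane at 0.35 mm resolution, each cusp
  encircled by an annular blending groove (radius 4.2 mm, depth 1.2 mm);
  fused pairs are joined by a smooth ridge (2.2 mm over the base) emulating
  the fused interproximal scan surface, with the saddle col between the
  cusps as the fusion region. The heightfield is closed by walls and a flat
  bottom into a watertight mesh. Ground truth: conservative per-cusp cores
  (inside 80% of the groove radius — groove-floor vertices are genuinely
  boundary and are deliberately unlabeled), valley-floor sets per adjacent
  pair, and the fusion band per fused pair. Amplitudes are set so the
  valley floors have κ_min below roughly −0.2/mm, well separated from the
  flat base.

The phantom emulates the geometry the method exploits — valley-shaped fusion
and blending regions between hill-shaped crowns — but not scanner artifacts
(holes, spikes, anisotropic sampling), real enamel microtexture, or arch
curvature. Passing the end-to-end test therefore demonstrates the pipeline's
correctness on clean anatomy-like geometry, not robustness to raw scanner
output.

For the end-to-end study the feature threshold is set to κ_min < −0.1/mm
rather than the quantile default: the phantom's valley area fraction
(≈ 19% of the surface) exceeds the 0.15 quantile's coverage, which would cut
the grooves into open arcs; −0.1/mm sits between the groove floors (≈ −1.5)
and the flat base (|κ_min| ≲ 0.05) and is the natural absolute choice when
units are known. Problem sizes used by the tests: phantoms of 2–4 cusps
(≈ 3–5 thousand vertices), tori of 60 × 30 (noise study) and 100 × 50
(clean accuracy), boundary loops of 241 and 437 vertices.

## Numerical choices and known limitations

* Duplicate-vertex merge tolerance on import: 10⁻⁹ × bounding-box diagonal
  (STL duplicates are bit-identical in practice).
* Geometric predicate tolerances: 10⁻¹² relative for segment crossing and
  triangle intersection; exact-arithmetic predicates are out of scope.
* The weight-queue tie rule (lowest original boundary index) exists for
  reproducibility and for oracle equivalence; any fixed rule would do.
* `trace_line` is an approximate geodesic; exact geodesics (MMP, heat
  method) are out of scope, as are VRML input, color/texture attributes,
  and mesh repair beyond duplicate merging.
* Candidate exits in `trace_line` are restricted to the forward direction;
  the behavior at normal sections grazing backward triangles is thereby
  fixed.
* Fragments from cutting (single triangles isolated by skeleton junctions)
  are reported, not silently merged.
* The base/tooth designation after cutting (largest component = base) is a
  heuristic that is correct for casts, where the base dominates.
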