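---
title: "Automated odontometry on triangulated crowns: models and choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Automated odontometry on triangulated crowns: models and choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette records the scientific model behind the package, the tunable
parameters and their defaults, what the synthetic fixture does and does not
emulate, and the numerical choices made where the design was genuinely
open. It states no empirical result that the test suite does not itself
compute.

## The measurement model

A posterior tooth crown is represented as a triangulated irregular network
in millimetres. The pipeline makes three anatomical identifications:

1. **The occlusal surface is a bounded central depression.** Its border is
   the crest of maximal Gaussian curvature `K = κ₁κ₂` that encircles the
   depression; the mean of the border normals defines the vertical axis,
   the border centroid the origin.
2. **Transverse contours show two principal elevations.** The cusp pair
   admits exactly one common tangent line bridging the occlusal valley;
   the parallel line through the deepest occlusal point completes the
   construction, giving the occlusal depth as the inter-line distance.
3. **Enamel-cap contours are closed bands.** Outer (enamel) and inner
   (dentine-facing) arcs meet at the two cervical enamel edges; splitting
   there lets both morphological layers be measured under one orientation.

## Parameters that matter

| parameter | default | units | why |
|---|---|---|---|
| curvature radius | 5 × mean edge length | mm | smallest ball giving stable overdetermined quadric fits; for border work on the bundled fixture use ~ r0/3 (0.8 mm), i.e. small enough to resolve the fossa-rim crest |
| border percentile | 90 | – | top-K share among convex vertices; scale-free proxy for "maximal K" |
| orientation tolerance | 0.005 | rad | vertical-axis settling threshold; well below the pipeline's own angular noise |
| max iterations | 10 | – | border/frame alternation cap |
| calibration angle | 25 | deg | if the border-ellipse major axis and the crown's maximal planar extent disagree more than this, the extent wins and the frame is flagged |
| sections `ns` | 80 | – | the dense sectioning mode; maxima of plateaued per-section profiles stabilise with dense stacks |
| landmark mode | euclidean | – | hull-bridge construction; `curvature` reproduces the contour-curvature variant |
| curvature window | 0.5 | mm | arc-length smoothing for curvature mode (resampling step = window/10) |
| min pocket depth | 0.2 | mm | valley shallower than this is mesh noise, not an occlusal groove; drives marginal-section exclusion |
| contour minima | 1.0 × 0.5 | mm | width × height below which a sliver contour is invalid |

## Occlusal border detection: depression-first

The obvious reading — threshold K, take connected components of the mask,
extract a cycle — fails structurally on enamel caps: cusp tips, cervical
creases and flank ridges monopolise the top percentile, and the crest never
forms one connected ring. The implemented detector inverts the search:

1. Concave basins = connected components of negative mean curvature.
   Basins spanning more than 35 % of the surface are rejected (the pulpal
   vault of a cap is one giant concave component, not a "centrally located
   depression").
2. For each basin, the border is traced per azimuth as the maximal-κ₁
   vertex just outside the basin edge (window = basin edge + 2.5 smoothing
   radii), preferring vertices of the high-K percentile mask. κ₁ rather
   than K localises the crest where it crosses saddle cols between cusps
   and marginal ridges, where K changes sign but the transverse ridge
   curvature still peaks. A second pass re-picks each azimuth near the
   circular running median of the first-pass radii, rejecting undershoot
   onto the basin wall and overrun onto cusp flanks.
3. The loop must encircle a genuine depression: the enclosed same-facing
   region lies below the loop plane and is concave on average. Among
   qualifying basins the largest enclosed area wins; near-ties raise an
   ambiguity error.

The frame's vertical axis averages the loop-vertex normals (crest-top
normals are unbiased); the ellipse fit uses a 0.5 mm support tube around
the loop, a nearly selection-invariant point set that stabilises the
mesio-distal axis against vertex-quantisation jitter.

## Landmark construction details

*Euclidean mode.* The bridge is chosen exhaustively over upper-hull edges
by maximal subtended pocket depth (this also resolves contours with a small
intermediate cuspule). Two guards reject non-occlusal pockets: the bridge
must sit above the contour's vertical midline, and both tips must stand
above the valley floor (a pocket under a single hump's flank tail is not an
occlusal valley). On smoothly sampled summits the true tangency point lies
between vertices, so each tip is refined by a local parabola in the
tip-line frame and the bitangent iterated to convergence; sharp corners
(turning angle > 20°) are kept as vertices, which keeps hand-built
polygonal test contours exact. The refinement matters: tip positions on
blunt cusps are otherwise vertex-quantised, and the end-to-end
rigid-invariance of the occlusal width improves by roughly an order of
magnitude.

*Curvature mode.* The contour is arc-length resampled (step = window/10)
and its signed discrete curvature smoothed over the window. Cusp summits
are selected by topographic prominence of the height profile — robust
against intermediate ridgelets that carry higher curvature than blunt
cusps — and each tip is then localised at its summit's convex-curvature
maximum, so the two modes genuinely differ (as they should) on real
contours while agreeing on idealised two-hump fixtures.

*Cap splitting.* Cervical enamel edges are detected among lower-half
vertices with exterior turning angles above 45°, taking the outermost
(extreme-abscissa) corner of each cervical notch: an offset shell meets the
cervical plane in a flat notch with two corners, and the enamel edge proper
is the outer one.

## The synthetic fixture: what it emulates

The generator builds the crown top as a smooth analytic height field over
an elliptical base: a bulging dome (vertical tangent at the margin, so the
maximal width sits at the cervix), two blunt super-Gaussian cusps, an
elongated central fossa, and an explicit marginal-ridge crest at the
requested crest-ring radius. All perturbations are tapered to zero at the
margin so the cervical curve is exactly the base ellipse at z = 0. The
inner surface is a uniform inward offset along the analytic normal; outer
and inner tops plus a flat cervical annulus form a watertight enamel-cap
shell. Ground truth (cusp tips, fossa point, crest ring, cervical curves,
maximal dimensions) is computed from the continuous model by bounded
numerical optimisation, independent of the meshes.

Default geometry (chosen once, to the scale of an upper second molar):
crown 14 mm vestibulo-oral × 15 mm mesio-distal, cusp tips at 6.7/6.5 mm,
occlusal relief calibrated to exactly 3.0 mm, crest ring radius 2.5 mm,
enamel thickness 0.75 mm, target edge length 0.25 mm. Three defaults are
worth justifying:

- **Enamel thickness 0.75 mm.** An inward offset self-intersects where the
  offset exceeds the smallest curvature radius of the outer surface
  (~0.8 mm at the cusp shoulders of this model); the generator guards
  against this explicitly. Real cuspal enamel is thicker, but modelling
  non-uniform thickness is a non-goal.
- **Blunt cusps.** Super-Gaussian bumps keep apex curvature low for the
  same reason; they also make cusp-tip landmarks a genuinely hard (flat
  summit) case for the landmark stage rather than an easy sharp corner.
- **Mesio-distally elongated groove (elongation 2.2).** As on real molars
  the occlusal valley runs most of the crown length. This also makes the
  interior layer's valley fade about one enamel thickness earlier toward
  the crown ends, reproducing qualitatively the observation that dentine
  yields fewer usable contours than enamel.

What the fixture does **not** emulate — and hence what a green test does
not establish: enamel bulging above the cervix (a height field cannot
overhang, so both layers' cap sectors share the cervical edge points and
their width ratio sits at 100 %, a few percent above real crowns);
non-uniform enamel thickness; wear facets, multi-cusp crowns, scanning
noise beyond optional Gaussian vertex jitter; and segmentation artefacts.

## Numerical choices and degenerate inputs

- Curvature estimation needs ≥ 6 neighbours in the ball; fewer raises an
  under-sampled error naming the vertex. Vertex normals are angle-weighted;
  the fitted (quadric) normal is carried in the field.
- Duplicate vertices are merged at 1e-9 mm; faces below 1e-12 mm² are
  degenerate; edges bordering > 2 faces make repair fail loudly with the
  offending edges listed.
- Hole filling is perimeter-capped (default 2 mm) so a cervical opening can
  never be "repaired" shut. Smoothing is Taubin (0.5/−0.53) to avoid the
  shrinkage of plain Laplacian smoothing. Decimation is greedy quadric
  edge collapse with midpoint placement; collapses whose quadric error
  exceeds the drift tolerance are refused, and the target may therefore
  not be reached (a warning, not an error).
- The ellipse fit is the direct least-squares (ellipse-specific) method;
  circles break the axis tie toward (1, 0). The fitted axis is
  disambiguated against the data spread, which is convention-free.
- A sphere (no depression) or a degenerate border (collinear, cancelling
  normals) raise typed errors rather than returning frames.
- Sign conventions: the vertical axis points occlusally (positive dot with
  centroid-to-border direction); the positive mesio-distal direction is the
  larger crown half, overridable via the tooth-number/buccal-mark hints;
  the vestibulo-oral sign follows the buccal mark when given.

## Known limitations

- Pointwise crest localisation is limited by the curvature smoothing
  radius where the fossa-rim crest and a cusp shoulder approach within one
  smoothing length: the traced point can legitimately sit on either ridge
  (up to ~1 mm on the bundled fixture). The frame is insensitive to this
  (sub-degree recovery in the test suite), because it averages over the
  whole loop.
- The loop is azimuthally binned (72 bins) around the basin centroid;
  strongly non-star-shaped occlusal borders would need a different
  ordering scheme.
- Measurements on severely worn (single-elevation) contours are refused by
  design; such sections are excluded rather than guessed at.
- The iteration between border re-selection (restricted to the
  occlusally-facing half-space) and frame recomputation settles in 1–2
  iterations on the fixtures; its convergence is monitored, not proven.
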