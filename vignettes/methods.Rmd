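---
title: "Quantifying spatial expression along the embryonic cell layer: models and choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying spatial expression along the embryonic cell layer: models and choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(layerquant)
```

## The measurement model

A two-layered embryo seen in cross-section is a ribbon of tissue bounded by
two closed curves: the outer surface of the ectoderm and the inner surface
facing the blastocoel/archenteron. In situ hybridization stains transcripts
dark; under the assumption that stain density is proportional to local
transcript concentration and the tissue is optically thin, the mean inverted
intensity of the pixels in a patch of the ribbon estimates expression there.
`layerquant` makes that estimate along the full length of the cell layer:
the ribbon is tiled with parallel quadrilateral segments, and the per-segment
channel means, plotted against arc position, form the expression profile.

This model deliberately ignores what a cross-section cannot see: variation
through the thickness of the layer, chromogenic saturation, and the optical
interaction of the two body walls in a whole mount. The standardized output
is therefore a *relative* spatial profile (maximum fixed at 100), never an
absolute concentration.

## Geometries and splines

A geometry is two closed node rings (≥ 4 nodes each, normalized
counterclockwise) plus optional endoderm–ectoderm boundary markers and an
aboral anchor, both stored as arc-length fractions so they survive
averaging and interpolation. Nodes are connected by periodic cubic splines
under cumulative chord-length parameterization, sampled at 10⁵ points by
default; open node chains (used internally nowhere, but supported) get
natural end conditions. Chord-length parameterization was chosen because
node spacing from manual digitization is irregular; a uniform parameter
would warp the curve toward densely digitized stretches.

Averaging across embryos is node-wise and assumes the user digitized
corresponding anatomical positions with the same node count — there is no
automatic correspondence, matching common practice for small (2–5 embryo)
stage averages. Stage interpolation is linear in node coordinates, which is
adequate between adjacent stages where shapes differ smoothly.
Registration onto a new image is a closed-form least-squares similarity
transform (uniform scale, rotation, translation) from ≥ 2 landmark pairs;
individual nodes can then be overridden with `set_node()`, replacing the
interactive dragging a GUI would provide.

## Decomposition parameters

`decompose_cell_layer()` has three tunables:

* `segment_length` (px): target outer-curve arc per segment. The segment
  count is `round(perimeter / segment_length)` with the remainder spread
  uniformly, so the closed ribbon is tiled exactly; the paper-style choice
  of ~100 segments per embryo corresponds to `perimeter / 100`. Smaller
  segments raise spatial resolution but lower the pixel count per segment
  (noise) — below ~3 px segments on a 400 px embryo, single-pixel effects
  dominate.
* `gap_factor` (default 1.5): inner-curve arcs between consecutive nearest-
  point matches longer than `gap_factor * segment_length` are subdivided
  and matched back to the outer curve. This only triggers where the inner
  curve locally runs much longer than the outer one (deep invaginations).
* `smoothing_span` (odd, default 3) and `smoothing_passes` (default 1): a
  circular moving average applied to the boundary arc positions on both
  curves, which evens out segment widths after nearest-point matching. A
  single pass suffices on smooth geometries; uniform boundaries are a fixed
  point of the filter.

Pixel membership uses pixel centers at half-integer coordinates and the
even-odd rule, with no sub-pixel area weighting: each pixel belongs to
exactly one segment, so segment means are exactly re-computable (and are
tested against an exhaustive enumeration). Segments that catch no pixel
center — possible only for sub-pixel segment sizes — are filled by circular
interpolation from neighbours and flagged. Greyscale is the unweighted mean
of the three channel means; Rec.601 luma weights are available via
`grey = "luma"` but change nothing qualitative for purple/blue chromogens.

## Profile editing and the standardized coordinate

The editing operators mirror what a curator does to a raw trace: repair
annotation artefacts over a chosen index interval (linear interpolation
across the flanks, natural cubic spline or monotone Hermite over 4 context
points per side, or a constant), smooth with a circular moving average
(coefficients 1/span — circular because the ribbon is closed; a truncated
window would bias the two profile ends, which are the same physical point),
subtract a constant background with clamping at zero (expression cannot be
negative), zero out regions judged expression-free, and symmetrize by
averaging `v(s)` with `v(L − s)`. The symmetrization axis is the
decomposition start point (the aboral anchor), which for a symmetric
geometry also fixes the oral pole; it cancels lighting asymmetries but
must be skipped for genuinely asymmetric patterns.

Standardization maps arc position to the normalized coordinate piecewise
linearly: aboral pole → ±50, boundaries → ±`pin` (default 25, configurable;
the midpoint between boundary and pole is not anatomically meaningful, so
any fixed pin merely makes profiles comparable), endoderm center → 0.
Profiles without an endoderm (blastula stages) use oral pole → 0 with no
pins. The grid has 101 points so every integer position from −50 to +50
exists; values are linearly resampled and scaled to a maximum of 100. The
−50 and +50 samples are assigned from the same arc position, so their
equality is exact by construction. An all-zero profile is an error unless
`allow_zero = TRUE`, because rescaling it is undefined.

## 3D reconstruction

**Two views.** After aligning the oral image's height by the 1D least-
squares affine map between reference-point z coordinates, the volume is
`P[x, y, z] = min(S1[z, x], S2[z, y])`. The minimum is the only
conservative choice for dark stain: a voxel can be no more stained than
either of its projections, so the reconstruction is an outer bound that is
exact for patterns that are prisms along each viewing direction (the box
phantom round-trips exactly).

**One view.** For patterns roughly rotationally symmetric about a drawn
axis, each voxel at azimuth θ ∈ [0, π] from the image half-plane and radius
r takes the weight-averaged value `(1 − θ/π)·I(S1) + (θ/π)·I(S2)` of the
two intersections of its arc with the image plane, sampled bilinearly;
base points outside the image contribute 0. The linear-in-angle weight is
the simplest smooth interpolation between the two half-planes; it
reproduces the input exactly on the image plane and makes the volume
mirror-symmetric across it by construction.

**Slicing and landscapes.** Slices are full planes through the primary (x)
axis at angles k·180°/n, sampled trilinearly on the voxel grid; slice 1 is
the central plane, and the plane at angle 180° − a is the plane at a with
the in-slice coordinate flipped, so with 9 slices the last four repeat the
first half in reverse order. A landscape decomposes every slice with one
shared geometry (registered to the central slice), replays one shared edit
script, standardizes each profile and stacks the rows.

## The phantom generators

Phantoms emulate exactly the features the pipeline must cope with: a
two-layer ribbon (concentric circles, or circles with a Gaussian-profile
oral dimple for gastrula stages), a painted expression function g(s) along
the mid-curve, a light background with an optional linear lighting
gradient, dark glyph boxes standing in for "en"/"ec" style annotations
(only their artefact effect matters, so no text is rendered), and Gaussian
pixel noise under a caller-supplied seed. The whole render runs under that
seed and is bit-reproducible. Phantom volumes are axis-aligned boxes,
spherical shells with a linear edge ramp (default 2 voxels — hard binary
shells alias under oblique trilinear sampling), and uniform blocks; view
pairs are maximum-intensity projections, the optical model for a fully
transparent specimen with dark stain.

What phantoms do **not** emulate: chromogen saturation, out-of-focus blur,
partial occlusion by the second body wall, and biological asymmetries.
Passing the phantom suites therefore demonstrates the geometry and
measurement machinery, not robustness to real-world optics.

## Numerical choices and problem sizes

* Curves are compared and measured through their dense samples; nearest-
  point queries are exact scans over the samples with lowest-index
  tie-breaking.
* Interpolation is linear everywhere data are resampled (profiles, view
  rows, volume slices); bilinear/trilinear in 2D/3D. Out-of-support samples
  are 0.
* The test suite uses 2·10⁴-point curves for decompositions (arc
  quantization ≪ 0.1 px at the phantom scales used), 400×400 px rendered
  phantoms with 100 segments, 50³ two-view volumes, 61³ radial volumes and
  an 81³ soft-edged shell for the landscape symmetry check — sizes at which
  every property is interpolation-limited rather than resolution-limited.
* Clustering uses `d = 1 − r` as the monotone bridge from similarity to
  distance, unweighted average linkage, and drops the duplicated +50 grid
  point before correlating so the aboral pole is not double-weighted.
  Groups are renumbered in dendrogram leaf order for stable output.

## Known limitations

* Similarity transforms cannot absorb anisotropic distortion between image
  and geometry; heavy distortion needs manual node overrides.
* The radial reconstruction assumes the drawn axis lies in the image plane;
  tilted axes are not modelled.
* `average_geometries()` averages boundary markers arithmetically, which is
  wrong if markers of different embryos straddle the ring seam; anchor your
  digitization so markers stay away from arc fraction 0.
* Landscape rows are standardized independently (each row's maximum is
  100), so angular amplitude modulation is visible only before
  standardization — use the raw per-slice profiles to quantify it.
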