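---
title: "Topological segmentation of confocal z-stacks: model, parameters and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Topological segmentation of confocal z-stacks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(persiseg)
```

## The model

`persiseg` treats a grayscale slice as a function on a cubical complex:
pixels are the vertices, axis-adjacent pixels are joined by edges, and each
elementary square spans four mutually adjacent pixels. The intensity is
extended to higher cells by the maximum rule (an edge or square carries the
maximum of its pixels), which makes the family of sublevel sets
`K_t = {u <= t}` a filtration: cells enter in a nested order as `t` grows.

Order-1 homology of `K_t` counts its holes. Under the maximum rule a hole
of the sublevel complex is a bright region enclosed by darker pixels, so
tracking H1 along the ascending filtration inventories every bright shape
together with its lifetime, `persistence = death − birth`: the intensity
contrast between the shape's core and the level at which its surrounding
loop first closed. Running the same machinery on the descending
(superlevel) filtration inventories the dark blobs enclosed by brighter
surroundings — the internal cavities. Persistence is invariant to adding a
constant to the image and scales linearly with intensity rescaling, which
is what makes the automatic threshold below meaningful across slices.

### How the diagrams are computed

The engine uses planar duality rather than boundary-matrix reduction: a
hole of the sublevel complex is a bounded component of its complement, and
the complement is tracked on the grid of unit squares plus a single
"outside" node. Two squares communicate through their shared edge (weight:
the maximum of its two pixels) or shared corner pixel; border squares
communicate with the outside through the rectangle's border edges. A
union-find sweep over these dual edges in decreasing weight order, with the
elder rule (the component with the higher extreme survives a merge),
produces exactly the finite H1 pairs: a component with extreme `d` that is
absorbed at weight `b` is a hole alive for `t` in `[b, d)`. The sweep is
compiled (Rcpp); everything else is vectorized R.

Correctness is pinned by an independent oracle, `betti1_at_threshold()`,
which recounts β1 at any threshold from the Euler characteristic
`V − E + F` and a plain flood-fill component count. The test suite checks
diagram/oracle agreement at every distinct intensity of seeded random
images (16 x 16, an 11-value intensity grid, both directions), along with
the shift/scale equivariance properties above.

Numerical conventions:

* zero-persistence pairs are discarded — they carry no shape information;
* cells with equal value enter in a fixed order (edge-adjacency cracks,
  then corner cracks, then border cracks, then construction index), and
  equal component extremes are resolved toward the lower cell index, so
  diagrams are bit-reproducible;
* the complex is exactly the image rectangle. A bright structure touching
  the border never closes its loop and is dropped; `pad_border = TRUE`
  adds one dark pixel all around when such structures must be kept.

### Representatives

The diagram alone does not say *where* a class lives. Each pair is
represented by the 8-connected component of the strict level set at the
pair's birth value (`{u > birth}` for sublevel classes, `{u < birth}` for
superlevel ones) that contains the pair's critical pixel, and the closed
curve traced around that region on the pixel-corner lattice.
8-connectivity matches the dual-graph adjacency, so the region is exactly
the set the class was born around; taking it at the birth level means an
elder class keeps its original extent when a saddle later splits its
region — the younger class, born at the saddle, gets the smaller region at
the saddle level. This reproduces the nested-representative configuration
that the splitting rule (below) is designed to resolve.

Contours live on pixel corners (half-integer coordinates) so that even a
single-pixel region has a well-defined closed boundary of four unit steps;
a parity scanline fill reconstructs the interior mask exactly from the
vertices, and the stored mask is defined as that fill (fill-consistency is
asserted in the tests).

## The automatic persistence threshold

Given the positive persistences `p_1 ... p_n` of a diagram (intensities
normalized to [0, 1]), the selector scans the sorted values together with
the zero anchor — the diagram diagonal — and returns the midpoint of the
widest gap; ties go to the gap at higher persistence, and classes with
persistence strictly above the threshold are selected. The zero anchor
encodes that persistence is measured from the diagonal: a diagram whose
values form one tight cluster far from the diagonal is entirely signal and
must not be split by its own small internal gaps (a singleton diagram, or
two cavities of equal contrast, would otherwise be emptied or halved). In
the noisy regime the method is built for — many near-diagonal noise
classes, a few contrasted structures — the widest gap separates the two
populations and the anchor is immaterial.

The selector is exposed as `threshold_config(selector = "max_gap")`, with
`"fixed"` available when a reproducible manual cutoff is wanted. It is a
heuristic with a failure mode worth knowing: on a diagram that contains
*only* noise (no contrasted structure at all), some gap is still widest,
and a few noise classes will be selected. In the data this package targets
every slice carries membrane signal, and cavity selection is anchored by
the cavity classes themselves; slices without any such signal should be
handled by the `"fixed"` selector or by masking.

## Per-slice segmentation

1. **Membrane.** The sublevel diagram is thresholded; the union of the
   selected bright regions is taken, and Γ is the external boundary of its
   largest connected component (several components trigger a warning — one
   cell profile per image is assumed; an empty selection raises a
   dedicated "no membrane found" condition). Dark holes inside the union
   are deliberately ignored at this stage.
2. **Cavities.** The superlevel diagram is restricted to classes whose
   filled representative lies inside Γ — at least 99% of its pixels
   (`inside_tol`), a tolerance for one-pixel boundary rasterization — and
   the threshold is chosen *on that subfamily's persistences alone*, so
   background clutter outside the cell never influences it.
3. **Nested cycles.** If one cavity interior contains another, the inner
   filled mask is dilated by a Euclidean disk (rasterized via the exact
   distance transform) whose radius is the directed Hausdorff distance
   from the inner curve to the outer curve, the dilation is subtracted
   from the outer interior, and the external boundary of the largest
   remaining component replaces the outer representative. The direction of
   the Hausdorff distance is a genuine design choice
   (`hausdorff_direction`): inner-to-outer is the default because that
   radius makes the dilated region just reach the outer curve, so the
   subtraction carves away the inner lobe and leaves the complementary
   lobe — the geometry a saddle split calls for. The outer-to-inner
   distance would dilate past the outer curve almost everywhere and
   degenerate. Two safeguards handle rasterization: if the carved region
   still wraps around the inner curve the dilation is retried one pixel
   larger, and if the subtraction empties the outer region entirely the
   outer curve is kept unchanged with a warning. Refinement iterates
   innermost-first until no nesting remains (bounded by n² sweeps);
   partial overlaps that are not nestings are left untouched — only the
   nested configuration arises from saddle points.

Intensities are min-max normalized per slice by default (`"stack"` and
`"none"` are available). Per-slice normalization was chosen because
acquisition intensity drifts along z in confocal stacks and the
segmentation of one slice should not depend on the brightness of another;
persistence itself is shift-invariant, so the choice only matters for
comparability of thresholds across slices.

## Surface reconstruction

Contours are lifted to physical coordinates
(`x = col * pixel_size`, `y = row * pixel_size`,
`z = (slice − 1) * axial_spacing`; defaults 0.16 and 0.3 µm). Each
membrane contour is split at its two extremal vertices along the axis
perpendicular to the configured lumen side (`lumen_direction`, default
`"up"`), the arc facing the lumen being luminal; cavity contours are never
split and count as luminal structures. The extremal-vertex rule is an
interpretation — nothing in the problem fixes the split points — but for
the roughly convex profiles of this application it is stable and
reproduces the expected split at the extreme columns for a lumen above.

Tiling between successive slices forms, for each vertex, the triangle
(vertex, successor, nearest vertex of the other contour) when the nearest
partner lies within `d_max` (default 1.0 µm ≈ three pixels at the default
lateral resolution, against a 0.3 µm axial step); the complementary pass
anchors at the successor's nearest partner so aligned contours produce a
properly split quad strip (Euler characteristic 0 for a closed tube). The
assembled mesh additionally drops any triangle whose cross-slice edge
exceeds `d_max`, so the distance contract holds for every edge, not just
the association edges. Contours are oriented counter-clockwise before
tiling; cavities are tiled only against cavities of the adjacent slice
whose projected interiors overlap by at least one pixel (the minimal
consistent matching rule — the segmentation guarantees separation, not
correspondence), and unmatched cavities end in an open rim rather than
welding onto the membrane. Slices more than `max_slice_gap` steps apart
(default 2, i.e. one failed slice may be bridged) are not tiled, splitting
the surface instead of hallucinating geometry.

Smoothing uses Taubin's λ/µ alternation with the classical stable pair
(λ, µ, iterations) = (0.5, −0.53, 10), chosen for its volume-preserving
behaviour (the stability condition µ < −λ < 0 is enforced); the tests
measure the enclosed-volume change on a closed synthetic sphere.
Remeshing is area-weighted centroidal vertex clustering: the mesh is first
refined by midpoint subdivision wherever an edge exceeds the intended
cluster spacing (clustering cannot exceed input vertex density), seeds are
spread by deterministic farthest-point sampling, Lloyd iterations relocate
them under per-vertex area weights, and triangles are re-indexed through
the clusters. Clustering runs per connected component with seats allocated
by component area, which preserves the component count. At extreme
decimation (a handful of clusters) the Lloyd iteration can settle in
symmetric fixed points, so watertightness is not guaranteed there; the
remesher is intended for moderate simplification to uniform density.

## The phantom and what passing it means

`generate_phantom_stack()` rasterizes a known 3D geometry per slice: a
bright ellipsoidal membrane band (default 96 x 96 x 16 at
0.16/0.3 µm spacing — a ~11 µm cell, sizes chosen to keep the full test
suite fast while leaving dozens of pixels across every structure), a dark
invagination channel breaching the top of the band, an axially elongated
dark cavity (a section of the luminal invagination, present in all
slices) and a bleb-like void (slices 2–15), with intensities
background 0.05 < cavity 0.10 < cytoplasm 0.65 < membrane 0.95. The
rasterization is degraded by Gaussian blur (default σ = 0.25 px: inputs
are assumed deconvolved, so only a sub-pixel residual point spread
remains, and the blur mainly antialiases the rasterized geometry),
additive Gaussian noise after the blur (default 0; the noisy test
condition uses σ = 0.05), clipping to [0, 1], and 8-bit quantization as a
camera would apply. Ground truth (membrane mask, per-cavity masks, counts,
expected 3D component count) comes from the same rasterization.

The phantom emulates the *structure* of the real data — closed bright
band, luminal opening, dark cavities of distinct contrast scales, additive
noise below the structural contrast — but not everything real stacks
contain: no anisotropic or depth-varying point spread, no Poisson photon
statistics, no intensity drift along z, no neighbouring cells or membrane
texture, and its geometry is piecewise-ellipsoidal. Passing the phantom
suite therefore demonstrates that the topological machinery, the threshold
selection and the reconstruction contracts are implemented correctly and
are robust to blur, additive noise and quantization at realistic contrast
ratios; it does not certify segmentation accuracy on arbitrary microscopy
data, where deconvolution quality and clutter dominate.

## Known limitations

* One cell profile per slice is assumed; multi-cell instance segmentation
  is out of scope.
* The gap-based threshold can select noise classes on slices with no
  contrasted structure (see above).
* Open rims are left open: no hole-capping or watertighting is attempted.
* Cavity correspondence across slices is overlap-based; cavities that
  drift laterally by more than their radius between slices will not be
  matched.
* The basal/luminal split assumes a roughly convex profile with a
  configured lumen side; strongly folded profiles may need a different
  split rule.
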