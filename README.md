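# persiseg

Topology-based segmentation and 3D reconstruction of confocal z-stacks.

`persiseg` segments cell membranes and their internal cavities in confocal
volumes — the setting it targets is live imaging of endothelial cells
undergoing the endothelial-to-hematopoietic transition (EHT) in the
zebrafish dorsal aorta, where the luminal membrane folds into deep
invaginations and the cytoplasm contains dark voids, and where no annotated
ground truth exists to train a learning-based segmenter. Instead of tuning
intensity thresholds per image, the package reads the topology of the
intensity function itself.

## Method

Each slice `u : {1..H} x {1..W} -> [0,1]` is turned into a cubical complex
(pixels are vertices; each edge and square carries the maximum of its
pixels) and filtered two ways:

* **Sublevel filtration** `K_t = {u <= t}`, `t` ascending. Holes of `K_t`
  (classes of H1, counted by the Betti number β1) are bright shapes on a
  darker surround; the cell profile is the most persistent one.
* **Superlevel filtration** `{u >= t}`, `t` descending. Holes are now dark
  blobs enclosed by brighter surroundings — the internal cavities.

Every H1 class is a point `(birth, death)` of the persistence diagram with
persistence `|death − birth|`, the intensity contrast of the structure. A
threshold `t*` is chosen automatically as the midpoint of the widest gap in
the sorted persistence values (with the diagram diagonal as lower anchor),
and the classes with persistence `> t*` are kept. Each kept class is
represented by the external boundary of its level-set region (the
8-connected component of the strict level set at the class's birth value
containing its critical pixel), traced as a closed curve on the
pixel-corner lattice.

The membrane profile Γ is the external boundary of the union of the
selected bright regions; cavities are the selected superlevel classes whose
region lies inside Γ. Nested representatives produced by saddle points are
separated by a splitting rule: the inner filled mask is dilated by a
Euclidean disk whose radius is the directed Hausdorff distance from the
inner to the outer curve, subtracted from the outer interior, and the
remainder's external boundary becomes the new outer representative,
iterated until all cavity interiors are pairwise disjoint.

For 3D reconstruction, each membrane contour is split into luminal and
basal arcs at its extremal vertices perpendicular to the configured lumen
direction, and successive contours of the same role are tiled: each vertex
forms a triangle with its successor and the nearest vertex of the next
contour, provided that partner lies within `d_max` (default 1 µm, about
three pixels). Vertices with no admissible partner leave open rims, which
is what keeps a cavity rim from welding onto the membrane sheet. The tiled
surface is smoothed with Taubin's λ/µ method (volume-preserving) and
optionally remeshed to uniform vertex density by area-weighted centroidal
vertex clustering.

A synthetic phantom generator produces z-stacks with exact ground truth
(ellipsoidal membrane band, invagination channel, cavity ellipsoids,
blur + noise + quantization), so the whole pipeline is testable without
microscope data.

## Worked example

```r
library(persiseg)

## two bright hills joined by a saddle: the H1 diagram of the ascending
## filtration has an elder class and a class born at the saddle value 0.3
img <- generate_toy_image("saddle_dumbbell")
sublevel_h1_diagram(img)$pairs
#>   birth death persistence crit_row crit_col
#> 1  0.05  0.75        0.70       12        5
#> 2  0.30  0.57        0.27       12       25
optimal_threshold(c(0.70, 0.27))
#> [1] 0.485

## default phantom: membrane band + invagination + two cavities
ph <- generate_phantom_stack()
seg <- segment_slice(intensity_image(ph$stack[[8]]$values), slice_index = 8)
seg
#> <slice_segmentation> slice 8: membrane 3774 px, 2 cavities
iou_score(seg$membrane$interior, ph$truth$membrane_masks[[8]])
#> [1] 1

## full pipeline: per-slice segmentation, tiling, Taubin smoothing
res <- run_pipeline(pipeline_config(lapply(ph$stack, `[[`, "values"),
                                    out_dir = "out", verbose = FALSE))
res$mesh
#> <triangle_mesh> 6244 vertices, 11676 triangles, 4 component(s)
res$audit
#> $max_interslice_edge 0.516  $d_max_ok TRUE  $welding_ok TRUE  $components 4
```

The first block shows the elder-rule bookkeeping: when the saddle at 0.3
splits the figure-eight region, only one new class is born (persistence
0.27) while the elder class keeps its representative. The phantom slice is
recovered exactly (IoU 1 against the rasterized truth), and the
reconstructed surface has four connected components — luminal sheet, basal
sheet, and one closed surface per cavity — with every cross-slice edge
within the 1 µm association bound.

A thin command-line driver wraps the same functions:

```sh
exec/persiseg phantom --out ph --noise 0.03 --seed 2
exec/persiseg segment ph/stack.tif --out seg
exec/persiseg eval --pred seg --truth ph/truth_membrane.tif
#> mean IoU: 0.9280 over 16 slices
```

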