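---
title: "Automated pulmonary air and tissue segmentation: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Automated pulmonary air and tissue segmentation: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

Quantifying lung disease in mouse microCT means separating three
compartments in a reconstructed grayscale volume: air outside the animal,
aerated lung (air inside the chest), and intra-lung tissue — vessels plus
dense or diseased tissue. Manual region-of-interest (ROI) drawing is slow
(an hour per animal for an experienced reader) and carries strong
inter-reader variability; inflammation and fibrosis blur the boundary
between lung tissue, heart, and chest wall, which is precisely where
readers disagree. `patsr` implements the pulmonary air and tissue
segmentation (PATS) protocol as an ordered task list of elementary,
fully specified image operations, so the same segmentation runs
identically on any machine, plus the 3D morphometry used to report it.

# The protocol

The task list operates a small state machine: the immutable grayscale
*image*, the current *ROI*, and the current binary *selection*. The
canonical in vivo sequence (`pats_task_list()`, 20 operational steps) is:

1. **Body threshold** 55–255: selects everything denser than air.
2. **Shrink-wrap** (diameter 4 px): fits the ROI to the body's outer
   contour, bridging surface openings up to 4 px, so the ROI becomes the
   solid body cross-section, lungs included.
3. **Reload + air threshold** 0–55 inside the body ROI; the ROI becomes
   *air within the body*.
4. **Sweep despeckle** (3D, keep largest object): the aerated lung —
   a single 26-connected component once the airways join the two lungs —
   survives; stomach gas or stray air pockets do not. This ROI is saved,
   analyzed (volumes) and meshed.
5. **Per-slice round closing, radius 40 px**: vessels and lesions are
   holes and bays in the aerated ROI; closing fills them, producing the
   anatomical lung envelope.
6. **Reload + tissue threshold** 55–255 inside the closed envelope, then
   one **per-slice round erosion of radius 1** on the tissue selection.
   The erosion peels the one-pixel rind where the envelope overlaps chest
   wall and mediastinum; inevitably it also thins genuine intra-lung
   tissue (the protocol accepts this trade and the package logs it).
   The result is the vessels-and-dense-tissue ROI: saved, analyzed
   (volumes, structure thickness, structure linear density) and meshed.

The ex vivo list (`ex_vivo_task_list()`) is the converse situation —
dried, fixed lungs are tissue-bright on an air background — so it is
simply threshold, keep-largest, analyze, mesh.

Both printed threshold ranges include intensity 55. A voxel of exactly 55
can therefore satisfy the air *and* the tissue range; `pats_segment()`
resolves the conflict by removing such voxels from the tissue ROI and
logging how many were affected (ordinarily zero to a handful of
noise-boundary voxels).

## Parameters

| Parameter | Default | Units | Meaning |
|---|---|---|---|
| `body_threshold` | (55, 255) | 8-bit intensity | body/tissue density range |
| `air_threshold` | (0, 55) | 8-bit intensity | air density range |
| `shrinkwrap_diameter` | 4 | px | widest body-surface opening bridged by the wrap |
| `closing_radius` | 40 | px | per-slice round closing that rebuilds the lung envelope; 1.4 mm at 35 µm voxels, chosen to exceed the largest vessel/lesion diameter while staying below the inter-lung distance |
| `erosion_radius` | 1 | px | per-slice peel of peripheral tissue |
| `enable_optional_despeckle` | off | — | second sweep for datasets where less-dense body tissue leaks into the ROI |
| `enable_manual_roi_export` | off | — | export hook for manual correction of the envelope in severe disease |
| `manual_pre_roi` | none | — | rough manual pre-selection applied before step 1 (the documented fallback when hyperattenuation merges lung with chest wall) |

Thresholds are always in native image units. 16-bit volumes are accepted
but thresholds are **not** rescaled automatically — a warning reminds the
user — because silent rescaling is unreproducible. The defaults assume
8-bit reconstructions, the only bit depth consistent with 0–255 protocol
thresholds.

# Operator semantics (frozen contracts)

Vendor implementations of these operators are proprietary; `patsr`
freezes explicit contracts instead and tests against independent oracles
(igraph BFS labeling, `rle()` run counting, brute-force sphere
enumeration, truth tables):

* **Threshold** is inclusive at both ends.
* **Connectivity** is 26 for 3D foreground (8 in 2D), with the
  complementary 6/4 for background, avoiding the classic topological
  paradoxes in hole filling.
* **Despeckle sweep ties** keep the component whose minimal `(z, y, x)`
  voxel is lexicographically smallest — deterministic and
  order-independent. `space = "2D"` processes each slice on its own.
* **Round structuring elements** are the exact Euclidean set
  `{offsets: |offset| <= radius}`, realized through an exact squared
  Euclidean distance transform, so a radius-40 closing is not an
  octagonal approximation.
* **Border padding** is background for dilation and foreground for
  erosion. Closing therefore never trims foreground at the volume border,
  and `closing(A)` is *identically* `erosion(dilation(A))` — a property
  the test suite asserts on random masks. The flip side: an object lying
  within `radius` pixels of the border is treated as continuing beyond
  it, so closing can connect it to the border. Real scans center the
  animal with generous margins; the phantom generator keeps its lungs at
  least `radius + 1` pixels from the lateral borders for the same reason.
* **Shrink-wrap** is defined constructively per slice: close the
  foreground with a round element of radius `ceiling(diameter/2)`,
  flood-fill the background from the slice border (4-connectivity), take
  the complement, and intersect with the hole-filled dilation of the
  original foreground (the wrap may not extend outward beyond the
  bridging radius, while enclosed cavities remain eligible). A convex
  solid wraps to itself; a C-shaped cavity is included exactly when its
  opening is no wider than `diameter`.

# Morphometry

**Volumes.** TV is the ROI (VOI) volume, BV the foreground volume inside
it, both as voxel count x voxel volume. In the pipeline the tissue ROI
*is* the analyzed object (the protocol sets ROI = tissue before
analysis), so its TV equals the reported lung tissue volume.

**Structure thickness (St.Th).** The largest-inscribed-sphere definition:
the thickness at a voxel is the diameter of the largest sphere fully
inside the foreground that covers it, computed by exact Euclidean
distance transform plus distance-ridge sphere painting (the ridge
reduction is exact: a sphere contained in a neighbor's sphere
contributes nothing). Diameters are measured between voxel boundary
faces (`2*EDT - 1` voxels), so an isolated voxel reports 1 voxel and a
10-voxel slab reports 9 — within the one-voxel discretization band, and
exactly matching a brute-force enumeration oracle on small masks. Volume
beyond the image border counts as foreground, so slabs spanning the
field of view are not artificially thinned at their open ends. The mean
is volume-weighted (every foreground voxel contributes equally).

**Structure linear density (St.Li.Dn).** The directed-secant
implementation of "number of structures that cross a vector": for each
principal axis every axis-parallel voxel row is a test line; maximal
consecutive foreground stretches inside the VOI are runs. Lines crossing
no structure are excluded; the axis value is total runs divided by the
total VOI length of counted lines (1/mm), and the scalar is the mean of
the three axes. Under this rule a slab stack of period 20 mm yields
exactly 0.05/mm along its normal and 1/L in-plane, and a solid cube
yields 1/L on every axis. Because the vendor formula is unpublished, the
plate-model alternative `(BV/TV) / St.Th` is computed and reported
side-by-side in every CSV; neither is claimed to match vendor output
numerically.

One stereological subtlety, visible in the phantom experiments: adding
the *first* sparse lesions to a vessel-only tissue ROI can raise
St.Li.Dn, because isolated new structures add secant crossings. Only as
lesions grow and coalesce does the mean intercept length rise and the
density fall below baseline — which is the regime the in vivo
observations describe. The acceptance suite asserts monotone decrease
across the coalescing fractions and that diseased lungs sit below the
lesion-free baseline.

**Surface models.** `surface_mesh()` extracts the iso-0.5 surface of a
binary mask with marching tetrahedra over the Kuhn 6-tetrahedron lattice
decomposition. The Kuhn decomposition tiles space with matching face
diagonals, so the extracted surface is *guaranteed* closed and manifold —
the property the classic 256-case cube tables only achieve with
disambiguation ("marching cubes 33"-class variants); the tetrahedral
route achieves it by construction. Vertices sit at crossing-edge
midpoints in physical mm; triangles are wound outward (right-hand rule),
and meshes export to binary or ASCII STL. Enclosed volume (divergence
theorem) converges to the voxel volume as structures grow (relative
error well under 5% for a radius-20 sphere, shrinking with radius); the
one systematic bias is at the smallest scale — a single voxel encloses
0.5 voxel volume, since any midpoint scheme cuts its corners.

# The phantom generator

`generate_thorax_phantom()` is the package's study-condition stand-in
for a mouse chest scanned at the 35 µm class: a 200 x 256 x 256 volume
(~7 x 9 x 9 mm) containing an ellipsoidal soft-tissue body (intensity
120) in air (20), two lung fields of parenchyma (35), a bifurcating
vessel tree per lung (130), optional spherical lesions (110), a medial
heart (125), and additive Gaussian noise (sd 6, clamped to [0, 255]).
Intensities sit >= 15 units clear of the 55 threshold on both sides so
that validation exercises the pipeline, not threshold luck; a "hard
mode" is available simply by narrowing the margins in `phantom_spec()`.

Design choices worth knowing:

* **Airways.** The two lung air fields are joined by a single short
  bronchial bridge across the mediastinum rather than a full trachea.
  The protocol's sweep step keeps the *largest connected* air component,
  so the phantom must present the lungs as one object, as real airways
  do; but any long mediastinal air path would make the per-slice closing
  pocket mediastinal tissue into the lung envelope far beyond what the
  radius-1 erosion can trim. The compact bridge keeps that capture to a
  few thousand voxels — the same qualitative artifact real scans show at
  the hila, at realistic magnitude.
* **Vessels.** Root radius 14 px (~0.5 mm, proximal pulmonary artery
  scale), tapering by 0.78 over four generations, floored at 3 px, and
  confined to the inner 88% of each lung field: calibres below ~0.1 mm
  are unresolvable at this voxel size and subpleural microvasculature is
  invisible to the scan, so neither belongs in the ground truth.
* **Lesions.** Spheres of 8–18 px radius placed fully inside a lung
  until their net volume (excluding vessels and airways) reaches the
  requested fraction of the lung-field volume; the final sphere is
  resized to land on the target. One seeded RNG stream with documented
  placement order (left tree, right tree, lesions) makes generation
  bit-reproducible, and the lesion sequence for a larger fraction
  extends the one for a smaller fraction, so phantom disease series are
  monotone by construction.
* **Geometry margins.** Lungs keep >= 41 px to the lateral volume
  borders (see the border contract above) and >= 80 px between their
  medial surfaces so the radius-40 closing cannot bridge the mediastinum
  and swallow the heart.

What the phantom does *not* emulate: partial-volume blur at tissue
interfaces, beam hardening, ring and motion artifacts, anatomical lobe
structure, or a diaphragm. Passing its tests demonstrates that the
operator chain implements the protocol's set-level semantics correctly
under realistic contrast and noise — not that segmentation of real,
artifact-laden scans achieves the same overlap scores.

# Problem sizes and numerical choices in the test suite

The unit suite runs reduced-scale phantoms (80 x 128 x 128 and
60 x 96 x 96, with the closing radius scaled to 20 and 15 px to match
the halved geometry). The acceptance suite runs the full default
conditions: 200 x 256 x 256, noise sd 6, protocol defaults, plus the
analytic calibration phantoms (sphere r = 25 for volume, 10-voxel slab
for thickness, 5 + 15 slab stack for linear density, spheres
r = 10/20/40 for mesh convergence) and a 128^3 dried-lung phantom for
the ex vivo path. Oracle comparisons use 100 random 20^3 masks
(labeling) and 100 random 32^2 slices (closing composition). These sizes
were chosen so the entire validation reflects the study-scale geometry
while each suite completes in minutes on a single core.

Degenerate inputs are contracts, not surprises: empty masks error in
sweep despeckle ("no objects"), thickness and meshing reject empty and
volume-filling masks, uniform volumes abort segmentation with
"segmentation failed: no lung air" (CLI exit code 2), and two empty
masks compare with Dice 1 (identical emptiness, logged).

# Known limitations

* Bit-compatibility with vendor software is not claimed anywhere; the
  contracts above are this package's definitions.
* The radius-1 erosion removes a calibre-dependent fraction of thin
  vessels (about a one-pixel shell); tissue volumes are accordingly
  conservative, exactly as the protocol's own caveat warns.
* St.Li.Dn values depend on the VOI convention (lines through the tissue
  ROI itself in the pipeline; the full grid in the ex vivo path); compare
  like with like across studies.
* 16-bit support is mechanical (I/O and thresholds in native units); the
  shipped defaults are meaningful for 8-bit reconstructions only.
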