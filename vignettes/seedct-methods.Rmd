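---
title: "Measuring seed morphological structure from micro-CT volumes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring seed morphological structure from micro-CT volumes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The measurement problem

X-ray micro-CT resolves the internal anatomy of a cotton seed
non-destructively: the dense seed coat (testa) and the embryo ("kernel":
cotyledons, radicle and hypocotyl treated as one structure) absorb
strongly and appear bright, while the gas-filled cavity between kernel
and coat is dark. From a reconstructed voxel volume, `seedct` extracts
for each seed eleven morphological traits — length, width, thickness
(Feret dimensions), seed / kernel / coat / cavity volumes, seed and
kernel surface areas, average coat thickness, and seed fullness (kernel
volume over seed volume) — plus three derived evaluation indices:

* **coat specific surface area** = seed (coat) surface area / coat
  volume, in mm^-1^ — exposure of the coat per unit of coat tissue;
* **coat thickness ratio** = average coat thickness / seed thickness —
  the coat's relative thickness, robust to seed size;
* **seed density ratio** = cavity volume / kernel volume — smaller
  means a denser, more compact seed.

Scanners deliver slice stacks (TIFF/PNG) with an isotropic voxel pitch
of roughly 13 µm, usually block-mean downsampled by 3 before analysis
(`downsample()`), giving an effective pitch near 0.04 mm.

# Processing chain

1. **Binarisation and hole filling** (`binarize_fill`): a global Otsu
   threshold on the 256-bin histogram, removal of connected specks below
   `min_size_vox` (default 1000), then 3D hole filling
   (background components not 6-connected to the border become
   foreground), so each seed becomes one solid object.
2. **Instance segmentation** (`split_instances`): Euclidean distance
   transform of the solid mask; markers at distance maxima separated by
   at least 2 mm (about half the smallest seed width); marker-based
   watershed by priority flood, 6-connected. Undersized fragments merge
   into the adjacent label with the largest contact. Everything is
   deterministic: ties resolve by voxel index.
3. **Per-seed surface refinement and extraction**: the global threshold
   of step 1 sits slightly off the centre of the surface partial-volume
   ramp when background dominates the histogram, so each seed's surface
   is re-centred against the midpoint of its local background and coat
   plateau levels (`refine_seed_mask`), mirroring the per-seed histogram
   analysis of the underlying protocol; the instance mask is then ANDed
   with the image (`extract_instance`).
4. **Component segmentation** (`segment_components`): per-seed
   gray-level histogram analysis. An Otsu split of the in-mask
   intensities lands either between cavity and tissue or between kernel
   and coat (depending on cavity size); both interpretations are
   pursued, every class boundary is re-centred on the midpoint of
   raw-intensity plateau medians (a mode-robust Ridler–Calvard
   iteration; plateau levels for the kernel/coat cut come from
   depth-resolved bands so that coats only a few voxels thick are
   handled), and the kernel is the largest component of its class that
   stays clear of the 2-voxel boundary shell after a radius-1 opening.
   Kernel and coat cannot be separated by their intensity *alone* —
   both are bright — so geometry (interior vs. surface-connected) breaks
   the tie, and when no intensity contrast exists at all the kernel must
   be isolated by the cavity gap. The shell (seed minus kernel) is split
   into bright coat and dark cavity the same way; dark rims confined to
   the outermost voxel layers are partial-volume artefacts and return to
   the coat, while dark components reaching deeper are genuine cavity.
5. **Damage flags** (`flag_damage`): a cavity adjacent to the seed
   exterior, or an open channel revealed by morphological closing,
   flags `coat_breach`; a kernel with more than one large component
   flags `fragmented_kernel`. Flagged seeds are excluded from statistics
   — when the cavity communicates with outside air its grayscale no
   longer separates, and quantification would be unreliable.
6. **Traits** (`compute_traits`): volumes are voxel counts times the
   voxel volume; surface areas and Feret dimensions come from
   marching-tetrahedra isosurfaces; coat thickness from maximal
   inscribed spheres; fullness is the kernel/seed volume ratio.
7. **Statistics** (`describe`, `pearson_matrix`, `zscore`,
   `ward_cluster`, `group_compare`, `trend_fit`, `agreement`): the
   population-level workflow — descriptive table, correlation matrix
   with significance stars, z-scoring, Ward clustering on squared
   Euclidean distances, one-way ANOVA with LSD (normal data, per-group
   Shapiro-Wilk at 0.05) or Bonferroni (non-normal) pairwise letters,
   least-squares trend fits, and CT-vs-manual agreement (R²).

```{r example}
library(seedct)
specs <- sample_specs(default_population(), 3, rng_seed = 1)
scene <- make_scene(specs, spacing_mm = 0.06, rng_seed = 2)
mask <- binarize_fill(scene$volume)
inst <- split_instances(mask)
ex <- extract_instance(scene$volume, inst, 1)
comp <- segment_components(ex$volume, ex$mask)
compute_indices(compute_traits(comp))
```

# The phantom generator

No public scan data accompany the protocol, so validation rests on a
synthetic seed phantom with exact ground truth (`seed_spec`,
`make_seed`, `make_scene`). The generator is the package's definition of
the study conditions, not a tuning knob.

**Shape.** The outer surface is a blunt-poled, waisted solid of
extension: cross-sections perpendicular to the long axis are ellipses
whose radius follows `g(t) = sqrt(1 - t^2) (1 - pinch t^2)
(1 - taper (1 + t) / 2)` along the normalised axis position `t`. `pinch`
slims the body away from its widest cross-section — which decouples the
enclosed volume from the L × W × T box so that the default population's
mean volume matches its target of 100.34 mm³ (`pinch = 0.643`, solved
once from the analytic volume integral) — and `taper` (default 0.12)
gives the teardrop asymmetry toward the micropylar pole. A linear taper
alone cannot achieve the volume decoupling: with semi-axes re-derived
from the drawn L/W/T, taper shrinks volume and the widest cross-section
together, and their ratio stays essentially fixed. Poles are kept blunt
(square-root profile) deliberately: needle-like tips would be lost to
partial volume at scan resolution and bias the measured length.

**Interior.** The coat is the shell of constant inward normal depth
`coat_thickness_mm` (first-order signed distance `phi / |grad phi|`,
sub-voxel accurate at seed scale); the cavity is a spherical cap between
kernel and coat centred on the innermost-surface point along
`cavity_pole`, with its radius bisected until the voxel-counted
kernel/seed ratio hits the target fullness within 0.005
(`calibrate_cavity`); the kernel is the remainder. The three binary
masks partition the seed exactly, by construction.

**Grayscale.** Voxel intensity is the occupancy-weighted mix of the
phase intensities with additive Gaussian noise. The defaults (background
0.08, cavity 0.22, kernel 0.72, coat 0.88, noise SD 0.04) are chosen for
plausibility: both tissues are bright, with the dense palisade coat
slightly brighter than the embryo. The source protocol reports no
intensity statistics — only that coat and kernel are both high — so the
kernel/coat contrast is a modelling choice; it is what makes a
threshold-only path viable where the original work used a learned
segmenter for the kernel. Partial-volume edges come from a one-voxel
linear occupancy ramp. Surface texture, lint fibres and beam-hardening
are deliberately not modelled, so passing phantom tests demonstrates
correct geometry and measurement, not robustness to every real-scan
artefact.

**Population.** `sample_specs()` draws length, width, thickness, coat
thickness and fullness from truncated normal distributions
(`default_population()`: means 9.22 / 5.40 / 4.86 / 0.16 mm and 0.54,
SDs 0.70 / 0.50 / 0.41 / 0.02 mm and 0.06, with their admissible
ranges). Width and thickness are drawn jointly with correlation 0.8 and
re-drawn until L ≥ W ≥ T: in real seed populations the two transverse
dimensions co-vary strongly, and fully independent draws would violate
the generating shape's own axis ordering for about a fifth of the seeds,
making the nominal "width" unrecoverable by any measurement. All
randomness funnels through one integer seed; repeated calls are
identical.

# Numerical choices

* **Isosurfaces** use marching tetrahedra (six tetrahedra per cell
  around the main diagonal, shared vertices hashed on grid edges):
  the same linear-interpolation surface as table-based marching cubes,
  with no ambiguous cases and watertight output. Input fields are first
  smoothed with a one-voxel box filter: an occupancy ramp confined to a
  single voxel kinks the interpolant and crumples the surface (about +5%
  area on spheres); widening the ramp removes the artefact without
  moving the level set. Binary masks pass through the same filter, which
  doubles as their sub-voxel surface estimate. Sphere area and volume
  are then within 2% of closed forms at scan resolution (tested).
* **Feret dimensions**: length is the exact farthest vertex pair (seeded
  by extremes over 128 quasi-uniform directions, refined by alternating
  farthest-point steps); width is the planar diameter of the projection
  onto the orthogonal plane, computed on its convex hull; thickness is
  the extent along the third axis.
* **Average coat thickness** is Hildebrand-style local thickness: each
  coat voxel takes the diameter of the largest inscribed sphere covering
  it, and values are averaged over the coat. Sphere radii are distance
  transform values minus half a voxel (centre-to-boundary offset), and
  an additive correction of 0.42 voxel compensates the loss from
  sampling sphere centres on the grid; the correction was calibrated
  once against constant-thickness analytic shells (slabs, spheres and
  seed-shaped shells spanning 2–6 voxel thickness) and is validated in
  the test suite (a 0.16 mm spherical shell is recovered within
  0.01 mm at 0.04 mm pitch). One quantisation effect remains visible on
  perfectly axis-aligned slabs: when the digitised thickness is an even
  number of voxels the medial plane falls between voxel centres and the
  estimate carries an extra penalty of about a tenth of a voxel beyond
  the half-voxel bound that odd counts satisfy; curved, arbitrarily
  oriented shells — the actual use case — average over these phases.
  Masks from noisy segmentations are first
  regularised with a 3-voxel majority filter. A cheap cross-check
  estimator, 2 V / (A_outer + A_inner), is provided as
  `coat_thickness_from_areas`.
* **Thresholds**: `otsu_threshold` maximises the between-class variance
  over the 256-bin histogram, ties broken toward the smaller threshold,
  and matches an exhaustive oracle on a thousand random histograms
  (tested). Where a threshold defines a *surface* whose sub-voxel
  position matters, the Otsu cut is re-centred on the midpoint of the
  raw-intensity class medians; plateau medians resist the partial-volume
  tails that drag class means.
* **Ward clustering** uses the classic SSE-increase criterion (merge
  heights are reported as the SSE increase itself), implemented on
  squared Euclidean distances via `stats::hclust(method = "ward.D")`;
  an O(n³) brute-force re-computation serves as the oracle in tests.
  The squared-distance + `ward.D` combination is the criterion commonly
  described as Ward's method with squared Euclidean distance (the
  `ward.D2` variant squares distances internally and is not used).
  Average coat thickness is excluded from clustering by the calling
  workflow, which standardises the remaining ten indicators.
* **Degenerate inputs** are first-class: single-voxel masks mesh to a
  small watertight surface; cavity-free seeds yield an empty cavity
  mask; contrast-free volumes raise "kernel not found" rather than
  returning a noise split; constant columns are rejected by `zscore`
  and reported as missing by correlation.

# The learned segmentation path

The package also provides a trainable kernel segmenter behind the same
contract as the threshold path. The patch geometry follows the tiled
volumetric protocol — 32 × 128 × 128 patches, inference stride
(24, 96, 96) with boundary clamping, overlapping probabilities averaged
and thresholded at 0.5, Dice/IoU reporting, 8:2 train/test splits — see
`net_spec()`, `sample_patches()`, `infer_sliding()`, `dice_iou()`. The
model itself is a voxel-wise single-hidden-layer perceptron (`nnet`)
over multi-scale local intensity features (raw value, box means at radii
1/2/4, local SD): with the phantom's kernel/coat contrast this trains in
seconds on a CPU and reaches Dice above 0.95 on held-out phantom seeds
(tested). It is an optional alternative — the default path, and the one
used for all acceptance checks, is the deterministic threshold chain.
Training uses only synthetic data; no scan imagery ships with the
package.

# Problem sizes and design limits

The validation suite uses phantom populations at 0.05 mm voxel pitch
(102 seeds for parameter recovery — about 3.4 million voxels per seed —
and 20 seeds for segmentation quality), scenes at 0.06–0.08 mm, and
small 2–4 mm seeds for unit tests; these sizes keep the full suite
reproducible on a single CPU while leaving every trait at least two
voxels of resolution in its thinnest structure (the generator refuses
coats under two voxels as under-resolved). At 0.05 mm the half-voxel
term in the coat-thickness tolerance is 0.025 mm.

Known limitations: seeds touching the volume border are not handled;
the inner/outer coat sub-layers are not separated (the underlying study
could not segment them either); atypical cavity types (inside the
kernel, under endosperm remnants) are outside the generator's scope and
surface only through damage flags; and the phantom's smooth surface
makes measured surface areas systematically cleaner than real, wrinkled
seed coats — areas recover the phantom truth within a few percent, but
absolute areas of real seeds will depend on resolution in a way no
smooth phantom can capture.
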