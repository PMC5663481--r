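---
title: "Detection, description and classification of plankton in 3D confocal mosaics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detection, description and classification of plankton in 3D confocal mosaics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hcfm)
```

## The problem

High-content confocal imaging of preserved seawater samples produces, per
sample, hundreds of multi-channel Z-stacks arranged in an overlapping
rectangular mosaic. Each position records a bright-field channel and four
fluorescence channels: DNA/nuclei, intracellular membranes, cell
surfaces/covers, and chlorophyll autofluorescence. The organisms of
interest are environmental microbial eukaryotes in the 5–20 µm range —
far too many objects, across far too much morphological diversity, for
manual annotation. The package automates the chain from raw stacks to an
object registry, a fixed descriptor catalog, hierarchical classifications
and ecological summaries, and ships a ground-truthed scene generator so
the whole chain is testable without microscope data.

## Acquisition model and configuration

`acquisition_config()` captures the geometry the pipeline assumes:

* lateral voxel size 0.188 µm, axial step 1.090 µm (anisotropy ≈ 5.8×);
* square frames of 2048 px (385.62 µm field width);
* mosaic overlap fraction 0.10 in both axes;
* five channels, exactly one of them bright field, which is never
  thresholded for masks (`use_for_masking = FALSE`) but contributes
  intensity/texture descriptors.

All of these are explicit parameters; the tests use smaller frames with
the same voxel size. Axes are ordered (x, y, z) with x fastest-varying;
pixel coordinates are 0-based and regions half-open, so mosaic arithmetic
has no off-by-one ambiguity. Intensities stay stored integers (8- or
16-bit input) until feature computation, which makes thresholds bit-exact
and lets an 8-bit and a ×257-scaled 16-bit acquisition of the same scene
produce identical masks.

## Detection

**Background.** Per fluorescence channel, the mean and *population*
standard deviation of all voxels of all fields of the sample give the
threshold `max(µ + 1.5σ, 1)`. Population rather than sample SD is an
arbitrary but fixed choice; at ≥ 10⁶ voxels per channel the difference is
far below the intensity quantization. Estimation is global per sample —
one pass over all fields before any per-field work — so that per-field
processing is independent and parallelizable afterwards, and so that dim
fields do not get per-field thresholds dragged down onto noise.

**Almost-max projection.** Columns are reduced to their second-highest
value. Compared with a max projection this ignores any single-voxel
outlier (hot pixels, cosmic events, detector spikes) at the cost of
slightly dimming structures genuinely one optical section thick; with a
1.09 µm step, organelles of interest span at least two sections. Ties are
kept: two equal maxima project to that value. A single-plane stack is
rejected rather than silently degraded.

**Masks and labeling.** The projection is 3×3 median filtered (the
smallest standard window; it preserves 5 µm-scale structure while
removing isolated pixels; edges by reflection) and thresholded strictly
(`>`). Channel masks are OR-combined; one opening then one closing with
the 4-connected 3×3 cross; hole closing fills background regions not
4-connected to the frame border; components are labeled 4-connected,
matching the structuring element. Objects with projected area < 12.6 µm²
(strict) are removed — at 0.188 µm pixels the boundary falls between 356
pixels (12.581 µm², removed) and 357 pixels (12.617 µm², kept) — as is
any object with a pixel in row/column 0 or N−1. The printed cutoff
12.6 µm² is adopted verbatim even though it does not equal the area of a
5 µm-diameter circle (19.6 µm²); the constant, not the gloss, is the
contract.

The Otsu variant (`otsu_thresholds()`) exists only as a comparison
detector: on low-contrast scenes over a heavy-tailed background a global
Otsu threshold settles in the gap between the speckle mode and the noise
floor and misses dim particles that mean + 1.5σ keeps; the packaged
`dim_field` scene is constructed to exhibit exactly this regime and the
acceptance suite asserts the direction of the difference.

## Mosaic deduplication

Fields overlap by `0.10 × field_width` (38.562 µm at full frames), so an
object can be detected in up to four fields. Detections are mapped to
global µm coordinates (`to_global()` adds the field origin
`(row, col) × spacing`, `spacing = field_width × 0.9`). Each field's
*core* is its rectangle shrunk by half the overlap width on every edge
shared with a neighbor; outer edges are not shrunk, so the cores tile the
mosaic exactly. An object belongs to the field whose core contains its
centroid; a centroid exactly on a core boundary goes to the smaller
(row, col) — implemented as "count midlines strictly below the
coordinate", which realizes the tie-break deterministically in floating
point. Any object fully visible in some field (diameter below the overlap
width) has its centroid in exactly one core; each physical object
therefore enters the registry once, and `dedup_counts()` renumbers
objects sequentially in (row, col, label) order, making every downstream
output independent of field processing order.

Objects wider than the overlap band are truncated in *every* field,
removed everywhere by the border filter, and systematically missed. This
is a known limitation of geometry-only deduplication, not corrected here;
no image-content registration between fields is attempted.

## Sub-segmentation and the 480-descriptor catalog

Inside each object's bounding-box crop (masked to the object footprint),
each fluorescence channel is 3×3×3 median filtered and thresholded at the
*same global channel threshold* used for detection. Re-estimating a
threshold on the mostly-foreground crop would be biased upward, so
"the same thresholding procedure in 3D" is read as the same threshold
values; this reading is a declared choice. Components are labeled with
6-connectivity and dropped below 0.5 µm³ (strict); at the default voxel
volume (0.03852 µm³) the boundary falls between 12 voxels (0.462 µm³)
and 13 voxels (0.501 µm³).

`feature_catalog()` freezes a versioned catalog of exactly 480 named
descriptors:

| group | per | count |
|---|---|---|
| Haralick (13 statistics × direction mean/range; distance 1, 4 directions, 64 min–max gray levels) | channel | 26 × 5 |
| uniform LBP histograms (radius 1 / 8 points → 10 bins; radius 2 / 12 points → 14 bins) | channel | 24 × 5 |
| Zernike magnitudes to degree 8, over the disk circumscribing the mask | channel | 25 × 5 |
| intensity statistics (min, max, mean, SD, median, MAD, integrated, skewness, kurtosis, fraction above threshold) | channel | 10 × 5 |
| 2D morphology of the combined mask (area, chain perimeter, convex area, solidity, axes, Feret diameters, Euler/holes, Hu 1–4, …) | object | 20 |
| 3D biovolume (total above-threshold volume, sub-object count/total/max/mean volume) | fluorescence channel | 5 × 4 |
| overlap (Jaccard and smaller-fraction overlap of 3D masks) | channel pair | 2 × 6 |
| 3D bounding-box extents (µm) | object | 3 |

Numerical conventions, all fixed for reproducibility: Haralick
co-occurrence is symmetric and counts only pixel pairs inside the mask,
quantized to 64 levels between the object's min and max (making the group
invariant to affine intensity changes); LBP compares bilinear samples to
the center with a relative 10⁻⁹ tolerance (bilinear weights only sum to 1
up to rounding); Zernike moments are computed on the masked intensity
normalized to unit total, hence invariant to positive intensity scaling
and to rotation; the 2D perimeter is the boundary chain length through
boundary-pixel centers (axis step 1, diagonal √2), with an exposed-edge
fallback for sub-3-pixel masks; convex pixel area uses Pick's theorem on
the hull of pixel centers; second moments add the 1/12 pixel-variance
term. Every degenerate case (one-pixel masks, zero-variance intensities,
empty channels) yields 0, never NA/NaN — classifiers require finite
inputs. Each catalog entry carries a documented `scale_behavior`
(`invariant`, `linear`, or `threshold`-dependent), and the tests verify
the declared behavior entry by entry.

## Classification

Curation keeps leaf categories with **more than 30** specimens, without
any class reweighting. The classifier is a seeded 500-tree probability
random forest (`ranger`), `⌊√p⌋` candidate features per split, unlimited
depth, bootstrap resampling. Objects are assigned to the most probable
leaf (ties to the lowest class index) with confidence = highest −
second-highest probability; a single-class degenerate model has
confidence 1 by the convention that the second-highest of a length-1
probability vector is 0.

Accuracy is estimated by stratified 10-fold cross-validation (the
estimation protocol is a fixed design choice), with out-of-fold leaf
predictions aggregated to each of the 4 hierarchy levels; per-level
accuracy, per-category recall and confusion matrices are reported, and a
fold that loses a class entirely excludes it from that fold with a
warning. Feature importance is impurity (Gini) importance divided by its
mean, so the reported values average exactly 1. The feature-reduction
curve ranks features by importance *within each training fold only* and
retrains on the top-k, so held-out data never influences the ranking.
`brightfield_only_subset()` selects the 85 catalog entries scoped to the
bright-field channel — the descriptors available without fluorescent
staining.

## The synthetic scenes

`render_scene()` rasterizes parameterized solids at the anisotropic voxel
centers of each mosaic field in *global* coordinates, so an object inside
an overlap band appears consistently (up to independent per-field noise)
in every field that images it. Six shape families emulate common
morphotypes: sphere (coccolithophore-like), three-cell ellipsoid chain
(diatom-chain-like), spiky star (radiolarian-like), hollow ring, textured
blob, and a touching cell pair. Channel structure per cell: one nuclear
blob (DNA), a solid cytoplasmic membrane signal (optionally modulated by
a deterministic spatial texture), a surface rim, 0–2 chloroplast blobs,
and a faint uniform bright-field silhouette. Organelle blobs get a
minimum 1.15 µm axial semi-axis so they span at least two optical
sections and survive the almost-max projection, mirroring real organelle
sizes. Background noise is Gaussian per channel (fluorescence mean 12,
SD 3; bright field 30/4 — arbitrary but realistic PMT-like scales), with
an optional heavy-tailed component of bright 3-voxel speckle columns.

Three packaged fixtures (`make_fixture()`): `dim_field` (one 640-px
field, 30 low-contrast solid particles, heavy-tailed background — the
Otsu comparison scene), `six_classes` (900 single-object 96-px fields,
150 per class, under a 6-leaf, 4-level taxonomy; the textured blob shares
the coccosphere's silhouette and level-3 parent and differs mainly in
fluorescence structure, which is what makes the bright-field-only subset
measurably weaker), and `mosaic_straddle` (3×3 mosaic of 384-px fields
with 10 objects inside overlap bands and 8 interior objects). The
`six_classes` problem sizes keep the full detection + 480-feature +
10-fold-CV acceptance run in a few minutes on one core while leaving all
six classes represented well above the curation threshold.

What the scenes deliberately do **not** emulate: optical blur/PSF (the
pipeline performs no deconvolution, so blur adds nothing to contract
testing), spectral bleed-through (handled at acquisition in practice),
staining chemistry variability, and photorealistic morphology. Passing
tests therefore demonstrate the correctness of the algorithms and the
qualitative behaviors (threshold comparisons, dedup uniqueness,
separability directions), not field performance on ocean samples.

## Quantification

Counts are pooled over technical replicates *before* normalization
(counts summed, imaged volumes summed, then divided) — pooling after
division would weight replicates wrongly. Concentrations are counts per
liter. Covariate relationships use Spearman correlation with average
ranks on ties, exact p-values for n ≤ 9 without ties and the large-sample
approximation otherwise (the tie/p-value conventions are declared
choices); samples not containing the taxon are excluded, and a
least-squares line is reported for display only. A "live cell" is
operationalized as: at least one DNA sub-object and non-zero membrane
biovolume — a declared proxy for preserved organellar content.

## Determinism and problem sizes

Every stochastic step (scene noise, forest training, fold assignment)
takes an explicit seed; per-field noise seeds derive from the scene seed
and the field index, so outputs are bit-identical across runs and across
field orderings. The test suite runs the full `six_classes`
detection-to-CV chain once and memoizes it; the remaining tests use
hand-built fields, tiny stacks (8×8×5 exhaustive projection oracles), and
closed-form oracles (direct GLCM counting, rank-formula Spearman,
brute-force hierarchy aggregation).

## Known limitations

* Objects larger than the mosaic overlap band are systematically missed
  (see above).
* The chain perimeter underestimates true contour length by up to ~5% on
  smooth shapes and makes a square's "circularity" ≈ 0.97; descriptors
  are internally consistent, which is what classification needs, but are
  not calibrated absolute shape measures.
* Sub-objects close to the 0.5 µm³ cutoff are also at the survival limit
  of the 3×3×3 median filter (a compact 13-voxel component does not
  survive filtering); the volume filter's boundary is exact, but the
  practical detection limit for organelles is set by the filter, at
  roughly twice that volume.
* The bright-field channel contributes descriptors only; scenes with
  signal exclusively in bright field are invisible to detection, by
  design.
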