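---
title: "Context-aware hot-spot selection in Ki-67 stained whole-slide images"
author: "Ki67Hotspot package"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Context-aware hot-spot selection in Ki-67 stained whole-slide images}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(Ki67Hotspot)
```

## The problem

Grading a meningioma requires the Ki-67/MIB-1 proliferation index: the
percentage of immunopositive tumour nuclei among all tumour nuclei,
evaluated in a set of high-power fields of view (FOV) with locally maximal
density of stained nuclei — the *hot-spots*. Manual hot-spot selection at
low magnification is poorly reproducible, and whole-slide images (WSI) are
full of structures that mimic immunopositivity: hemorrhages and
erythrocytes stain brown, vessel walls take up DAB, and tissue folds
compress nuclei into artificially dense dark bands. This package implements
a complete, deterministic selection system: specimen mapping, artifact
elimination, immunopositive-cell marker extraction, and spatially
diversified field selection, together with the agreement statistics
(Spearman's rho, Bland-Altman) used to compare two examination series.

## Working resolution and FOV geometry

The reference acquisition is a 20x scan at 0.38895 um/px, where the
digitized FOV is 1024 x 766 px — the rectangle covering the same ~0.12 mm^2
as a circular 400x microscope field. All context analysis runs at an
eight-fold reduction (~3.11 um/px), where nuclei are a few pixels across:
large enough to count as markers, small enough that a whole slide fits in
memory. `fovGeometry()` rescales the reference FOV to any resolution with
per-axis rounding to whole pixels, so window counts are exactly
reproducible; `readSlide()` selects the pyramid level closest to the
configured downsample (multi-page TIFF pyramids; plain PNG/TIFF rasters are
level 0) and reports every result in level-0 pixel coordinates.

## Color model

Three representations feed the pipeline (`colorPlanes()`):

* **CIE Luv** under sRGB companding and a D65 white point (the source
  material does not state its convention; this one is fixed and
  documented). Luminance L is the altitude map for cell extraction; the
  chroma plane v (blue-yellow axis) drives the immunonegative counting
  pass.
* **Naive CMYK** (K = 1 - max(R,G,B)/255). The Y plane highlights
  DAB-brown structures and is the substrate for vessel-wall detection.
* **The composite u*512 + C channel**, a stain-ratio-oriented plane whose
  texture statistics separate tumour tissue from hemorrhage largely
  independently of the fraction of immunopositive cells. u is kept on its
  native CIE scale, C in [0, 1]; the 512 factor makes u dominant by
  construction.

## Specimen map

Pixels with R = G = B = 0 are non-scanned regions and are excluded
outright. The remaining pixels are thresholded on the B - R difference with
Otsu's method (`otsuThreshold()` works on any numeric scale via a 256-bin
histogram and is verified against exhaustive variance search), then cleaned
by closing with a disk of radius 6 (admissible range 5-8), hole filling,
and removal of components below one-fiftieth of a FOV area — small enough
to close nucleus-scale holes, large enough to preserve genuine inter-lobe
gaps. The cleanup is idempotent.

## Texture description and the artifact cascade

Hemorrhage and fold regions are recognized from local texture, not color
alone. Two descriptor families are computed over circular neighborhoods
Omega:

* **Unser sum/difference-histogram features** (mean, variance,
  homogeneity, contrast, energy, correlation, cluster shade, cluster
  prominence), built from pixel pairs with both endpoints inside Omega,
  averaged over the four unit displacements for rotation robustness.
  Intensities are quantized to 64 levels; the quantization range of the
  training plane is stored in the trained model so quantized units are
  comparable across slides. The feature vector carries Unser features of
  the composite plane and of luminance (fixed 0-100 range — folds are
  first of all a darkness artifact) plus a 16-point rotation-invariant
  uniform LBP histogram.
* **Local binary patterns** with arbitrary radius and sampling count,
  bilinear interpolation and a >= comparison; uniform, rotation-invariant
  and uniform-rotation-invariant mappings are supported.

Features are ranked per stage by Fisher's linear discriminant
(population-variance convention, epsilon guard) and the top 8 feed two
Gaussian-kernel SVMs in cascade: stage 1 separates tumour from
hemorrhage/erythrocytes; stage 2 runs only inside the stage-1 tumour
output and flags folds. Hyperparameters come from a small seeded grid
(kernel width over {0.1, 1, 10} x the median-distance heuristic computed on
standardized features, cost over {0.1, 1, 10}) with a held-out split.
Training samples keep a two-Omega margin from class boundaries, because
border patches mix textures; accordingly the training radius (12 px) is
slightly larger than the testing radius (10 px). At test time the cascade
is evaluated on a stride grid (one radius) and rasterized back by
nearest-grid assignment; no dilation is applied, since boundary grid
points with mixed neighborhoods already overshoot the region by about one
radius.

## Vessel walls

Brown-stained vessel walls would otherwise be segmented as immunopositive
cells. Two detectors run on the Y plane and their union forms the vessel
map:

* an LBP-gated intensity channel (locally contrasted pixels, mean-filtered
  5x5, Otsu threshold with an absolute floor, opening with radius 3 to
  erase nucleus-sized specks, closing, and a 100-px component floor for
  merged-nucleus remnants), and
* a CORF-style contour operator: the positive part of a
  difference-of-Gaussians (sigma 2 px vs 4 px) evaluated at five collinear
  sub-field positions per orientation (8 orientations) and combined by a
  geometric mean, so only contrast sustained along a line responds. The
  response is zero on constant images and invariant to intensity offsets.
  Binarization uses the 0.95 in-tissue quantile with an absolute floor of
  0.02 — the quantile alone would threshold numerical noise on
  vessel-free slides.

Components smaller than a 15-px-diameter disk are removed, and an
elongation filter (filled area at least 3x the squared thickness) drops
compact blobs. At this resolution a dense immunopositive cluster can still
imitate a wall, and eliminating it would destroy the very hot-spot the
tool exists to find — the known sensitivity trade-off of wall detection.
The pipeline therefore vetoes any vessel component whose density of
extracted cell markers exceeds one per 150 px (a preliminary extraction
pass; genuine walls resolve into at most a handful of large components).
All constants are exposed in `corfConfig()`, `vesselsFromLbp()` and
`pipelineConfig()`; `--no-vessel-removal` disables the stage entirely.

## Color artifacts

Small near-black foreign objects (dust, ink) destabilize color transforms
and would register as ultra-deep luminance wells. `colorArtifactCutoff()`
computes the 5th-percentile luminance inside the analyzed region, clips
the lowest 5% of values to it, and flags an individual artifact when the
gap between the true minimum and the cut-off exceeds a threshold — the
cut-off acts as a robust minimum estimator. Two numerical choices matter:

* **Gap threshold 50 L-units.** Anti-aliased and overlapping DAB nuclei
  spread luminance continuously from about L 28 to 70, so artifact-free
  slides show gaps up to ~45; near-black matter (L < 10) pushes the gap
  well past 50.
* **Pipeline wiring.** When flagged, the pipeline excludes only the
  near-minimum band (minimum + 10 L-units) from analysis and keeps the
  *unclipped* plane for extraction. Clipping dark values to the 5th
  percentile is harmless only when nuclei occupy more than 5% of the
  region; on sparse specimens it would flatten every immunopositive well
  to the percentile level and erase them. The clipped plane remains
  available for range-sensitive consumers.

## Immunopositive cell extraction

Nuclei are wells in the luminance plane. Thresholding is unreliable across
slides, and extended regional *maxima* overestimate object areas when
cells merge; the package therefore recognizes the *non-immunoreactive*
region (background plus immunonegative cells) as the extended regional
minima of the inverted plane — every basin flooded by depth h — and takes
the complement within the tumour mask. Each connected component emits one
marker at its centroid (rounded, ties toward smaller coordinates). The
machinery is grayscale morphological reconstruction (hybrid
raster/anti-raster algorithm with a FIFO queue, 8-connectivity, compiled),
verified against a naive fixpoint oracle. The complement region shrinks
monotonically as h grows; the marker *count* is non-increasing for
isolated wells (the controlled regime the parameter is meant for), though
a merged pair of cells can transiently split into two components when the
saddle between them submerges.

Numerical choices:

* **Altitude reference.** Before the transform the plane is capped at its
  in-mask 0.8 quantile (the tissue plateau). Without the cap, bright glass
  pixels inside the tissue mask become the basin reference and every well
  gains the plateau-to-glass gap, changing the meaning of h.
* **h = 20 L-units** by default: comfortably above the ~15-unit wells of
  hematoxylin-only nuclei (which must stay on the minima side) and below
  the ~50-unit wells of DAB-brown nuclei. Exposed in `pipelineConfig()`.
* **Immunonegative pass.** The full-resolution counting algorithm of the
  original system is out of scope here, so the Ki-67 index is the marker
  ratio 100*pos/(pos+neg). Negatives are extracted with the same transform
  on the Luv v plane, where hematoxylin-blue nuclei are wells (default
  h = 10 v-units) while DAB-brown nuclei lie *above* the background level.
  A CMYK-based plane was rejected: brown nuclei and bare glass both carry
  C ~ 0, so they are indistinguishable there.

## Hot-spot gradual extinction

A density map counts markers in every candidate FOV window (stride: half a
FOV per axis; candidates covering less than half their area with tumour
are invalid; counts are verified against brute-force recounting).
Selection is iterative: each candidate is scored as raw count times

    penalty = 1 - rho * sum_i d_i^(-1/2)

with d_i the Euclidean distances to the already selected fields, measured
in FOV widths so that rho is resolution-independent; the penalty is
clamped at zero and applied multiplicatively (the source material says
only that the candidate value is "reduced with a penalty factor"). The
maximum wins; ties break by higher raw count, then row-major grid order,
making selection bit-reproducible. With rho = 0 the algorithm is plain
greedy top-k. rho defaults to 0.3 — the original calibration is not
recoverable, so the value was chosen once such that two equal far-apart
clusters alternate while a cluster dominating by two orders of magnitude
retains all selections; both behaviours are asserted by the test suite.
After many selections the penalty sum can saturate (clamp to zero over the
whole map), at which point the raw-count tie-break governs; this is a
property of the published penalty form.

Specimen-size rules: specimens smaller than 500 FOV-equivalents are capped
at floor(area * 20 / 500) fields instead of 20; low-compactness specimens
(area under 100 FOV, or effective radius — the largest inscribed-circle
radius — under 6 radii of a FOV-area circle) scale rho down
proportionally.

## Agreement statistics

`spearmanRho()` uses average ranks for ties and the large-sample t
approximation for p; `blandAltman()` reports the mean difference and
mean +/- 1.96 SD limits on linear or log scale. The log scale uses
log10(value + 0.1) so that Ki-67 = 0 cases stay usable; the offset is a
documented, configurable choice.

## The synthetic-slide generator

`generateSlide()` renders seeded, bit-reproducible scenes with complete
ground truth: elliptical tissue lobes on a bright background, anti-aliased
nucleus disks of radius 2.5 px (DAB brown / hematoxylin blue palettes
chosen so positive wells are ~50 L-units deep and negative ~15), optional
dense immunopositive clusters, granular hemorrhage patches, darkened fold
bands with duplicated nucleus texture, thin brown vessel walls, near-black
artifact clusters, pinholes, and a Gaussian blur of sigma 0.8 px. Nucleus
placement is rejection sampling with a spacing of one diameter plus 1-2 px
and a retry cap; achieved counts are always reported. The generator
emulates geometry, palette and density structure — it does **not** emulate
stain variation between laboratories, scanner noise, chromatic aberration,
out-of-focus regions or genuinely ambiguous histology. Passing tests
therefore demonstrate the correctness and internal consistency of the
algorithms under controlled conditions, not clinical performance on real
archives.

## Problem sizes in the test suite

Unit tests run on planes up to 64 x 64 (oracle equivalences) and slides of
300 x 200 to 700 x 500 px. Pipeline behaviour tests use 1400 x 900 px
scenes (about 64 FOV-equivalents). The selection-cardinality check builds
one 3800 x 2750 px specimen — about 529 FOV-equivalents with 51 dense
clusters — and runs the full default pipeline on it; the same conditions
are reproduced by `scripts/acceptance.R`. These sizes keep the whole suite
within a few minutes on a single core while exercising every stage at
realistic densities.

## Known limitations

* Thin vessel walls (thickness at or below the opening radius) escape the
  LBP channel and are only partially covered by the CORF operator;
  raising sensitivity misclassifies dense immunopositive regions — the
  veto guards the common case but the trade-off is real.
* The artifact-gap and h defaults assume DAB/hematoxylin staining with the
  palette contrast described above; heavily understained slides need
  reconfiguration.
* The Ki-67 index here is a working-resolution marker ratio, not the
  full-resolution nucleus count of the original system; absolute index
  values are comparable within this pipeline only.
* mrxs and other proprietary pyramid containers are not read directly;
  convert to multi-page TIFF or feed working-resolution rasters.
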