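---
title: "Single-cell histology cytometry: models, parameters and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Single-cell histology cytometry: models, parameters and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(histoflow)
```

`histoflow` quantifies two- and three-marker myeloid-cell populations in
immunofluorescently stained brain tissue by treating per-cell staining
intensities like flow-cytometry data. This vignette is the package's own
account of the underlying procedure: what is modelled, which parameters
matter, what the synthetic generator does and does not emulate, and where
genuinely open design choices were resolved.

## The measurement model

A stained field is a set of single-channel rasters in camera-native grey
levels with a known pixel size (µm/px). Intensities are **never rescaled to
0–1**: polygon gates are defined in intensity units and must transfer
unchanged between cases imaged under the same settings. Pixel coordinates
are 0-based `(row, col)`; all physical quantities are in µm.

Cells are not segmented from morphology. Instead, each marker channel is
thresholded adaptively — a pixel is foreground when it exceeds the
Gaussian-weighted mean of its local window by more than an offset — and the
per-channel masks are united into a *master mask*. Its connected components
are the "cells". This deliberately over-merges touching cells and
under-represents fine processes; it is the standard trade-off of this
pipeline family, and population proportions are robust to it because both
numerator and denominator count master-mask objects.

Key parameters:

| parameter | default | meaning |
|---|---|---|
| `window_px` | 31 (63 used for 0.5 µm/px fields) | adaptive-threshold window; should exceed the largest cell diameter so cell interiors sit above their local mean |
| `offset` | 0–5 grey levels | noise floor above the local mean |
| `min_area_um2` | 20 µm² | debris filter on component area (no size filter is inherent to the method; exposed in config) |
| `connectivity` | 8 | diagonal-touching processes stay one object |
| `drop_border` | FALSE | border objects are retained unless requested |

The per-cell mean intensity (arithmetic mean over the component's pixels)
is the analogue of protein concentration per cell, and the coordinate used
for gating. Background is not subtracted before measurement; an optional
preprocessing hook exists but the default mirrors the measurement as
practised.

## Gating

Gates are simple closed polygons in a 2D intensity plane, stored as JSON.
Containment uses the even-odd rule with **boundary points counted inside**;
gates of one set must be pairwise non-overlapping, and a cell contained in
two gates is an error naming both — assignment is therefore deterministic
and order-independent. Freehand gate drawing is inherently subjective and is
kept outside the package: `quantile_gates()` derives reproducible starter
rectangles from pooled-density quantiles, and `boundary_gates()` builds
quadrant gates at explicit decision boundaries (used throughout the tests,
where the generating mixture makes the true boundaries known).

Two readings of "mean population intensity" exist: the arithmetic mean of
member-cell intensities, and the centre of the population on a contour
(density) plot. Both are provided (`stat = "mean"` / `"density_mode"`);
the arithmetic mean is the default and is what the tests assert, and the
package does not claim either is the original pipeline's exact computation.
Similarly, gating operates on raw intensity axes by default because average
intensities are what the scatter plots show; log-axis gating is a user
choice, applied by transforming the table columns.

Abundances are reported as proportions of **all** master-mask cells, so the
gate proportions plus the ungated remainder sum to one per case. Pooling
concatenates per-case tables while preserving case identity, so gates drawn
on the pooled cloud can be evaluated per case; hierarchical gating applies a
stage-2 gate set only within a stage-1 gate (e.g. marker populations within
Iba1-low cells) and reports stage-2 proportions relative to stage-1 counts.

## Registration of sequential staining rounds

Two staining rounds of the same section are aligned on the Hoechst nuclei
channel. Preprocessing is a rolling-ball background subtraction
(grey-scale opening with a disk of radius 50 px, subtracted and clipped at
zero) followed by a 5 px-radius median filter. Landmarks are nuclei blobs:
8-connected components above `median + 0.2·(max − median)`, localised by
intensity-weighted centroids (sub-pixel). Each keypoint is described by its
sorted distances to its 8 nearest neighbouring keypoints — invariant to
rotation and translation and stable under the ≤10° rotations and ≤30 px
translations this protocol produces. Matches pass a 0.75 ratio test and a
mutual-consistency check; a 6-DOF affine is fitted by seeded RANSAC
(reprojection tolerance 3 px), refined by least squares on the consensus
set, then improved by two guided re-matching passes. A 4-DOF similarity
fallback (`model = "similarity"`) exists for degenerate keypoint geometry.
The ratio, tolerance and iteration count are configurable; none is claimed
to reproduce a specific historical parameterisation. On synthetic pairs the
estimator recovers the truth to ~0.05 px median corner error; the package's
acceptance checks require < 1 px in at least 9 of 10 seeded perturbations.

The recovered matrix maps moving `(row, col)` coordinates to fixed
coordinates and is applied identically to every channel of the moving
round, bilinear for intensities and nearest-neighbour for masks (which must
stay binary). EBImage's own affine resampler uses a different coordinate
convention, so warping is implemented in-package against the documented
`(row, col)` convention.

## Plaque proximity by incremental dilation

A cell overlapping the amyloid-beta mask by at least one pixel is `plaque`.
Otherwise the plaque mask is dilated with disks of radius `k·5` µm
(k = 1..10, converted to pixels by rounding) and the cell's bin is the
smallest dilation it overlaps — intervals are half-open, so a cell exactly
on a dilation boundary takes the smaller bin. Cells beyond 50 µm are
`non-plaque`. Each dilation is applied to the **original** mask rather than
iterating 5 µm steps: iterated rasterised dilations accumulate error,
whereas cumulative disks make the procedure equal to
`5·⌈d/5⌉` on the Euclidean distance transform up to one pixel of disk
rasterisation. That equivalence is asserted in the tests (≥99% of cells
over seeded fields; in practice 100%, with any discrepancy confined to
within half a pixel-width of a bin boundary). This cumulative reading of
"dilated circularly in 5 µm increments" is a deliberate design choice, not
a claim about the original implementation.

## Statistical decision procedure

Two-group comparisons are screened: Shapiro–Wilk on each group and the
variance-ratio F test, all at α = 0.05 (the same α as the final tests;
no separate screening level is defined anywhere, so one constant is used).
If all three screens pass, Student's pooled-variance t test; otherwise
Mann–Whitney. Zero-variance samples, on which Shapiro–Wilk is undefined,
route to the nonparametric branch. Correlations are Pearson (parametric
branch) or Spearman, classified *strong* at `r ≥ 0.8` and *moderate* at
`0.7 ≤ r < 0.8`. The rule is stated for positive r only; negative
correlations are left unclassified under the signed default, with
`strength_on = "absolute"` as the documented alternative.

Population × group layouts use a between-subjects two-way ANOVA with
Tukey-adjusted contrasts; the spatial-location analysis uses a
repeated-measures ANOVA whose location effect is corrected by the
Greenhouse–Geisser epsilon computed from the within-subject sample
covariance (ε = 1 under compound symmetry — asserted exactly in the tests
by constructing data whose sample covariance is compound symmetric).
All-equal degenerate inputs report F = 0 and adjusted p = 1 rather than
NaN. Cohort tables are summarised as mean ± sample SD (n − 1) with missing
values excluded pairwise; the packaged 16-case cohort table reproduces the
published group means that are arithmetically consistent with its rows
(the normal-group PMD mean and age SD as printed are not consistent with
their own rows; the package reports the row-derived values).

## The synthetic generator

`simulation_config()` defines the study conditions the tests run under:
512×512 px fields at 0.5 µm/px (a 20× field of cortical grey matter),
200 cells of radius 3–6 µm, three log-normal intensity populations
(Iba1-low/marker-high, Iba1-high/marker-high, Iba1-high/marker-low — the
canonical two-marker phenotypes; log-scale SD 0.2 separates them by ~3.5σ
at the geometric-mean boundaries), 5 plaques of radius 10–25 µm, background
10, additive Gaussian noise (SD 2) truncated at zero, and integer
quantisation, as a camera digitiser would apply. Cells are hard-edged disks
placed by bounded rejection sampling with no overlap, so every cell is one
connected component and the mean-intensity ground truth is exact; an
optional Gaussian blur is available but off by default for exactly that
reason. Log-normal intensities reflect the right-skewed single-cell
intensity clouds of stained myeloid populations; no specific distribution
is claimed by the method itself.

What the generator does **not** emulate — and what passing tests therefore
do not show about real tissue: ramified microglial morphology and touching
cells (real master masks merge cells; proportions are then per-object, not
per-biological-cell), shading/vignetting and staining-batch effects,
autofluorescence, 3D structure, and plaque morphology beyond disks. The
generator validates the machinery (segmentation arithmetic, gate geometry,
bin logic, transform recovery), not the biology.

## Numerical choices and environment notes

- EBImage's grey-scale morphology and fast median filter operate on
  [0, 1]; the package rescales by the image maximum around those calls. The
  constant-time median filter quantises to 16 bits, contributing relative
  errors of order 1e-5 of the dynamic range.
- TIFF storage is 8/16-bit unsigned integer in native grey levels (the
  no-rescale contract); float TIFF writing is not supported by the
  underlying library without clipping, and integer grey levels are what
  cameras produce anyway. All I/O round-trips are exact.
- `bwlabel` labels 4-connected components; 8-connectivity is obtained by
  union-find merging of diagonally adjacent labels, then consecutive
  relabelling in raster order.
- Disk structuring elements contain every pixel within the radius
  (inclusive); dilation radii in pixels are `round(r_um / pixel_size)`,
  and the EDT-equivalence tolerance accounts for this rounding.
- Polygon containment tolerances scale with the coordinate magnitude
  (1e-9 relative); adjacent quadrant gates are separated by a gap of 1e-6
  of the axis range so that no point can satisfy two gates.
- All randomness (generator, RANSAC) flows through one seeded wrapper that
  restores the caller's RNG state; identical configs are bit-reproducible.

Problem sizes in the tests and acceptance script (2000-cell mixtures at
1024 px for gating recovery, 8–20 seeded 512 px fields for the spatial
oracle, 10 registration perturbations at 384 px) were chosen as the
smallest sizes at which the binomial and sub-pixel tolerances above are
meaningful statements about the method.

## Known limitations

- Master-mask segmentation cannot split touching cells; abundances are
  per-object.
- Landmark registration needs a few dozen detectable nuclei per field and
  assumes the two rounds image the same physical section (affine motion
  only; no deformation).
- The dilation-based proximity analysis is 2D; distances in thick sections
  are underestimated projections.
- Tau-tangle proximity is out of scope (the procedure is defined for
  plaques only), as are proprietary microscope formats and whole-slide
  pyramids.
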