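---
title: "Canopy segmentation and waterlogging-tolerance statistics: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Canopy segmentation and waterlogging-tolerance statistics: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(canopywtc)
```

## The measurement problem

Waterlogging injures grasses by starving roots of oxygen; the visible
symptoms are stunted growth and leaf senescence. Tolerance screening needs
two quantities per plant: how much shoot it produced, and how much of that
shoot is still green. Harvest-based phenotyping measures both directly but
destroys the plant. An overhead RGB photograph provides a non-destructive
proxy: the projected area of green canopy correlates strongly with green
shoot biomass, and the projected dead (chlorotic/senescent) area with dead
leaf biomass, so image-derived areas can stand in for harvested weights in
genotype comparisons and in the waterlogging tolerance coefficient.

This vignette documents the package's model of that measurement: each
processing step, its assumptions, its tunable parameters, and the numerical
and design choices behind them.

## The segmentation pipeline

`segment_plant()` is a deterministic function of the image, a
`segmentation_config()` and a seed. Its steps:

### 1. Background removal by color threshold

Soil is identified by a per-channel inclusive color volume learned from
labeled example pixels (`learn_soil_threshold()`). The working space is HSV
by default: soil separates from foliage mainly by hue and saturation, and
those coordinates are less sensitive to the brightness variation of field
illumination than raw RGB. RGB is available where the soil/plant contrast
is best expressed there.

The learning rule is a *trimmed envelope with greedy refinement*: start
from the [p1, p99] percentile box of the soil training pixels per channel,
then repeatedly move the one bound whose tightening excludes at least one
misclassified plant pixel at the smallest cost in enclosed soil pixels,
stopping when no plant pixel remains inside or a floor width (10% of the
initial envelope) is reached. A final relaxation pass grows each bound back
toward the soil extremes wherever that re-admits no plant pixel. The result
maximizes soil coverage subject to excluding plant colors where the two
classes are separable, and every step is auditable from the returned
bounds. Degenerate training sets (all-soil or all-plant) are rejected.

The assumption to be aware of: the threshold is a box, not an arbitrary
region. Soils whose color wraps around the hue origin or overlaps foliage
hues (heavily algae-covered flood water, for instance) violate it and need
a manually chosen RGB threshold or retraining per session.

### 2. Color stretch

Foreground colors are contrast-stretched before clustering
(`stretch_colors()`). The default is a decorrelation stretch: center the
foreground colors, whiten with the symmetric inverse square root of their
covariance, and rescale each output channel to span [0, 255]. Whitening
makes the output channels exactly uncorrelated over the foreground, which
spreads subtle hue differences (green vs. yellowing tissue) across the full
dynamic range and makes the subsequent Euclidean clustering much better
conditioned. The transform is affine and is retained in the result so that
class prototype colors, specified in raw RGB, can be pushed through the
identical mapping before distances are measured.

Numerical edge cases: a foreground covariance with an eigenvalue below
1e-8 of the largest (e.g., a gray ramp with R = G = B, or fewer than 4
foreground pixels) cannot be whitened; the method falls back to the
percentile stretch and flags the fallback in the provenance. The percentile
stretch maps each channel's [p2, p98] to [0, 255] linearly with clipping; a
channel with zero dynamic range maps to the midpoint 128 rather than
dividing by zero. Background pixels always pass through untouched.

### 3. Seeded k-means with prototype assignment

`kmeans_cluster()` is Lloyd's algorithm with k-means++ initialization from
an explicit integer seed. All tie-breaks are fixed so the procedure is a
pure function of (data order, seed): nearest-centroid assignment breaks
ties toward the lowest centroid index; a cluster emptied during an update
is re-seeded to the point farthest from its current centroid; iteration
stops when the largest centroid movement falls below `tol` (default 1e-3
color units) or after `max_iter` (default 100) rounds. The within-cluster
SSE trace is recorded and is non-increasing — a property the test suite
asserts on every run it examines.

The clustering itself is unsupervised; supervision enters afterwards, when
each cluster centroid takes the class of its nearest prototype color
(`assign_classes()`). Default k = 4 intentionally exceeds the three
classes: foliage under field light typically splits into sunlit and
shadowed clusters, and the extra cluster lets shadowed leaf fall to the
green prototype instead of contaminating the dead class. Exact prototype
ties resolve in the fixed priority green > dead > background. Pixels
outside the foreground mask are forced to background regardless of their
cluster.

On 13-megapixel frames, centroids are fitted on a seeded subsample
(default cap 200,000 foreground pixels); the final assignment is always
computed exactly for every pixel, so the cap affects only the fitted
centroids, not coverage, and determinism is preserved.

### 4. Counting, percentages, areas

`count_pixels()` tallies the mask exactly (the three classes always sum to
H × W). `to_percentages()` reports both denominators — percent of the whole
image and percent of the plant silhouette — because downstream uses differ:
areas and the projected WTC need absolute extent, while the green:dead
split of the plant is a per-plant injury score. A plant-free image yields
missing (`NA`) of-plant percentages, never 0/0. `pixels_to_area()` applies
`area = count × mm_per_pixel²`. The calibration is a required user input:
the physical scale depends on camera height, sensor and lens, which the
package deliberately does not guess; areas are stored in mm² and reported
in cm² (100 mm² = 1 cm²).

An optional cleanup pass removes connected plant components smaller than a
configured pixel count (8-connectivity, via EBImage); it is off by default
because the threshold step already suppresses most background noise and
silent removal of real small tillers would bias areas low.

## Trait statistics

The waterlogging tolerance coefficient is
`WTC = 100 · SHB_waterlogged / SHB_control` per genotype, with the
genotype-mean ratio as the default pairing (replicate-wise ratios are not
defined in an unpaired field layout); the projected WTC substitutes
projected green areas for biomass. Both are scale-invariant — multiplying
both arms by any positive constant leaves them unchanged — which is why the
projected WTC needs no absolute area calibration to rank genotypes.

Genotype means are arithmetic cell means. In the balanced designs this
package targets (equal replicates per genotype × treatment), these coincide
with the least-square means a mixed model would produce, so the package
does not carry REML machinery; unbalanced data are averaged per cell and
flagged through the per-cell `n`. The coefficient of variation uses the
pooled within-genotype standard deviation over the grand mean.

Pearson correlations use pairwise deletion with per-cell `n` reported, and
two-sided p-values from `t = r·sqrt((n−2)/(1−r²))` on n − 2 degrees of
freedom. Star conventions default to 0.05/0.01/0.001 and are configurable;
the thresholds are strictly nested by construction. No multiple-testing
correction is applied across a correlation matrix — the convention of the
field-trial literature this serves — so a matrix of m traits is expected to
show ~5% falsely starred cells under the null, a rate the acceptance checks
verify by simulation.

Fisher's protected LSD: the LSD is computed only when the one-way ANOVA
F-test is significant at α (the protection); otherwise all groups share one
letter. `LSD = t(1 − α/2, df_error) · sqrt(2·MSE/n)` with the harmonic mean
replicate count when groups are unbalanced (the standard correction; exact
only under balance). Letters come from the classical sweep over means
sorted descending; because the LSD is common to all pairs, letter sharing
is exactly equivalent to |difference| ≤ LSD, and the tests verify that
equivalence pairwise on every case they construct.

## What the synthetic data emulate — and what they do not

`generate_scene()` renders a soil-textured frame, composites dead-leaf
ellipses, then green-leaf ellipses on top (green occludes dead, as an
overhead view of a senescing canopy does), adds independent Gaussian color
noise per pixel and channel (default sd 5 around class means chosen to be
separable but not trivially so — about 60 RGB units apart), and returns the
image together with the exact visible-class mask. The compositing order is
configurable. `generate_cohort()` draws log-normal genotype effects around
a 700 g/plant control biomass, applies a mean fractional biomass reduction
under waterlogging (default 0.5), splits shoot biomass into green and dead
fractions with per-genotype sensitivity, and links projected areas to leaf
biomass linearly with Gaussian noise — optionally calibrated so the planted
area–biomass correlation takes a requested value.

Passing the recovery tests on these scenes therefore demonstrates that the
pipeline's logic is correct under its own assumptions: roughly Gaussian,
spatially independent color noise; classes separated in color space; flat
or mildly graded illumination. It does not demonstrate robustness to what
real field frames add: specular water reflections in flooded plots, mixed
soil/leaf boundary pixels, cast shadows with colored light, overlapping
leaves that hide biomass (projected area systematically underestimates
large vigorous plants), or frame-to-frame illumination drift. Those effects
are why the threshold is re-learnable per session and the prototypes are
user-configurable rather than constants.

## Problem sizes and numerical conventions

The test suite and the acceptance script use 512 × 512 scenes (20 seeds)
for segmentation recovery, 1,000 simulated 22-genotype trait tables for
star calibration, and 100 cohorts of 200 plants for parameter recovery —
sizes at which the Monte-Carlo error of each check is far below its
tolerance while the full suite runs in well under a minute. Images are
8-bit sRGB, row-major, origin top-left, 0-based pixel semantics at the
array level; JPEG input is supported but all bit-exactness guarantees (and
all fixtures) use PNG, since JPEG is lossy. All randomness flows through
explicit integer seeds via `withr::with_seed`; no global RNG state is
consumed or leaked.

## Known limitations

- One plant per frame is assumed; multi-plant scenes are out of scope and
  must be split upstream.
- The pixel-to-area calibration cannot be inferred from image content; an
  uncalibrated run still yields percentages and the projected WTC, but no
  absolute areas.
- The box-shaped color threshold and Euclidean prototype matching are
  deliberately simple, auditable models; canopies whose classes are not
  color-separable (early chlorosis grading into green) will blur the
  green/dead boundary, and the k-means partition inherits the usual
  sensitivity to k.
- NDVI is ingested (or computed from two supplied reflectance bands), not
  measured: sensor interfacing is outside the package.
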