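---
title: "rootlapse: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{rootlapse: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The measurement problem

Plate-based germination assays image a grid of seeds (typically 8 x 8 at
1 cm spacing on dark agar) once per hour for up to five days. From those
frames we want, per seed: whether and when it germinated, its root length
over time, and its growth rate; and per genotype: a germination index,
a mean growth rate, and a statistical comparison against the other
genotypes on the experiment. `rootlapse` implements that pipeline —
segmentation, per-seed instance tracking, calibrated length measurement,
germination/growth-rate estimation, and the ANOVA/Tukey comparison layer —
together with a fully ground-truthed synthetic plate generator so every
stage is testable without real imagery, plus the supporting optics
arithmetic and a simplified depth-from-focus profilometry.

## Pipeline model

1. **Seed detection.** The first frame is segmented for seed pixels;
   8-connected components above a minimum size become seed instances, and
   grid identities `(row, col)` are assigned by snapping centroids to the
   implied regular grid. Components and identities are deliberately
   decoupled: a missing seed leaves a `lost` placeholder rather than
   shifting its neighbours' identities.
2. **Tracking.** For each frame the root mask's components are claimed by
   any instance whose previous bounding box, dilated by `margin_px`
   (default 5 px), contains at least one component pixel; the instance box
   becomes the union of itself and the claimed components' tight boxes, so
   boxes expand monotonically. A component claimed by two instances, or two
   boxes intersecting, marks both instances *overlapped* at that hour —
   irreversibly, because once roots touch, their pixels can no longer be
   attributed reliably. An instance that never grew and catches no
   component for 3 consecutive frames is *lost* (seed drift).
3. **Length.** Root pixels inside each box — including disconnected
   fragments, which occur when a seed coat occludes part of the root — are
   thinned to a skeleton (Zhang-Suen); length is the weighted step count
   along the skeleton (1 per 4-neighbour step, sqrt(2) per diagonal)
   divided by the pixel scale. Two corrections keep the estimate unbiased
   at tube ends: spurs (short thinning artifacts branching off the medial
   curve) of at most `prune_px` (4) pixels are removed, and each remaining
   endpoint is extended by its city-block distance to the background minus
   one, compensating the roughly half-width retraction that thinning
   applies at tube ends. Both corrections vanish on ideal one-pixel lines,
   so digital bars and diagonals measure exactly.
4. **Germination.** The seed body (the frame-0 seed component, dilated by
   `seed_dilate_px` = 1) is masked out before measuring, otherwise the seed
   blob itself would count as ~0.4 mm of "root". Germination is *confirmed*
   by the first hour at which the measured length reaches `min_len_mm`
   (0.25 mm) for `persist_frames` (2) consecutive frames. The *onset hour*
   reported in summaries is then refined by back-extrapolating the fitted
   early-growth line to the radicle origin (next section).
5. **Growth rate.** An ordinary least-squares line through length vs time
   over the window from the confirmation hour to either one frame before
   the first overlap or the end of the series; the slope is the growth
   rate. Windows of fewer than 3 samples leave the rate undefined
   (recorded, not thrown). Hourly rates (first differences) are also
   emitted, both per seed and as genotype means — the mean of the hourly
   rates over a window equals the OLS slope for noiseless linear growth.
6. **Comparison.** Germination index = percent of sown seeds that
   germinated. Rates are compared across genotypes by one-way ANOVA with
   Tukey HSD; compact letters are assigned by an insertion algorithm
   (split letters containing a significant pair, absorb contained letters,
   then drop redundant ones) and verified in tests against an exhaustive
   pairwise-consistency check and against `multcomp`. Replicate plates are
   pooled before the ANOVA rather than averaged; N per genotype counts
   only seeds with a defined rate, while the germination index denominator
   counts every sown seed.

## Germination onset by back-extrapolation

A radicle emerges from under the seed body, so its first ~0.2-0.3 mm are
invisible to any detector operating on root pixels: a raw threshold
crossing is systematically late by (hidden length)/rate — hours, for slow
genotypes. The onset estimate therefore extrapolates the fitted visible
length line back to the radicle origin:

    onset = x0 - hidden_mm / slope

where `x0` is the hour at which the fitted line crosses zero visible
length, and `hidden_mm` is the per-seed hidden length. `hidden_mm` is
calibrated by *replaying the measurement on the seed's own frame-0
component*: the component's pixels are copied to a clean canvas, a
synthetic tube of known length is attached at its centroid, and the same
exclusion-and-skeleton measurement is applied; the deficit between known
and measured length is the hidden length. This forward-model calibration
absorbs every constant bias at once (seed-body masking, mask dilation,
skeleton end corrections) without any reference to generator internals.
On synthetic plates spanning 0.03-0.17 mm/h this places onsets within one
frame of truth for far more than 95% of seeds; the residual error scales
as (sub-pixel mask error)/(rate x scale), so slow rates at coarse scales
are the hard case.

## The synthetic generator

`synthetic_config()` defaults describe the reference assay: 8 x 8 seeds at
10 mm spacing, 58.4 px/mm, hourly frames (up to 96), germination
probability 0.95 with delays uniform on 0-24 h, per-seed rates uniform on
0.03-0.17 mm/h, 5-px root tubes, seeds drawn as 0.45 x 0.30 mm ellipses,
background/foreground intensities 30/180 on the 8-bit scale (dark
charcoal agar convention; the intensity statistics are conventions, and
config-exposed) with Gaussian noise of 8 grey levels. Root paths extend
incrementally from the seed centroid with heading = down plus a Brownian
angular perturbation scaled by `curl` (0 = gravitropic; positive values
emulate agravitropic curling); an optional per-seed initial heading lets
tests engineer collisions at known frames. Seed drift is a rigid per-frame
translation of the whole object in a random fixed direction. Truth records
carry exact germination hours, per-frame arc lengths (rate x time by
construction), polylines, and the first hour at which two seeds' rendered
footprints, dilated by 1 px, share a pixel — verified in tests against a
brute-force per-frame raster check.

What the generator does *not* emulate: photoreal agar texture,
condensation, cotyledon/hypocotyl growth, contamination, lighting
gradients, or seeds of varying size. Passing recovery tests on this data
therefore demonstrates the pipeline's geometric and statistical
correctness, not robustness to every real-world artifact.

## Problem sizes

Recovery studies run at reduced resolution because resolution only has to
support the quantity being measured. Slope recovery needs aggregate
resolution over the fit window (rate x scale x window >> 1 px), which
10 px/mm satisfies for every rate down to 0.03 mm/h: the 64-seed cohort
study (96 hourly frames, delays 0-24 h, 10% never-germinating) recovers
per-seed slopes within 10% and a cohort MAPE well under 5%, and onsets
within one frame for >= 95% of germinated seeds. The engineered-collision
and unit fixtures use 2-9 seed plates at the same scale. The optics and
focus-stack modules are analytic or operate on constructed fixtures and
run at full precision.

## Numerical choices

- **Classical backend:** Gaussian smoothing (sigma 0.8), global Otsu
  threshold, 3 x 3 opening, component size filter >= 5 px. A guard rejects
  near-unimodal images (foreground-background separation below 4 noise
  standard deviations), so blank frames segment to empty masks instead of
  splitting noise.
- **Learned backend:** a single-hidden-layer neural network over windowed
  intensity features (pixel value, 3 x 3 and 7 x 7 box means, local
  contrast), trained on a balanced pixel sample with foreground weighting
  (background/foreground ratio capped at 50), binary cross-entropy, and a
  0.5 probability cut. It is deliberately compact — desk-scale CPU
  training in seconds, deterministic under a fixed seed. Because its
  features are intensity-only, it cannot distinguish seed from root
  pixels; the pipeline separates them geometrically via frame-0 seed
  masking, as does the classical backend.
- **Seed path:** seed-targeted models may block-average each 256-px patch
  down 8x, classify at 32 x 32 and nearest-neighbour upsample — only seed
  *positions* are needed. At coarse desk scales where a seed is only a few
  pixels, the pipeline runs the seed model at full resolution instead
  (`downsample = 1`).
- **Patching:** images tile into 256 x 256 patches with edge-reflection
  padding; stitching inverts extraction bit-exactly for any image size.
- **Depth-from-focus:** sharpness is the local variance (9 x 9) of the
  4-neighbour Laplacian; the depth index is the argmax across slices with
  ties broken toward the earlier slice; validity requires the winning
  sharpness to exceed a noise floor (1e-6 absolute by default, or a
  flat-field calibration percentile); an optional 3 x 3 median on the
  index map suppresses dust-trail artifacts. Surface meshes triangulate
  each fully-valid pixel quad into two triangles; a full w x h region
  yields (w-1)(h-1)x2 triangles.
- **Degenerate inputs:** empty masks measure 0 mm; empty first frames
  yield an explicit empty-plate report; constant samples are an error for
  the Shapiro-Wilk wrapper; a constant line probe has modulation 0 (global
  extrema fallback); single-slice stacks are all-valid at height 0.
- **Determinism:** one RNG seed drives the generator (per-seed draws in
  row-major order, then frame noise in frame order); training seeds both
  sampling and weight initialisation; the pipeline itself is
  deterministic, so reruns produce byte-identical CSVs.

## Known limitations

- Weighted step counting overestimates the length of tubes digitized at
  intermediate angles (up to ~8% near 30 degrees — the staircase effect),
  and thinning wiggle can add more at coarse scales. Vertical
  (gravitropic) roots are unaffected; strongly curled roots inherit the
  bias, which also propagates into their onset back-extrapolation.
- Tracking closes a seed's measurement window at the first overlap and
  never re-identifies lost seeds; crossing roots are not disentangled at
  the centerline level.
- The genotype comparison assumes pooled, independent seeds; no
  repeated-measures or plate random effects are modelled.
- Surface profilometry assumes surface dynamics slower than one stack's
  acquisition; a 70-slice, 10-um stack spans 690 um and should be acquired
  well within the timescale of the deformation being observed.
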