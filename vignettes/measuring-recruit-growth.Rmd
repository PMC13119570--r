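---
title: "Measuring coral recruit growth with a hierarchical detection-to-segmentation pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring coral recruit growth with a hierarchical detection-to-segmentation pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(coralmorph)
```

## The measurement problem

Land-based coral propagation programs track the growth of juvenile corals
("recruits", settled larvae a fraction of a millimetre to a few millimetres
across) by photographing each recruit under a stereo microscope and measuring
the surface area of its live tissue. Manual polygon tracing takes minutes per
image and does not scale to the thousands of images a growth trial produces.
coralmorph implements the automated alternative as a modular pipeline:

1. **Detect**: a detector localises the single recruit in the frame as an
   axis-aligned bounding box and classifies its developmental stage.
2. **Route**: the binary stage label (early/late) selects a stage-specific
   segmenter.
3. **Prompt**: the box is turned into a prompt set for a promptable
   segmenter. Early-stage recruits additionally get four *background*
   (negative) points at the box-edge midpoints.
4. **Segment and post-process**: the segmenter returns a binary tissue mask;
   post-processing keeps the largest connected component intersecting the
   box and can fill interior holes.
5. **Measure**: the mask's pixel count is converted to physical area with
   the pixel size from the image metadata.

The stage split exists because the two regimes have opposite failure modes.
Early recruits have thin, weakly pigmented tissue confined to the skeletal
(corallite) cup; segmentation tends to leak outward into the cup, inflating
areas. Late recruits have thick, strongly pigmented tissue with a
well-defined edge; the risk there is eroding the boundary, not leakage. The
four edge-midpoint background points are an explicit geometric prior against
leakage: for a roughly circular organism tightly boxed, the box-edge
midpoints are the nearest points *outside* the tissue, so marking them as
background pins the mask inside the box on all four sides. Late-stage
prompts are the box alone.

## Geometry conventions

Boxes and points use continuous coordinates with the origin at the top-left
image corner; the area of pixel (row 1, column 1) spans $[0,1)\times[0,1)$
and its centre is $(0.5, 0.5)$. For a box with corners
$(x_{\min},y_{\min})$, $(x_{\max},y_{\max})$ the centre is

$$x_c = \tfrac{x_{\min}+x_{\max}}{2},\qquad y_c = \tfrac{y_{\min}+y_{\max}}{2},$$

and the four background points are, in fixed top/bottom/left/right order,
$(x_c,y_{\min})$, $(x_c,y_{\max})$, $(x_{\min},y_c)$, $(x_{\max},y_c)$.
Continuous coordinates make these midpoints exact and make rescaling between
frames a pure per-axis affine map, under which midpoints map to midpoints.
Prompts are constructed in the original acquisition frame and rescaled into
the segmentation frame — not rebuilt after resizing — so all recorded
geometry stays tied to the physical image.

Model frames follow the common convention of 640 px for detection (coarse
features suffice to localise a recruit) and 1024 px for segmentation (the
boundary drives the area estimate). Masks travel between frames by
nearest-neighbour resampling with centre-aligned index mapping; this
preserves binarity, and upsampling followed by the matching downsampling is
an exact identity whenever the model frame is at least as large as the
image, so a perfect segmenter loses nothing in transit. For images larger
than the segmentation frame the round trip is lossy at the boundary, which
is one reason areas are always computed on the mask mapped back to the
*original* frame — the other being that the metadata pixel size refers to
that frame.

## From pixels to micrometres

With $A_{px}$ the number of mask pixels and $s$ the pixel size in µm/pixel,

$$A = A_{px}\, s^2 \quad [\mu m^2].$$

$s$ is resolved with the precedence: explicit override > JSON sidecar >
embedded OME-style XML physical-size fields > TIFF resolution tags
(pixels-per-inch/cm converted to µm/pixel). Two deliberate strictnesses:

* **Missing calibration is an error**, never a default of 1 µm/px — a wrong
  silent default corrupts every downstream area and acceptance statistic.
  In the pipeline the record is flagged `missing-calibration` and carries a
  pixel count but no physical area.
* **Anisotropic pixels are rejected** beyond 0.1% relative difference
  between the per-axis sizes rather than silently averaged, because the
  area formula assumes one scalar $s$.

When the package writes calibrated TIFFs it embeds the pixel size twice:
as full-precision text in the image description (the preferred, exact read
path) and as rational resolution tags (interoperable, but read back at
single precision by TIFF readers).

## Evaluation statistics

Per image $i$, with predicted area $A^{pred}_i$ and ground-truth area
$A^{true}_i$:

$$AR_i = A^{pred}_i / A^{true}_i,\qquad
AAR = \frac{100}{N}\sum_i \mathbf{1}\!\left[\,|AR_i - 1| \le \tau\,\right],$$

with tolerance $\tau = 0.05$ by default. The acceptance interval is the
*closed* band $[1-\tau, 1+\tau]$ (a strict variant is available via
`closed = FALSE`; the difference has measure zero for continuous data, but
the closed convention makes boundary examples well-defined). A small
epsilon guards the comparison so that ratios sitting exactly on the printed
boundary (0.95, 1.05) are accepted despite binary floating point. MAR, the
median area ratio of a stratum, measures systematic bias as its deviation
from 1; the mean ± sample (N−1) standard deviation is reported alongside.

Two-arm comparisons report
$\Delta AAR = AAR_{cmp} - AAR_{ref}$ and
$\Delta|\mathrm{Bias}| = |MAR_{ref}-1| - |MAR_{cmp}-1|$. The two published
table conventions differ only in which arm is the reference: an
*improvement* table takes the baseline as reference (positive deltas favour
the new arm), an *inversion/ablation* table takes the trusted final arm as
reference (negative deltas confirm it). `compare_reports()` exposes the
role assignment through its argument order and `convention` label rather
than through two different formulas.

Flagged records (no detection, empty mask, missing calibration, unreadable
file) are excluded from ratio statistics but counted in an `excluded_n`
column: the acceptance rate is a statement about produced measurements, and
silently including zeros would conflate detection failure with measurement
bias. Detection quality itself is summarised by precision/recall at box-IoU
0.5 with greedy confidence-ordered one-to-one matching.

## Deterministic reference backends

The package ships no trained networks. Instead, three reference backends
implement the detector/segmenter contracts so that every pipeline stage is
testable with exactly known error:

* `mock_detector()` jitters a ground-truth box by uniform corner noise
  (clamped to the frame, degenerate draws retried) and classifies with the
  ground-truth stage at confidence 0.99.
* `perturbation_segmenter()` returns the ground-truth mask dilated or
  eroded by a disc of radius $|\delta|$ pixels. On a disk of radius $r$ the
  expected area ratio is $((r+\delta)/r)^2$, giving a closed-form oracle
  for bias propagation; $\delta = 0$ reproduces ground truth bit-for-bit,
  so the whole chain must return $AR = 1$ and IoU $= 1$ exactly.
* `threshold_segmenter()` is a classical calibration-free baseline: Otsu
  thresholding inside the prompt box, veto of any connected component
  containing a background point (the deterministic analogue of a negative
  prompt suppressing leakage — the package makes no claim that trained
  promptable segmenters behave this way), keep-largest, minimum-size guard.

Backends are pure functions of their inputs, seeded per image from the run
seed by stable integer hashing, so batch runs are byte-reproducible.

## The synthetic image generator

`generate_recruit()` emulates the features the pipeline actually relies on:
a roughly circular tissue region whose radius is perturbed by low-order
harmonics $r(\theta) = R\,(1 + \sum_k a_k \cos(k\theta + \phi_k))$, a
darker textured corallite annulus around it, a linear illumination
gradient, additive Gaussian noise, and stage-dependent tissue contrast.
The ground-truth mask is the exact rasterization of that region under the
pixel-centre inclusion rule (a pixel belongs to the region iff its centre
does), which makes area oracles exact and orientation-free.

Defaults, chosen once as the study conditions of the synthetic experiments:
256×256 px frames at 8 µm/px; week-0 tissue radius 40 px (≈0.64 mm recruit
diameter, typical of a young recruit); cup ring 14 px; harmonic amplitudes
(0.05, 0.03); illumination gradient 0.10; noise sd 0.02; tissue contrast
0.15 (early) and 0.60 (late); geometric radial growth of 1.03 per week,
which roughly doubles the radius over a 23-week series while keeping the
largest recruit inside the default frame. Time-series datasets assign early
stage before week 8 and late after, mirroring the developmental span such
studies cover.

What the generator does **not** emulate: real corallite texture, septal
structure, symbiont patchiness, specular highlights, multi-recruit scenes,
damage, or the annotation noise of human tracing. Passing tests on these
fixtures therefore demonstrate the *plumbing* — geometry, calibration,
routing, statistics — with known-error backends, not the accuracy of any
trained segmenter on real imagery.

## Numerical choices and edge cases

* Acceptance band closed with a 1e-12 epsilon (above).
* Primary detection ties broken by confidence, then larger box area, then
  lexicographic corner order — fully deterministic.
* 8-connectivity for mask components (4-connected labelling plus
  union-find merge across diagonals).
* Empty masks, contrast-free crops, below-minimum components, and
  calibration failures become flags on the record, never silent drops;
  only an unreadable image file is an error, and batch runs convert even
  that into a flagged row.
* IoU of two empty masks is defined as 1 (exactly one empty: 0).
* Train/validation/test splits use a seeded shuffle with largest-remainder
  rounding, so a 10-row manifest splits 7/2/1 under 70/20/10.

## Problem sizes

The test suite and the acceptance script run entirely on synthetic
fixtures: 50 images at 128 px for the end-to-end identity and routing
checks, 500 images at 96 px for the acceptance-rate recovery experiment,
1000 random boxes for the prompt-geometry property, and 100 pixel sizes
spanning $[10^{-3}, 10^3]$ µm/px for the calibration roundtrip. These sizes
were chosen so the full suite completes in well under a minute while the
Monte-Carlo standard error of the recovery experiment (≈2 percentage
points at $n = 500$, $p = 0.7$) stays small against its 3-SE check.

## Known limitations

* Single recruit per image by design; the manifest/record schema would
  extend to multiple detections, but selection currently keeps exactly one.
* Stage is binary. The finer qualitative grades A–G are honoured only
  through their early/late mapping (A–C early, D–G late); fixtures encode
  only the two contrast regimes.
* The threshold segmenter is a baseline for bright-on-dark synthetic
  tissue, not a competitive segmenter for real microscopy.
* Resolution-tag-only calibration is float-accurate (~1e-7 relative), a
  limit of the TIFF rational representation as commonly read; the embedded
  text field is exact to double precision.
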