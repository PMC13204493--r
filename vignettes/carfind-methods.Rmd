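---
title: "Counting surface-captured CAR T-cells in brightfield images: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Counting surface-captured CAR T-cells in brightfield images: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(carfind)
```

`carfind` quantifies CAR T-cells captured on a CD19-functionalized sensor
surface from label-free brightfield tiles. This vignette explains the
underlying models, the parameters that matter, the numerical choices, and
what the bundled synthetic benchmark does and does not establish.

## Imaging model and conventions

Tiles are 16-bit monochrome images. The acquisition geometry is a 6.5 µm
camera pixel behind a 40× objective, so one pixel spans
6.5/40 = 0.1625 µm at the sample plane; the instrument never writes this
into file metadata, so the package takes it from configuration
(`pixel_size_um`, default 0.1625). All code uses 1-based `[row, col]`
matrix indexing with the origin at the top-left pixel; CSV outputs map
`x_px` to the column and `y_px` to the row. Candidate centers are real
numbers (mask centroids). Every filter handles borders by mirror padding
(edge pixel included), which avoids the spurious border maxima that zero
padding would create.

Lymphocytes are 7–15 µm across, i.e. 43–92 px in diameter at this scale.
Defocused cells show ring contrast — a bright (or dark) center inside a
rim of opposite polarity — and which polarity appears depends on the
focus direction, which is why the first detection stage is a texture
filter rather than a threshold on intensity.

## The five-stage prefilter

1. **Local SD filter** (`std_window_px`, default 7 px, odd). Each output
   pixel is the population SD of the window around it. The window is kept
   near the rim width: large enough to see the rim's gradient as
   variance, small enough not to bleed adjacent objects together. The
   implementation uses sliding box sums (two cumulative sums per axis),
   identical to the per-window definition up to floating-point error.

2. **Match filter** (`template_radius_px` 20 px, `template_kind`
   `"annulus"`, `annulus_inner_frac` 0.4). The texture response of a cell
   is an elevated region with a quieter core; crucially, the *inner
   transition* of that region sits at a similar radius (roughly 10–25 px)
   across the whole 7–15 µm size range, while the outer extent scales
   with the cell. A single fixed template therefore targets the
   transition: an annulus with outer radius 20 px and a hollow core at
   0.4 of that. During development we found that templates sized to a
   full cell radius (~31 px) swallow a small cell's entire texture band
   inside their hollow core and push the correlation peak off the cell;
   the smaller annulus centers correctly for both extremes. The filter is
   zero-mean normalized cross-correlation over the template support:
   template and window are mean-subtracted, the product is normalized by
   both norms, so flat background scores exactly 0 and output lies in
   [−1, 1]. A `"disc"` template kind is also available — implemented as a
   uniform inner disc (0.7 of the radius) inside a background ring,
   because a disc filling its whole support would be constant and
   zero-mean correlation with a constant template is undefined.

3. **Negative-value thresholding** (`threshold`, default 0). Values below
   max(0, threshold) become 0. With the zero-mean correlation of stage 2,
   this is exactly "remove everything that anti-correlates or matches no
   better than flat background".

4. **Local-maxima identification** (`min_peak_distance_px`, default
   31 px). Strictly positive pixels that are maximal in their
   (2d+1)² neighborhood, then greedy Euclidean suppression so no two
   peaks are closer than d. 31 px is about the median cell radius: one
   cell yields one peak, and two cells whose centers are closer than a
   radius would not be resolvable anyway. Ties are broken by descending
   score, then (row, col) lexicographic order, making the stage fully
   deterministic.

5. **Radial segmentation** (`n_rays` 32, `boundary_frac` 0.2,
   `segment_radius_px` 45, `min_area_px` 150, `max_area_px` 6000,
   `min_center_snr` 5). From each peak, rays are cast over the *original*
   tile. The local background is the median of a thin ring at the
   segmentation radius, and its MAD estimates the local noise. On each
   ray the boundary is the first radius where |intensity − background|
   drops below 0.2 of the center deviation (center deviation taken as a
   3 × 3 mean, robust to single-pixel noise). The mask is the star-shaped
   region under the angularly interpolated boundary. Two gates make the
   stage safe under noise: a peak whose center deviation does not exceed
   `min_center_snr` standard errors of the local noise is dropped (the
   noise-regime reading of "the boundary collapses on a flat image" —
   without it, a contrast-free correlation peak lets rays run arbitrarily
   far), and masks outside the area bounds are dropped (platelet-scale
   specks below 150 px², runaway regions above 6000 px²). Overlapping
   masks are never merged: separating crowded neighbors is the stage's
   purpose. The candidate center is the mask centroid, which recenters
   the broad correlation plateau onto the object.

`detect_candidates()` is the exact composition of the five stages and is
deterministic for fixed input and configuration.

## Features and classification

Each candidate yields 16 features in a frozen order (`feature_names()`):
mask area, equivalent radius, perimeter, circularity, eccentricity; mean,
median, SD, min, max and three quartiles of the masked intensities; ring
contrast (mean intensity in an annulus 1–1.5 equivalent radii from the
centroid minus the inner disc at 0.6); the mean stage-1 texture response
over the mask; and the match-filter peak score. The perimeter is the
4-connected boundary edge count scaled by 0.76, an empirical
Manhattan-to-Euclidean correction calibrated on digital discs so that
disc circularity sits near 1; eccentricity comes from the second moments
of the mask. The feature order is part of the model contract: saved
models embed it and refuse mismatched inputs.

The classifier is a 100-tree random forest (unlimited depth, √p features
per split, bootstrap on), trained on labeled crops with an explicit seed.
Prediction aggregates tree votes and takes a deterministic argmax (first
class wins ties), so a saved and reloaded model reproduces predictions
bit-for-bit. Four categories are distinguished: CAR T-cells, platelets,
RBCs, and debris/anomalous objects ("OTHER"). Evaluation reports the
4 × 4 confusion matrix and one-vs-rest sensitivity/specificity; the CART
row is the assay's operating point. Training uses 150 crops per category
in a 100/50 train/test split by default, matching the assay's labeling
design.

## Calibration and detection limits

Buffer samples follow a power law `y = a·x^b`, fitted by ordinary least
squares of ln y on ln x; whole-blood samples follow `y = a·ln(x) + b`,
fitted on the semilog scale. R² is reported on the fitting scale in both
cases, and the report states the scale. Whole-blood blanks are high
(nonspecifically captured leukocytes); the blank never gets subtracted
from the curve — it enters only through the detection limits, which
keeps the fitted intercept interpretable.

The "95% certainty" limits use a blank-based decision-threshold
construction: the detection threshold on the count scale is
`y_D = blank_mean + 2·z·blank_sd` with z = 1.645 (false-positive and
false-negative rates both 5%, the familiar 3.29σ rule), and the
quantification threshold is `y_Q = blank_mean + 10·blank_sd`. LOD and LOQ
are the concentrations where the fitted curve crosses these thresholds,
solved in closed form (`x = (y/a)^{1/b}` or `x = exp((y−b)/a)`). When the
blank SD is zero (noise-free blanks, as in clean buffer), the fit's
residual SD substitutes, so the limits still reflect measurement spread.
Since 3.29 < 10 and both curve forms are increasing, LOD ≤ LOQ always.
Alternative certainty constructions exist; this one is reproducible and
closed-form, and every report carries the blank statistics and confidence
level so another rule can be applied downstream.

## Fluorescence validation arm

For each brightfield detection, the paired fluorescence ROI yields
SD/median of its pixels — *population* SD, so a constant ROI scores
exactly 0, and the ratio is invariant under multiplicative gain, which is
the point of the normalization (experiments differ in lamp intensity and
exposure). The statistic is computed per cell ROI, not per whole image:
only the per-cell reading produces the histogram over thousands of cells
that the gating needs.

Gating fits a two-component Gaussian mixture by EM, initialized from
k-means (2 centers, 5 restarts, seeded). The gate is the intersection of
the two *weighted* component densities between the means — identical to
the minimum-error Bayes boundary under the fitted priors — found as the
root of a quadratic in closed form (linear when the variances coincide).
Components are ordered by ascending mean to resolve label-swap symmetry.
Numerical guards: densities are floored at the smallest double to keep
the log-likelihood finite; a component SD collapsing below `sd_floor`
(default 1e-4) aborts with an error suggesting a higher floor; inputs
with fewer than 20 values or coincident cluster means are rejected. The
log-likelihood is non-decreasing across iterations (a property test
asserts the trace).

## The synthetic generator

The generator is the package's ground-truth harness. It emulates: the
acquisition geometry (pixel scale, tile size, tiles per scan); Poisson
object counts at configurable per-class densities with a minimum-spacing
constraint; the four object appearances as radial profiles (ring cells
with bright or dark centers, 7–15 µm; small low-contrast platelet blobs,
2–4 µm; biconcave RBC profiles, 6–8 µm; irregular multi-blob debris);
additive Gaussian read noise with 16-bit clamping; paired fluorescence
tiles in which CAR-positive cells carry 3–8 punctate dots inside their
footprint while negatives show only dim autofluorescence; and
calibration count tables with a capture-efficiency and background model
(linear capture for buffer; a saturating `a·ln(1+x)` response for whole
blood, since surface crowding depresses per-cell capture probability at
high load — the reason whole-blood curves are fitted logarithmically).

Default conditions: 512 × 512 test tiles (full 2048 × 2048 by
configuration), background 10 000 counts, ring amplitude 8% of
background, read noise 100 counts (tile SNR 8; detection tests run at
SNR 5 via read noise 160), spiking at 1/10/100/1000 cells/µL in
triplicate, blood blanks of mean 120 ± 15 counts. Placement uses
rejection sampling with restarts and falls back to a jittered grid whose
pitch guarantees the spacing constraint; genuinely impossible
density/spacing combinations raise an error.

What it does **not** emulate: optical physics (no PSF, no shot noise on
the signal, no illumination gradients or vignetting), RBC agglutination
chemistry, adhesion kinetics, CD19⁺ B-cells (indistinguishable from CAR
T-cells in brightfield and a known background source in healthy-donor
blood), or the appearance statistics of real stained residue. Passing
the bundled tests therefore demonstrates the *algorithmic* correctness
and the behavior of the chain under controlled SNR and crowding — it
does not certify performance on real instrument data, for which the
classifier must be retrained on fluorescence-verified real crops.

## Numerical choices

- Filter-stage correctness is held to 1e-9 against brute-force
  sliding-window oracles on random grids; the FFT-based correlation and
  box-sum SD agree with per-window arithmetic to ~1e-15 on unit-scale
  data.
- The match filter's variance floor is relative
  (`varw > 1e-10·(energy+1)`), because FFT round-off in the window
  variance scales with window energy; an absolute floor misclassifies
  flat 16-bit windows as textured.
- Calibration R² is defined as 1 − SS_res/SS_tot on the fitting scale,
  with the flat-response degenerate case (SS_tot = 0) reported as 0.
- The power fit refuses non-positive concentrations or counts (the form
  is undefined there); the log fit refuses non-positive concentrations
  and directs blanks to the LOD machinery instead.
- Seeds: every stochastic operation takes an explicit seed
  (default 20240101); rendering, library building, training, EM and the
  calibration simulator are reproducible bit-for-bit under a fixed seed.

## Problem sizes in the test suite

The suite renders 512² tiles for detection properties (20 tiles of 20
cells for recall, 10 blank tiles for the false-candidate rate), builds
the full 4 × 150 object library for the classifier operating point
(5 seeds), runs 100–200 Monte-Carlo replicates for calibration parameter
recovery, and gates a 1500-cell simulated mixture. Oracle equivalence
runs on ≤ 32 × 32 grids where exhaustive per-pixel checks are exact and
fast. These sizes were chosen as the smallest at which the binomial or
Monte-Carlo error bars are comfortably inside the asserted tolerances.

## Known limitations

- A single fixed match template trades peak sharpness for size
  tolerance; sub-pixel localization and per-scale matched filtering are
  out of scope.
- Tiles are treated as disjoint — no cross-tile deduplication. The scan
  protocol captures abutting fields; if tiles overlapped, counts would
  need a stitching step.
- The forest is trained on synthetic appearances here; the feature
  contract (not the fitted weights) is the portable artifact.
- LOD/LOQ inherit the blank model: with only three blank replicates the
  blank SD is itself noisy, and the limits vary accordingly from run to
  run.
- Whole-image fluorescence statistics, receptor-count calibration (MESF)
  and FCS parsing are out of scope.
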