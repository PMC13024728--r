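---
title: "Methods: quantifying scleral exposure and neck swelling from photographs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying scleral exposure and neck swelling from photographs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(thyrofacemetrics)
```

Hyperthyroidism leaves two visible marks on a frontal photograph:
exophthalmos widens the band of white sclera between the eyelid margin and
the iris, and goiter thickens the anterior neck. This package measures both
from ordinary images, without any trained network: geometry and intensity
statistics do all the work. This vignette explains each procedure, its
assumptions, the tunable constants, and the synthetic phantoms used to
validate everything end to end.

## Periocular cropping

A face-mesh landmark provider (external to the package; any model returning
normalized landmark coordinates works, including file-based JSON) supplies
the canthal anchors: indices 33/133 for the left eye and 362/263 for the
right, two per eye because the eye corners are the most anatomically stable
periocular points. Normalized coordinates map to pixels by
$x_i = \lfloor x^{(n)}_i W \rfloor$, $y_i = \lfloor y^{(n)}_i H \rfloor$,
clamped into the valid index range (the floor lands one past the edge at a
normalized coordinate of exactly 1). The crop box is the min/max extent of
the anchors padded by a fixed margin $m$ (default 50 px) on every side and
clamped to the image; the margin retains the full eyelid contour and
adjacent skin that the scleral measurement needs, and absorbs small
landmark jitter. Crops use half-open slices, so coordinates are 0-based
throughout; a consequence worth knowing is that a landmark sitting exactly
on the padded box's far edge is excluded by the half-open interval, which
is why re-extraction is exactly idempotent only with a positive margin.
Whether $m$ should instead scale with the inter-canthal distance is an open
question; a fixed margin is used because it is what the measurement
convention downstream assumes. An image with no landmarks at all is a
detection failure and the sample is excluded rather than guessed at.

## Sclera map unwrapping

Each eye is measured in a polar ("rubber-sheet") frame around an estimated
pupil center. The center is the raw-moment centroid of the eyelid contour
points — strictly an eye-opening centroid rather than a true pupil center;
for roughly symmetric apertures the two nearly coincide, and all distances
are defined relative to this center, so the convention is internally
consistent. The radial extent is $R_{max} = \lceil D_{max} + \beta \rceil$
where $D_{max}$ is the largest center-to-contour distance and $\beta$
(default 5 px) keeps the eyelid boundary off the raster edge.

The unwrap samples an $H \times W$ raster (default $128 \times 128$): row
$i$ is radius $r_i = i/(H-1) \cdot R_{max}$, column $j$ is angle
$\theta_j = j/(W-1) \cdot \pi$, and intensities are read at
$(c_x + r_i\cos\theta_j,\; c_y \pm r_i\sin\theta_j)$ with bilinear
interpolation, edge clamping, and a luma conversion for color crops.
Because $\arccos$ only covers a half circle, one raster cannot distinguish
the upper from the lower eyelid; the package therefore unwraps **both
hemispheres** (the $\pm$ above) and measures every boundary point in the
raster of its own hemisphere, decided by the sign of its vertical offset
from the center (image rows grow downward, so $\Delta y > 0$ is the lower
eyelid).

Twelve reference points on the eyelid boundary, labeled `L0`–`L11` (or
`R0`–`R11`), map into the unwrapped frame by
$u = \theta_{1/2}/\pi\,(W-1)$ and $v = \mathrm{clamp}(r/R_{max}, 0, 1)(H-1)$
with $\theta_{1/2} = \arccos(\Delta x / r)$. When the caller does not
supply them, the package places six rays per hemisphere at
$\theta_{1/2} = (j + 0.5)\,\pi/6$ and intersects them with the contour
polygon (piecewise-linear), labeling positions around the eye: along the
upper eyelid with increasing angle, then back along the lower eyelid. The
placement rule is a package decision — the twelve positions are a
convention, and user-supplied points override it.

The iris onset along a reference column is the row of maximum intensity
contrast between a window of $\omega_a$ rows above and $\omega_b$ rows
below a candidate row (defaults 3 each; setting 1 reproduces a single-pixel
comparison). The contrast is the absolute difference of the two window
means; windows are truncated at the raster edge, the search runs from
$\omega_a$ up to one row inside the boundary point, and ties break toward
the larger row (the eyelid side). A column whose best contrast falls below
`min_contrast` (default 10 on the 8-bit scale, rejecting essentially flat
columns) yields a **missing** position, reported as such and never imputed
as zero. The scleral distance at position $j$ is then $d_j = |v_j - y^*_j|$
in unwrapped rows.

Profile comparison (patient vs. reference eye) takes signed per-position
differences, their total and mean, and the position of the largest absolute
difference (first label on ties); positions missing in either profile are
excluded and the count actually used is reported, so the mean is always
over positions compared. The comparison is antisymmetric by construction.

## Neck width profiling and the four indices

The neck pipeline consumes two detection boxes — the upper ("top-neck") and
lower ("low-neck") segments, in YOLO label format or as pixel boxes; an
optional whole-neck box is accepted but never used. The vector between the
box centers defines the neck axis. The image is rotated about the centers'
midpoint so the axis points straight down and scaled so its length is
`Lref` (default 200 px), with bilinear resampling onto a padded canvas and
a constant non-skin fill. Rotating the axis to vertical (rather than
horizontal) is deliberate: the width profile is defined across image rows,
so "width at level $y$" only makes sense with a vertical axis. The
horizontal variant is available as `mode = "literal"` for completeness.
Boxes are carried into the aligned frame by transforming their centers
exactly and scaling their extents; taking the axis-aligned hull of rotated
corners instead would inflate the region of interest with the incidental
camera rotation and make the band positions (below) orientation-dependent.

The region of interest is the union of the two boxes expanded by a
fractional margin (default 0.10) per side and clamped to the canvas. Inside
it, the luminance channel is contrast-normalized with CLAHE (clip limit 2,
8×8 tiles — the library defaults for this operator), skin pixels are
selected by a chroma box in YCrCb (Cr ∈ [133, 173], Cb ∈ [77, 127], the
standard photographic skin range; a luminance band is the fallback for
grayscale input), and the binary mask is cleaned by morphological opening
then closing with a 5-px elliptical element, keeping the largest connected
component. CLAHE operates on luminance only, so the chroma criterion is
unaffected by illumination normalization — which is the point of applying
it first.

The width profile samples $S = 60$ rows at
$y_i = \mathrm{round}(i\,(h-1)/(S-1))$ (round-half-up, so indices are
deterministic). On each row with mask pixels, the width is
$W = x_R - x_L + 1$ between the outermost mask columns, split about the
fixed ROI midline $x_m = (\text{width}-1)/2$ — the midline is deliberately
not the per-row mask centroid, otherwise asymmetry would be invisible.
Rows without mask pixels are flagged invalid and skipped everywhere. Band
means use rows 10–20% (top) and 80–90% (bottom) of the grid with
round-half-up index bounds; a band with no valid rows is an error rather
than a silent pass, and the bottom mean is guarded to at least 1. The
linear baseline interpolates the widths of the first and last valid
sampled rows, and $\mathrm{dev} = \max(W - W_{lin}, 0)$ is the positive
bulge deviation. The four indices are

* **TLR** $= W_{top}/W_{bot}$ — top-to-low width ratio;
* **BPI** $= \max(\mathrm{dev})/W_{bot}$ — bulge peak index;
* **BAR** $= \mathrm{mean}(\mathrm{dev})/W_{bot}$ — bulge area ratio;
* **ASR** $= \sum|W_L - W_R| \,/\, \sum(W_L + W_R)$ — asymmetry ratio.

All four are unitless ratios, which is what makes them invariant to
uniform scale and (with the alignment) to rotation.

## Ensemble thresholding

`nset_calibrate()` fits the decision model: per metric, the sample mean
$\mu_m$ and sample standard deviation $\sigma_m$ (denominator $n-1$) over a
cohort of normal necks define $\theta_m = \mu_m + k\,\sigma_m$ with $k = 2$
by default. A new image casts one vote per metric that **strictly** exceeds
its threshold (equality does not vote) and is called Swollen when at least
$q = 2$ of the four votes are cast. The quorum makes the rule robust to a
single noisy index; $k = 2$ puts each threshold two standard deviations
above the normal mean, so under roughly Gaussian variation each metric
alone fires on ~2% of normals and two simultaneous votes are rare.
Thresholds should be recalibrated whenever imaging conditions, devices or
the population change; no drift detection is attempted. `print()`,
`summary()` and `predict()` methods expose the fitted thresholds in the
usual modelling idiom.

## Synthetic phantoms and what they do (and do not) show

Clinical images cannot ship with the package, so every end-to-end claim is
validated on phantoms with closed-form ground truth.

The **eye phantom** renders concentric pupil and iris discs inside an
eyelid region whose radius varies with angle, on a skin background with
binary (non-anti-aliased) edges so the truth stays exact. The twelve
boundary points sit at full-circle angles $(j+0.5)\cdot 30°$ with radii
mirrored across both axes; the mirror symmetry pins the contour centroid to
the disc center exactly, which is what makes the analytic distance
$d_j = (r_j - \rho_i)/R_{max}\,(H-1)$ hold for the same $\beta$ and $H$ the
engine uses. Randomized phantoms draw the iris radius (14–26 px), three
eyelid radius groups (38–62 px) and a center jitter of ±6 px. Default
intensities (sclera 230, iris 60, pupil 20, skin 150) are separated far
beyond the onset detector's contrast floor.

The **neck phantom** renders a vertical skin-colored neck on white whose
width profile is a linear taper plus an optional Gaussian bulge
(amplitude expressed as a fraction of the bottom width, center and spread
in normalized height) and an optional constant lateral shift of the neck
relative to the detection-box axis. Boxes sit over the 15–30% and 70–85%
height bands, centered on the unshifted axis and sized so the
margin-expanded ROI stays inside the canvas — with the ROI touching the
padded canvas edge, boundary resampling corrupts the rows that anchor the
linear baseline. Analytic metrics are computed from the continuous width
function on exactly the $S$-point grid, ROI and midline the pipeline will
use, so measured and analytic values are comparable number for number; at
the default geometry the measured indices agree with the analytic ones to
about 0.01. The reference cohort draws top widths from 85–115 px, bottom
widths from 135–170 px, lateral jitter ±3 px and pixel noise of 2, which
stands in for the natural anthropometric variation of non-swollen necks.

What passing phantom tests does **not** show: robustness to real skin-tone
diversity outside the default chroma box (the range is configurable and
should be re-validated per population), to shadows, hair, jewellery or
clothing occluding the neck, to specular reflections and eyelashes in eye
crops, or to landmark/detector error — phantom boxes and contours are
exact. The phantoms validate the measurement geometry and the decision
arithmetic, not the upstream detectors.

## Numerical choices and degenerate inputs

* Rounding of sampled indices is half-up (`floor(x + 0.5)`), never
  half-to-even, so grids are reproducible.
* Bilinear sampling clamps to the nearest edge pixel inside an image;
  alignment fills truly out-of-source pixels with a constant non-skin
  value instead, so background never bleeds into the mask.
* Degenerate inputs fail loudly with classed conditions: empty landmark
  sets, boxes that clamp to nothing, contours under three points,
  coincident box centers, all-flat columns, empty masks and cohorts under
  two images each have a dedicated error class.
* CLAHE on a constant plane is a no-op (the equalizer is undefined there),
  and tile counts shrink automatically for small regions.
* JSON round-trips serialize doubles at 17 significant digits; profile
  CSVs likewise, so written artifacts reproduce in-memory values
  bit-exactly.

## Problem sizes used in the shipped checks

The test-suite and acceptance computations use 50 randomized eye phantoms
for distance recovery, 20 random crops for the unwrap-versus-oracle
comparison, a calibration cohort of 30 normal neck phantoms and fresh
batches of 100 normal and 100 large-bulge phantoms for decision behavior,
and 200 random score sets for the AUROC equivalence. These sizes give
stable rates (the binomial standard error on a 100-phantom rate is about
2–4 points) while keeping a full run within a coffee break.

## Known limitations

The eye-opening centroid drifts from the true pupil center for strongly
asymmetric apertures, biasing radii on one side; the twelve-position
convention is a sampling of the eyelid, not a segmentation of the sclera;
the skin chroma box is a blunt instrument compared to learned skin
segmentation; and the ensemble rule is intentionally simple — it trades
sensitivity to subtle, single-index presentations for robustness and
auditability. Classification of the resulting measurements into clinical
labels is out of scope by design: the package reports quantities, and
decisions belong to clinicians or downstream classifiers.
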