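---
title: "Quantifying macrosteatosis from ocular-captured biopsy images: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying macrosteatosis from ocular-captured biopsy images}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(steatoscope)
```

## The measurement problem

Donor-liver macrosteatosis above roughly 30% is a common reason to decline a
graft, yet the intraoperative gold standard — a frozen section read quickly by
whichever pathologist is available — is notoriously rater-dependent. Frozen
sectioning also introduces tears and exposes vascular lumina, both of which
are unstained white areas that mimic lipid droplets. This package implements
a deterministic pixel-counting pipeline for low-resolution RGB captures
(nominally 640×480 at 20x, photographed through a microscope ocular), and the
agreement statistics needed to compare its scores with human estimates.

The core assumption is chromatic: H&E tissue is pink (high red, moderate
green/blue), everything that matters for the numerator is white (high in all
channels), and the ocular vignette is near-black. The pipeline never uses
absolute colour calibration; every image contributes its own thresholds.

## Pipeline and parameters

`segment_image()` runs, in order: vignette detection, per-image green/blue
thresholding, binarization, erosion, background rejection, watershed,
first-pass classification, restoring dilation, second watershed and
classification. All constants live in `seg_config()`; the defaults are:

| parameter | default | role |
|---|---|---|
| `lower_bound` | 100 | histogram peaks at or below this intensity are ignored; must separate the pink-tissue modes (typically 110–170 in green) from dark nuclei and vignette |
| `smooth_window` | 5 bins | moving-average smoothing before peak finding, suppressing single-bin noise peaks |
| `combine` | `"and"` | a pixel is white only if green *and* blue reach their thresholds |
| `darkness_cutoff` | 40 | max-channel intensity below which a pixel can belong to the vignette |
| `kernel_radius`, `erosion_iterations` | 1, 1 | 3×3 square structuring element, one pass, mirrored by the restoring dilation |
| `ca_hard_max` | 2000 px | white regions larger than any macrosteatotic droplet are background |
| `ca_soft_max`, `c1_background_min` | 600 px, 0.3 | large *and* elongated regions (lumina) are background |
| `first_area_min/max`, `first_c1_min` | 2–1999 px, 0.2 | first-pass droplet band (area inclusive, circularity strict) |
| `second_area_min/max`, `second_c2_min` | 2–499 px, 0.7 | stricter second-pass band after dilation |
| `ws_tolerance`, `ws_ext` | 1, 2 | watershed seed suppression on the distance map |
| `rescale` | TRUE | area thresholds scale linearly with image area relative to 640×480; circularities are scale-free |

Area thresholds are in raw pixels; no physical-unit conversion is attempted
(the droplet bands encode the 20x magnification directly).

### Binarization choices

The published description of the threshold rule names "the mean of the two
highest peaks" per channel without fixing the peak detector, the AND/OR
combination across channels, or the lower bound. The choices here:

* **Peak detector.** The histogram is smoothed (centred moving average,
  partial windows at the ends so a saturated-white spike at 255 keeps its
  boundary maximum), runs of equal counts are collapsed, and a peak is a run
  strictly higher than both neighbouring runs. A plateau peak takes its
  centre bin; even-length plateaus round toward higher intensity, and ties
  between equal-height peaks are broken toward higher intensity. With a
  single qualifying peak the threshold is that peak's position; with no mass
  above the lower bound the image is rejected as a no-tissue field.
* **AND across channels.** The phrasing "blue or green intensity below the
  threshold … black" is ambiguous between conjunction and disjunction of
  whiteness. AND is the default because pink tissue can have moderately high
  green *or* blue alone, while genuine white space is high in both; the OR
  variant remains available via `combine = "or"`.
* **Lower bound 100.** Chosen so that the pink-tissue modes of plausible
  stain/exposure variation stay above it while nuclei (~60–110 max-channel)
  and vignette pixels stay below; exposed in the configuration because
  unusually pale stains may need a higher value.

### Geometry: circularities, enclosing circles, perimeters

Two dimensionless descriptors drive the filters. `C1 = CA / MECA` compares a
region's pixel count with the area of its minimum enclosing circle; `C2 =
2·sqrt(π·A) / P` compares its circle-equivalent circumference with its actual
perimeter. Both equal 1 for an ideal disk. Digitization details matter at
droplet scale (tens to hundreds of pixels):

* **MECA over pixel corners.** A region is the union of unit pixel squares,
  so the enclosing circle is computed over the 4 corner points of each pixel
  (reduced to the convex hull, then Welzl's construction, which is exact).
  This makes C1 of a digital square equal 2/π to machine precision — the
  analytic value — where a pixel-centre computation overestimates by ~10% on
  a 20×20 square. Correctness is cross-checked in the tests against an
  O(h³) brute-force enumeration of diametral and circumscribed candidate
  circles over the hull.
* **Perimeter.** The boundary is traced through pixel centres as a closed
  8-chain and measured with the Vossepoel–Smeulders corrected length
  (0.980 per axial step, 1.406 per diagonal step, −0.091 per direction
  change), plus π for the half-pixel outward offset of the true region
  outline relative to the centre chain (a convex outline grown by half a
  pixel gains 2π·½ of perimeter). An uncorrected chain length would leave C2
  of large digital disks stuck near 0.95 and push few-pixel blobs above 1.3;
  with the correction C2 of digital disks approaches 1 from below as the
  radius grows and stays within a 0.1 discretization tolerance down to
  single-pixel regions (a single pixel is defined as circle-equivalent,
  C2 = 1).
* **Connectivity.** White regions are 8-connected. The labeller merges
  diagonally touching 4-connected components with a union-find pass, and is
  validated against a brute-force flood fill.

### Watershed

Clustered droplets present as one white mass that the size/elongation rules
would misread as an artifact if it grew large enough. The watershed of the
Euclidean distance map splits such masses along ridges between distance
maxima. `ws_tolerance = 1` (minimum seed height) and `ws_ext = 2` (seed
suppression radius) leave isolated disks unsplit while separating abutting
pairs whose centres are more than about one radius apart; every white pixel
is assigned to exactly one region, so the split conserves pixels exactly.

Note an ordering consequence: background rejection runs before the first
watershed, so a sufficiently large merged mass (contour area above
`ca_hard_max`, or elongated above `ca_soft_max`) is discarded *before* the
watershed could separate it. This is intrinsic to the filter-then-separate
design; it only matters in fields where many droplets chain into one
>2000 px mass, and it biases such extreme fields downward (never upward).

### The steatosis fraction

Per image, the score is `100 · fat / tissue` with `tissue` = non-border
pixels that binarized black, plus the accepted fat pixels. White pixels that
were *rejected* (tears, lumina, background, failed droplets) belong to
neither count — the same convention as the green/(green+black) strict
estimate on control images, which deliberately excludes gray
neither-tissue-nor-fat areas. `strict_estimate_from_control()` and the
pipeline therefore share one denominator philosophy, and the tests assert
their agreement on control phantoms.

Per liver, `liver_steatosis_score()` computes the mean and *sample* standard
deviation of all image scores once, retains scores in the closed interval
[m − s, m + s], and averages the retained set. The omission is deliberately
single-pass — an iterative trim would be a different statistic — and the
retained set is provably never empty. Sample (n−1) SD and closed boundaries
are declared choices; nothing in the published description fixes them.

## Agreement statistics

`icc_two_way()` implements the single-rater two-way mixed-effects ICC from
the ANOVA mean squares, in both the consistency variant
((MSR − MSE) / (MSR + (k−1)·MSE)) and the absolute-agreement variant (which
adds the rater variance term k·(MSC − MSE)/n to the denominator), with exact
F-based 95% bounds (Satterthwaite degrees of freedom for the absolute
variant). Which flavour a published "2-way mixed-effects ICC" denotes is
often unstated; on the packaged control-image table the consistency variant
reproduces the published point estimates and CI bounds, so it is the default
and the absolute variant is reported alongside. Negative lower CI bounds are
reported raw and clipped at 0 (the usual display convention).

The lower bound is clipped only for display; inference uses the raw value.
Pearson correlation and OLS wrap `stats::cor.test()` and `stats::lm()`.
`threshold_disagreement_count()` counts subjects where at least one rater is
strictly above and one at or below the clinical threshold (default 30%).

## What the phantoms emulate — and what they do not

`generate_he_phantom()` renders: pink tissue (base RGB 200/130/150, per-image
uniform jitter ±25 per channel — this is what forces the thresholds to adapt
per image — and per-pixel Gaussian noise, sd 6), dark nuclei speckle at 2%
density, white droplets (radius 4–11 px by default, i.e. areas ~50–380 px,
inside the droplet bands), sparse single-pixel white speckle (erosion
fodder), optional tears (irregular disk unions above the 2000 px hard cap),
optional lumina (ellipses of aspect 5–8, area 800–1600 px, so C1 < 0.3),
and an optional circular vignette. With `clustering` > 0, droplets form
partially overlapping *pairs* of similar radii with two resolvable lobes —
the configuration a watershed can in principle separate; truly concentric
droplet stacks are not generated because no pixel-based method could count
them. The rendered truth (droplet pixels over droplet + tissue pixels) is
recorded exactly from pixel counts, never from the requested target.

`generate_control_phantom()` renders exact-colour green/black/gray images,
so the strict estimate recovers the stored truth bit-exactly.

Deliberately *not* emulated: real H&E texture (sinusoids, chromatin,
staining gradients), optical blur and droplet edge gradients, compression
artifacts, uneven illumination, and microsteatosis. Passing the phantom
suite therefore demonstrates the pipeline's geometric and arithmetic
correctness under the stated colour model — not clinical accuracy on real
slides, which requires validation against expert reads.

## Degenerate inputs and determinism

Grayscale images are promoted to three identical channels with a warning;
16-bit inputs are rescaled to 8-bit. Frames whose usable field (after
vignette exclusion) is below 1% of pixels, or whose histograms carry no mass
above the lower bound, raise a "no-tissue" error; batch runs log and skip
such images rather than aborting. Non-640×480 frames warn and rescale the
area thresholds linearly (disable with `rescale = FALSE`). Everything is
deterministic: identical image and configuration give a bit-identical mask,
and phantoms are fully reproducible from one integer seed.

## Problem sizes in the test and acceptance suites

The validation suites run 50 H&E phantoms (full 640×480 frames with two
tears, one lumen, vignette and clustering 0.3, truths spread over 0–30%) and
20 control phantoms for ground-truth recovery, 100 random regions for the
enclosing-circle brute-force cross-check, and 1000 random score lists for
the outlier-rule properties — sizes chosen so the whole suite exercises
every stage at realistic scale while remaining comfortable to run on a
laptop.

## Known limitations

* Micro- versus macrosteatosis is not distinguished; both count as fat.
* Scores are per-field; no whole-slide stitching or field-selection logic.
* The 30% clinical threshold analyses treat the threshold as exogenous; the
  package does not recalibrate pipeline scores to pathologist scales, though
  `linear_fit()` provides the per-rater slopes such a calibration would use.
* Extremely confluent steatosis (single masses above the hard area cap) is
  underestimated by design, as discussed under the watershed ordering note.
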