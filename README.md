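# steatoscope

Automated quantification of hepatic macrosteatosis from low-resolution RGB
images of H&E-stained frozen-section liver biopsies — the kind captured by
holding a smartphone to the ocular of a standard light microscope during organ
procurement. The package is aimed at transplant researchers and pathology
groups who need a fast, deterministic, non-machine-learning steatosis score at
the point of care, plus the agreement statistics used to compare such scores
with pathologist estimates.

## The algorithm

Lipid droplets, vascular lumina, tears and slide background do not take up
H&E stain and appear white; tissue is pink. Each image is segmented
independently:

1. **Vignette exclusion.** The black ring and out-of-field area left by the
   ocular are detected (largest bright connected component, holes filled) and
   excluded from all pixel accounting.
2. **Adaptive binarization.** For the green and blue channels separately
   (red carries no signal), the intensity histogram is smoothed and the
   threshold is the mean of its two highest peaks above a lower bound
   (default 100) — the tissue mode and the white-space mode. A pixel is white
   when both channels reach their thresholds.
3. **Erosion.** A 3×3 morphological erosion removes speckle noise that can
   mimic tiny droplets.
4. **Background rejection.** For each contiguous white region, the contour
   area CA and the circularity C1 = CA / MECA (MECA = area of the minimum
   enclosing circle) are computed. Regions with CA > 2000 px, or CA > 600 px
   with C1 < 0.3, are non-tissue background (tears, lumina, slide) and are
   removed. Thresholds are calibrated for 640×480 frames at 20x and scale
   with image area.
5. **Watershed.** Clustered droplets merge into one white mass; the watershed
   of the distance transform splits them into individual globules.
6. **First-pass classification.** A region is potentially a droplet if
   2 ≤ CA ≤ 1999 (inclusive) and C1 > 0.2.
7. **Restoring dilation.** A matching 3×3 dilation, intersected with the
   pre-erosion white set, restores droplet boundary pixels removed in step 3.
8. **Second pass.** After a second watershed, a region is a droplet if
   2 ≤ A ≤ 499 (inclusive) and C2 > 0.7, where C2 = 2·sqrt(π·A) / P with P
   the contour perimeter.

Per image, `steatosis % = 100 · fat pixels / tissue pixels`, where tissue =
non-border binarized-black pixels + accepted fat (rejected white regions
count as neither). Per liver, image scores are averaged after a single-pass
omission of scores outside mean ± 1 SD.

The package also provides two-way mixed-effects single-rater intraclass
correlation (consistency and absolute-agreement variants, exact F-based 95%
CIs), Pearson correlation, OLS calibration fits, the count of subjects with
rater scores straddling the 30% transplant threshold, and a synthetic phantom
generator (H&E-like fields and three-colour control images) with exact pixel
ground truth.

## Worked example

```r
library(steatoscope)

# a synthetic 640x480 biopsy field: ~12% fat, clustered droplets, two tears,
# one vascular lumen, vignette border
ph  <- generate_he_phantom(phantom_spec(target_fat_fraction = 0.12,
                                        clustering = 0.3, tears = 2,
                                        lumina = 1, seed = 42))
ph$truth$fat_fraction_percent
#> [1] 12.1662

seg <- segment_image(ph$image)
seg
#> <steatosis_segmentation>
#>   frame: 640 x 480 px (border excluded: 135212 px)
#>   thresholds: green 185.5, blue 207.5
#>   accepted droplets: 116
#>   fat 19705 / tissue 162443 px -> steatosis 12.13%
```

The adaptive thresholds (green 185.5, blue 207.5) sit between this image's
tissue and white-space modes; the tears and the lumen were rejected by the
size/circularity rules, and the recovered fraction (12.13%) is within 0.04
percentage points of the rendered truth.

```r
liver_steatosis_score(c(11.2, 12.5, 13.1, 30.4), liver_id = "donor-07")
#> <liver_score> donor-07
#>   4 images, 3 retained (mean 16.80, sd 9.10)
#>   final steatosis: 12.27%
```

The 30.4% outlier lies outside mean ± 1 SD and is omitted before averaging.

Rater agreement on the packaged 10-image control table:

```r
t1 <- lp_estimates_table()
icc_two_way(t1[, c("LP1_strict", "LP2_strict", "LP3_strict")])
#> ICC 0.651 (95% CI, 0.29-0.89)  [two-way mixed effects, consistency, single rater]
#>   F(9, 18) = 6.597, p = 0.0003567; 10 subjects x 3 raters
```

A command-line wrapper with `score`, `phantom` and `agreement` subcommands is
installed at `inst/cli/steatoscope.R`.

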