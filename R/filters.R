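#' Remove non-tissue background regions
#'
#' White regions larger than any macrosteatotic droplet are slide background,
#' tears, or vascular lumina, not fat. A region is discarded when
#' `CA > ca_hard_max`, or when `CA > ca_soft_max` and `C1 < c1_min`
#' (large and elongated). All other regions pass unchanged; the filter is
#' idempotent.
#'
#' @param regions Data frame with at least `CA` and `C1` columns (as from
#'   [label_regions()]).
#' @param ca_hard_max,ca_soft_max,c1_min Rule thresholds; defaults are
#'   calibrated for 640x480 frames at 20x magnification.
#' @return The retained subset of `regions` (attributes preserved).
#' @export
filter_nontissue_background <- function(regions, ca_hard_max = 2000,
                                        ca_soft_max = 600, c1_min = 0.3) {
  keep <- !(regions$CA > ca_hard_max |
              (regions$CA > ca_soft_max & regions$C1 < c1_min))
  subset_regions(regions, keep)
}

#' First-pass droplet classification
#'
#' After watershed separation, a region is potentially a steatotic droplet if
#' its area lies in `[area_min, area_max]` (inclusive) and `C1 > c1_min`
#' (strict).
#'
#' @param regions Data frame with `CA` and `C1` columns.
#' @param area_min,area_max Inclusive area band (pixels).
#' @param c1_min Strict circularity gate.
#' @return The accepted subset of `regions`.
#' @export
classify_fat_first_pass <- function(regions, area_min = 2, area_max = 1999,
                                    c1_min = 0.2) {
  keep <- regions$CA >= area_min & regions$CA <= area_max &
    regions$C1 > c1_min
  subset_regions(regions, keep)
}

#' Second-pass droplet rule on a region table
#'
#' The stricter rule applied after dilation and re-watershed: area in
#' `[area_min, area_max]` (inclusive) and perimeter circularity
#' `C2 > c2_min` (strict).
#'
#' @param regions Data frame with `CA` and `C2` columns.
#' @param area_min,area_max Inclusive area band (pixels).
#' @param c2_min Strict `C2` gate.
#' @return The accepted subset of `regions`.
#' @export
classify_fat_second_pass <- function(regions, area_min = 2, area_max = 499,
                                     c2_min = 0.7) {
  keep <- regions$CA >= area_min & regions$CA <= area_max &
    regions$C2 > c2_min
  subset_regions(regions, keep)
}

#' Second-pass refinement of the dilated droplet mask
#'
#' Re-runs the watershed on the dilated first-pass mask, recomputes geometry,
#' and keeps regions with area in `[area_min, area_max]` (inclusive) and
#' perimeter circularity `C2 > c2_min` (strict). The union of kept regions is
#' the final fat mask.
#'
#' @param mask Logical matrix: the dilated first-pass droplet mask.
#' @param area_min,area_max Inclusive area band (pixels).
#' @param c2_min Strict `C2` gate.
#' @param ws_tolerance,ws_ext Passed to [watershed_separate()].
#' @return List with `mask` (final logical fat mask) and `regions` (geometry
#'   data frame of accepted droplets).
#' @export
refine_second_pass <- function(mask, area_min = 2, area_max = 499,
                               c2_min = 0.7, ws_tolerance = 1, ws_ext = 2) {
  labels <- watershed_separate(mask, tolerance = ws_tolerance, ext = ws_ext)
  regions <- label_geometry(labels, what = "all")
  kept <- classify_fat_second_pass(regions, area_min, area_max, c2_min)
  final <- matrix(FALSE, nrow(mask), ncol(mask))
  pix <- attr(kept, "pixels")
  if (length(pix)) final[unlist(pix, use.names = FALSE)] <- TRUE
  list(mask = final, regions = kept)
}

# subset a region table, keeping the parallel pixel list in sync
subset_regions <- function(regions, keep) {
  out <- regions[keep, , drop = FALSE]
  pix <- attr(regions, "pixels")
  if (!is.null(pix)) attr(out, "pixels") <- pix[keep]
  lab <- attr(regions, "labels")
  if (!is.null(lab)) attr(out, "labels") <- lab
  rownames(out) <- NULL
  out
}

# paint the pixels of a region table onto a blank logical matrix
regions_to_mask <- function(regions, dims) {
  m <- matrix(FALSE, dims[1], dims[2])
  pix <- attr(regions, "pixels")
  if (length(pix)) m[unlist(pix, use.names = FALSE)] <- TRUE
  m
}
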