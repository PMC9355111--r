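#' Segment steatotic droplets in a biopsy image
#'
#' Runs the full pipeline on one RGB image: vignette-border detection,
#' per-image adaptive green/blue thresholding, binarization, morphological
#' erosion, non-tissue background rejection, watershed separation, first-pass
#' area/circularity classification, restoring dilation, and a stricter second
#' watershed-and-filter pass. Area thresholds are calibrated for 640x480
#' frames at 20x magnification and (by default) rescale linearly with image
#' area for other frame sizes, with a warning.
#'
#' @param image RGB image: file path, EBImage `Image`, or 0-255 array.
#' @param config A [seg_config()] object.
#' @param keep_stages If `TRUE`, intermediate masks (binarized, eroded,
#'   background-filtered, first-pass, dilated) are kept for inspection.
#' @param image_id Optional identifier carried into the result.
#' @return An object of class `steatosis_segmentation`: a list with
#'   `final_mask`, `border`, `fat_pixels`, `tissue_pixels`,
#'   `steatosis_percent`, `regions` (geometry of accepted droplets),
#'   `thresholds`, `area_scale`, `config`, `dim`, and optionally `stages`.
#' @seealso [image_steatosis_fraction()], [liver_steatosis_score()]
#' @export
segment_image <- function(image, config = seg_config(), keep_stages = FALSE,
                          image_id = NULL) {
  validate_seg_config(config)
  rgb <- as_rgb255(image)
  dims <- dim(rgb)[1:2]

  scale <- 1
  if (config$rescale &&
      !(dims[1] == config$reference_width && dims[2] == config$reference_height)) {
    scale <- (dims[1] * dims[2]) /
      (config$reference_width * config$reference_height)
    warning(sprintf(
      "image is %dx%d, not %dx%d: area thresholds rescaled by factor %.3f",
      dims[1], dims[2], config$reference_width, config$reference_height, scale))
  }

  border <- detect_vignette_border(rgb, config$darkness_cutoff)
  n_field <- sum(!border)
  if (n_field < config$min_tissue_fraction * length(border))
    stop("no-tissue/empty-field image: usable field below ",
         config$min_tissue_fraction * 100, "% of the frame")

  thr <- channel_thresholds(rgb, border, config$lower_bound,
                            config$smooth_window)
  binarized <- binarize_image(rgb, thr, border, config$combine)

  eroded <- erode_binary(binarized, config$kernel_radius,
                         config$erosion_iterations)

  regions0 <- label_regions(eroded, what = "C1")
  regions1 <- filter_nontissue_background(
    regions0,
    ca_hard_max = config$ca_hard_max * scale,
    ca_soft_max = config$ca_soft_max * scale,
    c1_min = config$c1_background_min)
  bg_mask <- regions_to_mask(regions1, dims)

  ws <- watershed_separate(bg_mask, config$ws_tolerance, config$ws_ext)
  regions2 <- label_geometry(ws, what = "C1")
  regions3 <- classify_fat_first_pass(
    regions2,
    area_min = config$first_area_min,
    area_max = config$first_area_max * scale,
    c1_min = config$first_c1_min)
  first_mask <- regions_to_mask(regions3, dims)

  dilated <- dilate_restore(first_mask, binarized, config$kernel_radius,
                            config$erosion_iterations)

  second <- refine_second_pass(
    dilated,
    area_min = config$second_area_min,
    area_max = config$second_area_max * scale,
    c2_min = config$second_c2_min,
    ws_tolerance = config$ws_tolerance, ws_ext = config$ws_ext)

  fat <- sum(second$mask)
  # liver tissue = non-border pixels that binarized black, plus accepted fat;
  # rejected white pixels (tears, lumina, background) stay out of both counts
  tissue <- sum(!binarized & !border) + fat

  out <- list(
    image_id = image_id,
    final_mask = second$mask,
    border = border,
    fat_pixels = fat,
    tissue_pixels = tissue,
    steatosis_percent = if (tissue > 0) 100 * fat / tissue else NA_real_,
    regions = second$regions,
    thresholds = thr,
    area_scale = scale,
    config = config,
    dim = dims
  )
  if (keep_stages)
    out$stages <- list(binarized = binarized, eroded = eroded,
                       background_filtered = bg_mask,
                       first_pass = first_mask, dilated = dilated)
  class(out) <- "steatosis_segmentation"
  out
}

#' @export
print.steatosis_segmentation <- function(x, ...) {
  cat("<steatosis_segmentation>",
      if (!is.null(x$image_id)) paste0(" ", x$image_id), "\n", sep = "")
  cat(sprintf("  frame: %d x %d px (border excluded: %d px)\n",
              x$dim[1], x$dim[2], sum(x$border)))
  cat(sprintf("  thresholds: green %.1f, blue %.1f\n",
              x$thresholds$green_threshold, x$thresholds$blue_threshold))
  cat(sprintf("  accepted droplets: %d\n", nrow(x$regions)))
  cat(sprintf("  fat %d / tissue %d px -> steatosis %.2f%%\n",
              x$fat_pixels, x$tissue_pixels, x$steatosis_percent))
  invisible(x)
}

#' @export
summary.steatosis_segmentation <- function(object, ...) {
  print(object)
  if (nrow(object$regions)) {
    cat("  droplet area (px): ")
    print(summary(object$regions$CA))
  }
  invisible(object)
}

#' Display the segmentation overlay
#'
#' @param x A `steatosis_segmentation` object.
#' @param image The source image (required to draw the overlay).
#' @param ... Passed to [graphics::rasterImage()] via EBImage display.
#' @export
plot.steatosis_segmentation <- function(x, image = NULL, ...) {
  if (is.null(image)) {
    EBImage::display(EBImage::Image(x$final_mask * 1), method = "raster", ...)
  } else {
    rgb <- as_rgb255(image) / 255
    green <- c(0.1, 0.85, 0.2); alpha <- 0.6
    for (ch in 1:3) {
      plane <- rgb[, , ch]
      plane[x$final_mask] <- (1 - alpha) * plane[x$final_mask] + alpha * green[ch]
      rgb[, , ch] <- plane
    }
    EBImage::display(EBImage::Image(rgb, colormode = "Color"),
                     method = "raster", ...)
  }
  invisible(x)
}
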