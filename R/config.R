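#' Segmentation configuration
#'
#' Collects every numeric constant used by [segment_image()] with the defaults
#' stated for 640x480 images at 20x magnification. Unknown keys are rejected so
#' no threshold can hide outside the configuration.
#'
#' @param lower_bound Intensity floor (0-254) below which histogram peaks are
#'   ignored when computing the adaptive green/blue thresholds. The tissue and
#'   white-space intensity modes must straddle it.
#' @param smooth_window Moving-average window (bins) applied to the intensity
#'   histogram before peak finding.
#' @param combine `"and"` (default) labels a pixel white only when both the
#'   green and blue channels reach their thresholds; `"or"` when either does.
#' @param darkness_cutoff Max-channel intensity below which a pixel counts as
#'   part of the black vignette border.
#' @param kernel_radius Radius of the square structuring element used for
#'   erosion and the matching restoring dilation (1 = 3x3).
#' @param erosion_iterations Erosion/dilation iteration count.
#' @param ca_hard_max Contour area above which a white region is always
#'   discarded as non-tissue background (tears, slide background).
#' @param ca_soft_max Contour area above which a region is discarded when its
#'   circularity `C1` is also below `c1_background_min` (vascular lumina).
#' @param c1_background_min Circularity floor for the soft background rule.
#' @param first_area_min,first_area_max Inclusive contour-area band of the
#'   first-pass droplet classification.
#' @param first_c1_min First-pass circularity gate; regions must have
#'   `C1 > first_c1_min` (strict).
#' @param second_area_min,second_area_max Inclusive area band of the stricter
#'   second-pass classification applied after dilation and re-watershed.
#' @param second_c2_min Second-pass perimeter-based circularity gate
#'   (`C2 > second_c2_min`, strict).
#' @param ws_tolerance,ws_ext Watershed parameters: minimum height of a
#'   distance-map object and the neighbourhood radius used to suppress nearby
#'   seed maxima.
#' @param rescale If `TRUE`, area thresholds scale linearly with image area
#'   relative to `reference_width * reference_height`; circularity thresholds
#'   are scale-free.
#' @param reference_width,reference_height Reference frame size for which the
#'   area thresholds are calibrated.
#' @param min_tissue_fraction Minimum fraction of non-border pixels below which
#'   an image is rejected as having no usable tissue field.
#' @return An object of class `seg_config` (a validated named list).
#' @export
seg_config <- function(lower_bound = 100,
                       smooth_window = 5,
                       combine = c("and", "or"),
                       darkness_cutoff = 40,
                       kernel_radius = 1,
                       erosion_iterations = 1,
                       ca_hard_max = 2000,
                       ca_soft_max = 600,
                       c1_background_min = 0.3,
                       first_area_min = 2,
                       first_area_max = 1999,
                       first_c1_min = 0.2,
                       second_area_min = 2,
                       second_area_max = 499,
                       second_c2_min = 0.7,
                       ws_tolerance = 1,
                       ws_ext = 2,
                       rescale = TRUE,
                       reference_width = 640,
                       reference_height = 480,
                       min_tissue_fraction = 0.01) {
  combine <- match.arg(combine)
  cfg <- list(
    lower_bound = lower_bound, smooth_window = smooth_window,
    combine = combine, darkness_cutoff = darkness_cutoff,
    kernel_radius = kernel_radius, erosion_iterations = erosion_iterations,
    ca_hard_max = ca_hard_max, ca_soft_max = ca_soft_max,
    c1_background_min = c1_background_min,
    first_area_min = first_area_min, first_area_max = first_area_max,
    first_c1_min = first_c1_min,
    second_area_min = second_area_min, second_area_max = second_area_max,
    second_c2_min = second_c2_min,
    ws_tolerance = ws_tolerance, ws_ext = ws_ext,
    rescale = rescale,
    reference_width = reference_width, reference_height = reference_height,
    min_tissue_fraction = min_tissue_fraction
  )
  validate_seg_config(cfg)
  structure(cfg, class = "seg_config")
}

validate_seg_config <- function(cfg) {
  stopifnot(
    cfg$lower_bound >= 0, cfg$lower_bound <= 254,
    cfg$smooth_window >= 1,
    cfg$combine %in% c("and", "or"),
    cfg$darkness_cutoff >= 0, cfg$darkness_cutoff <= 255,
    cfg$kernel_radius >= 1, cfg$erosion_iterations >= 1,
    cfg$ca_hard_max > 0, cfg$ca_soft_max > 0,
    cfg$c1_background_min >= 0, cfg$c1_background_min <= 1,
    cfg$first_area_min >= 1, cfg$first_area_max >= cfg$first_area_min,
    cfg$first_c1_min >= 0, cfg$first_c1_min <= 1,
    cfg$second_area_min >= 1, cfg$second_area_max >= cfg$second_area_min,
    cfg$second_c2_min >= 0, cfg$second_c2_min <= 1.2,
    cfg$ws_tolerance > 0, cfg$ws_ext >= 1,
    is.logical(cfg$rescale),
    cfg$reference_width > 0, cfg$reference_height > 0,
    cfg$min_tissue_fraction >= 0, cfg$min_tissue_fraction < 1
  )
  invisible(cfg)
}

#' Read a segmentation configuration from a YAML file
#'
#' Keys mirror the arguments of [seg_config()]; unknown keys raise an error.
#'
#' @param path Path to a flat YAML key-value file.
#' @param ... Overrides applied after the file is read (e.g. from CLI flags).
#' @return A `seg_config` object.
#' @export
read_seg_config <- function(path, ...) {
  vals <- if (is.null(path)) list() else yaml::read_yaml(path)
  overrides <- list(...)
  vals[names(overrides)] <- overrides
  known <- names(formals(seg_config))
  bad <- setdiff(names(vals), known)
  if (length(bad))
    stop("unknown configuration key(s): ", paste(bad, collapse = ", "))
  do.call(seg_config, vals)
}

#' @export
print.seg_config <- function(x, ...) {
  cat("<seg_config>\n")
  for (k in names(x)) cat(sprintf("  %-20s %s\n", k, format(x[[k]])))
  invisible(x)
}
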