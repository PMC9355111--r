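#' Adaptive channel threshold from histogram peaks
#'
#' H&E frozen sections photographed through an ocular have a bimodal green and
#' blue intensity distribution: a tissue mode (pink stain) and a white-space
#' mode (steatosis, lumina, tears, background). The binarization threshold for
#' a channel is the mean intensity of the two highest histogram peaks above a
#' lower bound; with a single qualifying peak that peak's position is used.
#'
#' The histogram is smoothed with a centred moving average before peak
#' finding; a peak is a run of equal smoothed counts strictly greater than its
#' neighbours on both sides (image-boundary runs qualify). Plateau peaks take
#' their centre position, ties between equal-height peaks are broken toward
#' higher intensity.
#'
#' @param channel_histogram Numeric vector of 256 non-negative counts for
#'   intensities 0-255.
#' @param lower_bound Only peaks at intensities strictly above this are
#'   considered (0-254).
#' @param smooth_window Moving-average window in bins.
#' @return Threshold intensity in `(lower_bound, 255]` (possibly fractional).
#' @export
compute_channel_threshold <- function(channel_histogram, lower_bound = 100,
                                      smooth_window = 5) {
  stopifnot(length(channel_histogram) == 256L, all(channel_histogram >= 0),
            lower_bound >= 0, lower_bound <= 254)
  if (sum(channel_histogram[(lower_bound + 2):256]) == 0)
    stop("no-tissue/empty-field image: no histogram mass above the lower bound")
  sm <- smooth_histogram(channel_histogram, smooth_window)
  peaks <- histogram_peaks(sm, lower_bound)
  if (nrow(peaks) == 0L)
    stop("no-tissue/empty-field image: no histogram peak above the lower bound")
  # two highest peaks by smoothed height, ties toward higher intensity
  ord <- order(-peaks$height, -peaks$position)
  top <- peaks$position[ord][seq_len(min(2L, nrow(peaks)))]
  mean(top)
}

# Centred moving average with partial windows at the ends so boundary spikes
# (e.g. saturated white at 255) keep a local maximum at the boundary.
smooth_histogram <- function(counts, window) {
  if (window <= 1L) return(as.numeric(counts))
  half <- (window - 1) %/% 2
  n <- length(counts)
  cs <- cumsum(c(0, counts))
  lo <- pmax(seq_len(n) - half, 1L)
  hi <- pmin(seq_len(n) + half, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

# Plateau-aware local maxima of a smoothed histogram, keeping only peaks at
# intensities strictly above lower_bound. A peak is a run of equal counts
# strictly greater than the neighbouring runs (edges count as -Inf); its
# position is the run centre, rounded toward higher intensity for even runs.
histogram_peaks <- function(smoothed, lower_bound) {
  r <- rle(as.numeric(smoothed))
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  nruns <- length(r$values)
  left <- c(-Inf, r$values[-nruns])
  right <- c(r$values[-1L], -Inf)
  is_peak <- r$values > left & r$values > right & r$values > 0
  centre <- ceiling((starts + ends) / 2) - 1L   # back to 0-255 intensity scale
  out <- data.frame(position = centre[is_peak], height = r$values[is_peak])
  out[out$position > lower_bound, , drop = FALSE]
}

#' Compute per-image green and blue thresholds
#'
#' Builds the green and blue channel histograms of the non-border pixels and
#' applies [compute_channel_threshold()] to each. The red channel is ignored:
#' it does not separate pink tissue from white space in H&E images.
#'
#' @param image RGB image (array, EBImage Image, or path).
#' @param border Optional logical matrix of excluded border pixels.
#' @param lower_bound,smooth_window See [compute_channel_threshold()].
#' @return List with `green_threshold`, `blue_threshold`, `lower_bound`.
#' @export
channel_thresholds <- function(image, border = NULL, lower_bound = 100,
                               smooth_window = 5) {
  rgb <- as_rgb255(image)
  g <- rgb[, , 2]; b <- rgb[, , 3]
  if (!is.null(border)) { g <- g[!border]; b <- b[!border] }
  hg <- tabulate(g + 1L, nbins = 256L)
  hb <- tabulate(b + 1L, nbins = 256L)
  list(green_threshold = compute_channel_threshold(hg, lower_bound, smooth_window),
       blue_threshold = compute_channel_threshold(hb, lower_bound, smooth_window),
       lower_bound = lower_bound)
}

#' Binarize an RGB image with per-image thresholds
#'
#' Labels a pixel white (candidate steatosis) when its green and blue
#' intensities reach their respective thresholds (`combine = "and"`, default)
#' or when either does (`combine = "or"`). Border pixels are always black and
#' excluded from tissue accounting downstream.
#'
#' @param image RGB image.
#' @param thresholds List as returned by [channel_thresholds()].
#' @param border Optional logical matrix of border pixels.
#' @param combine `"and"` or `"or"`.
#' @return Logical matrix, `TRUE` = white.
#' @export
binarize_image <- function(image, thresholds, border = NULL,
                           combine = c("and", "or")) {
  combine <- match.arg(combine)
  rgb <- as_rgb255(image)
  g <- rgb[, , 2] >= thresholds$green_threshold
  b <- rgb[, , 3] >= thresholds$blue_threshold
  white <- if (combine == "and") g & b else g | b
  if (!is.null(border)) white[border] <- FALSE
  white
}

#' Detect the black vignette border of an ocular image
#'
#' Photographing a slide through a microscope ocular leaves a black ring and
#' dark out-of-field corners. The usable field is taken as the largest bright
#' 8-connected component (max channel at or above `darkness_cutoff`) with its
#' interior holes filled; everything outside it is the excluded border set.
#'
#' @param image RGB image.
#' @param darkness_cutoff Pixels with all channels below this are dark.
#' @return Logical matrix, `TRUE` = excluded border pixel. All-`FALSE` for
#'   whole-field tissue images; all-`TRUE` for a fully dark frame.
#' @export
detect_vignette_border <- function(image, darkness_cutoff = 40) {
  rgb <- as_rgb255(image)
  bright <- pmax(rgb[, , 1], rgb[, , 2], rgb[, , 3]) >= darkness_cutoff
  dim(bright) <- dim(rgb)[1:2]
  if (!any(bright)) return(!bright | TRUE)     # fully dark: everything border
  if (all(bright)) return(bright & FALSE)      # no dark pixels: empty set
  lab <- label_mask8(bright)
  counts <- tabulate(lab[lab > 0L])
  field <- lab == which.max(counts)
  field <- EBImage::fillHull(EBImage::Image(field * 1)) > 0
  dim(field) <- dim(bright)
  !field
}
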