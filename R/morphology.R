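#' Morphological erosion of a binary mask
#'
#' Shrinks white regions with a square structuring element to remove sparse
#' white noise that can mimic small steatotic droplets. Pixels removed here
#' from genuine droplets are restored later by [dilate_restore()].
#'
#' @param mask Logical matrix (white = `TRUE`).
#' @param kernel_radius Radius of the square kernel (1 = 3x3).
#' @param iterations Number of erosion passes.
#' @return Logical matrix; white set is a subset of the input white set.
#' @export
erode_binary <- function(mask, kernel_radius = 1, iterations = 1) {
  stopifnot(kernel_radius >= 1)
  if (!any(mask)) return(mask)
  kern <- EBImage::makeBrush(2 * kernel_radius + 1, shape = "box")
  m <- EBImage::Image(mask * 1)
  for (i in seq_len(iterations)) m <- EBImage::erode(m, kern)
  out <- EBImage::imageData(m) > 0
  dim(out) <- dim(mask)
  out
}

#' Dilate an accepted-droplet mask back onto the pre-erosion white set
#'
#' Applies the dilation that mirrors [erode_binary()] and intersects the
#' result with the white set of the original binarized image, so restored
#' pixels were genuinely white before erosion and no white pixel is invented.
#'
#' @param mask Logical matrix of accepted droplet pixels (post-erosion).
#' @param pre_erosion_white Logical matrix: white set before erosion.
#' @param kernel_radius,iterations Mirror the erosion parameters.
#' @return Logical matrix with `mask <= result <= pre_erosion_white`.
#' @export
dilate_restore <- function(mask, pre_erosion_white, kernel_radius = 1,
                           iterations = 1) {
  stopifnot(identical(dim(mask), dim(pre_erosion_white)))
  if (!any(mask)) return(mask)
  kern <- EBImage::makeBrush(2 * kernel_radius + 1, shape = "box")
  m <- EBImage::Image(mask * 1)
  for (i in seq_len(iterations)) m <- EBImage::dilate(m, kern)
  out <- EBImage::imageData(m) > 0
  dim(out) <- dim(mask)
  (out | mask) & pre_erosion_white
}

#' Separate clustered droplets with a distance-transform watershed
#'
#' Tightly clustered droplets merge into one white mass that the area and
#' circularity filters would misread as an artifact. The watershed of the
#' Euclidean distance map splits such masses along the ridges between distance
#' maxima; every white pixel is assigned to exactly one output region.
#'
#' @param mask Logical matrix.
#' @param tolerance Minimum distance-map height of a separate object.
#' @param ext Neighbourhood radius used to suppress nearby seed maxima
#'   (larger values merge close markers).
#' @return Integer label matrix (0 = background); labels partition the input
#'   white set.
#' @export
watershed_separate <- function(mask, tolerance = 1, ext = 2) {
  if (!any(mask)) return(matrix(0L, nrow(mask), ncol(mask)))
  d <- EBImage::distmap(EBImage::Image(mask * 1))
  w <- EBImage::watershed(d, tolerance = tolerance, ext = ext)
  out <- EBImage::imageData(w)
  storage.mode(out) <- "integer"
  dim(out) <- dim(mask)
  out
}
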