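#' Read an RGB raster image
#'
#' Reads a TIFF, PNG or JPEG image into the 0-255 integer RGB array used
#' throughout the package. 16-bit images are rescaled to 8-bit; grayscale
#' images are promoted to three identical channels with a warning.
#'
#' @param path Path to a TIFF/PNG/JPEG file.
#' @return Integer array of dimension `c(width, height, 3)` with values in
#'   0-255 (column-major, x = width index, as in EBImage).
#' @export
read_raster <- function(path) {
  if (!file.exists(path)) stop("image file not found: ", path)
  img <- EBImage::readImage(path)
  as_rgb255(img)
}

# Normalize any supported image representation to an integer 0-255 array
# of dim c(nx, ny, 3). Accepts EBImage Image (0-1), numeric arrays in 0-1 or
# 0-255 (or 16-bit 0-65535), 2-D grayscale matrices, and file paths.
as_rgb255 <- function(image) {
  if (is.character(image) && length(image) == 1L) return(read_raster(image))
  if (inherits(image, "Image")) {
    image <- EBImage::imageData(image)
    if (length(dim(image)) == 3L && dim(image)[3] > 3L)
      image <- image[, , 1:3]  # drop alpha
    image <- image * 255
  }
  if (is.matrix(image)) {
    warning("grayscale input promoted to 3 identical RGB channels")
    image <- array(rep(image, 3L), dim = c(dim(image), 3L))
  }
  if (!is.array(image) || length(dim(image)) != 3L)
    stop("expected an RGB array, EBImage Image, matrix, or file path")
  if (dim(image)[3] > 3L) image <- image[, , 1:3]
  if (dim(image)[3] != 3L) stop("expected 3 channels, got ", dim(image)[3])
  mx <- max(image)
  if (mx <= 1 + 1e-9) image <- image * 255
  else if (mx > 255) image <- image * (255 / 65535)  # 16-bit input
  storage.mode(image) <- "integer"
  image[image < 0L] <- 0L
  image[image > 255L] <- 255L
  image
}

#' Write a binary mask as a PNG
#'
#' @param mask Logical or 0/1 matrix (white = `TRUE`).
#' @param path Output PNG path.
#' @export
write_mask_png <- function(mask, path) {
  EBImage::writeImage(EBImage::Image(mask * 1), path, type = "png")
  invisible(path)
}

#' Write a green-tinted overlay of accepted droplets on the original image
#'
#' Accepted fat pixels are blended toward green over the source image, the
#' usual way segmentation masks are displayed on histology.
#'
#' @param image RGB image (array, EBImage Image, or path).
#' @param mask Logical matrix of accepted fat pixels.
#' @param path Output PNG path.
#' @param alpha Blend weight of the green tint in (0, 1].
#' @export
write_overlay_png <- function(image, mask, path, alpha = 0.6) {
  rgb <- as_rgb255(image) / 255
  green <- c(0.1, 0.85, 0.2)
  for (ch in 1:3) {
    plane <- rgb[, , ch]
    plane[mask] <- (1 - alpha) * plane[mask] + alpha * green[ch]
    rgb[, , ch] <- plane
  }
  EBImage::writeImage(EBImage::Image(rgb, colormode = "Color"), path, type = "png")
  invisible(path)
}
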