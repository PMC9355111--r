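#' Per-image steatosis fraction
#'
#' The percent steatosis of one image is the number of accepted fat pixels
#' divided by the number of liver tissue pixels (tissue = binarized-black
#' non-border pixels plus accepted fat), on the 0-100 scale.
#'
#' @param result A `steatosis_segmentation` object from [segment_image()], or
#'   a list with `fat_pixels` and `tissue_pixels` counts.
#' @param image_id Optional identifier (defaults to the one in `result`).
#' @return A one-row data frame: `image_id`, `fat_pixels`, `tissue_pixels`,
#'   `steatosis_percent`.
#' @export
image_steatosis_fraction <- function(result, image_id = NULL) {
  fat <- result$fat_pixels
  tissue <- result$tissue_pixels
  if (is.null(fat) || is.null(tissue))
    stop("result must carry fat_pixels and tissue_pixels")
  if (tissue <= 0) stop("no-tissue image: tissue pixel count is zero")
  if (is.null(image_id)) image_id <- result$image_id
  data.frame(image_id = if (is.null(image_id)) NA_character_ else image_id,
             fat_pixels = fat, tissue_pixels = tissue,
             steatosis_percent = 100 * fat / tissue,
             stringsAsFactors = FALSE)
}

#' Per-liver steatosis score with one-pass outlier omission
#'
#' The liver score is the mean of its per-image percent estimates after
#' omitting outliers: the mean `m` and sample standard deviation `s` of all
#' estimates are computed once, images outside the closed interval
#' `[m - s, m + s]` are dropped, and the retained estimates are averaged. The
#' retained set is never empty (the mean always lies within one SD of itself).
#'
#' @param scores Numeric vector of per-image percent estimates, or a data
#'   frame with a `steatosis_percent` column (as from
#'   [image_steatosis_fraction()]).
#' @param liver_id Optional identifier.
#' @return List of class `liver_score`: `liver_id`, `final_percent`, `mean`,
#'   `sd`, `retained` (logical per input image), `image_percents`.
#' @export
liver_steatosis_score <- function(scores, liver_id = NULL) {
  if (is.data.frame(scores)) scores <- scores$steatosis_percent
  scores <- as.numeric(scores)
  if (!length(scores)) stop("at least one image score is required")
  if (anyNA(scores)) stop("image scores contain NA")
  if (length(scores) == 1L) {
    out <- list(liver_id = liver_id, final_percent = scores, mean = scores,
                sd = 0, retained = TRUE, image_percents = scores)
    class(out) <- "liver_score"
    return(out)
  }
  m <- mean(scores)
  s <- stats::sd(scores)
  retained <- scores >= m - s & scores <= m + s
  out <- list(liver_id = liver_id,
              final_percent = mean(scores[retained]),
              mean = m, sd = s, retained = retained,
              image_percents = scores)
  class(out) <- "liver_score"
  out
}

#' @export
print.liver_score <- function(x, ...) {
  cat("<liver_score>", if (!is.null(x$liver_id)) paste0(" ", x$liver_id), "\n",
      sep = "")
  cat(sprintf("  %d images, %d retained (mean %.2f, sd %.2f)\n",
              length(x$image_percents), sum(x$retained), x$mean, x$sd))
  cat(sprintf("  final steatosis: %.2f%%\n", x$final_percent))
  invisible(x)
}

#' Strict steatosis estimate from a three-colour control image
#'
#' Control images encode fat as green, liver tissue as black, and
#' neither-tissue-nor-fat as gray. The strict estimate is
#' `100 * green / (green + black)`; gray pixels are excluded from both
#' numerator and denominator. Pixels are classified by the nearest of the
#' three canonical colours, so mild compression noise still classifies
#' cleanly.
#'
#' @param control_image RGB image (path, EBImage Image, or array).
#' @param colors Named list of canonical RGB triplets (0-255) for `green`,
#'   `black`, `gray`.
#' @return Percent steatosis (0-100).
#' @export
strict_estimate_from_control <- function(control_image,
                                         colors = control_colors()) {
  rgb <- as_rgb255(control_image)
  n <- prod(dim(rgb)[1:2])
  flat <- matrix(as.numeric(rgb), nrow = n, ncol = 3)
  d <- vapply(colors, function(col) {
    rowSums((flat - matrix(col, n, 3, byrow = TRUE))^2)
  }, numeric(n))
  cls <- max.col(-d, ties.method = "first")  # 1 green, 2 black, 3 gray
  green <- sum(cls == 1L)
  black <- sum(cls == 2L)
  if (green + black == 0)
    stop("control image contains no green or black pixels")
  100 * green / (green + black)
}

# canonical colours of the control-image convention
control_colors <- function() {
  list(green = c(0, 200, 0), black = c(0, 0, 0), gray = c(128, 128, 128))
}
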