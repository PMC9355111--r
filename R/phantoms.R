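#' Specification of a synthetic phantom image
#'
#' Collects the parameters of the two phantom generators. Defaults emulate a
#' 640x480 ocular capture at 20x: droplet radii 4-11 px (areas ~50-380 px,
#' inside the droplet filter bands), a circular vignette field, and optional
#' tear and lumen artifacts sized so the background rules must reject them.
#'
#' @param width,height Frame size in pixels.
#' @param droplet_count Number of droplets to place (ignored when
#'   `target_fat_fraction` is given).
#' @param radius_range Inclusive droplet radius range `[min, max]` in pixels.
#' @param target_fat_fraction Optional target fat fraction in 0-1; droplets
#'   are added until the rendered fraction reaches it. The achieved fraction
#'   is recorded exactly from the rendered pixel counts.
#' @param clustering Overlap propensity in 0-1: probability that a droplet is
#'   seeded near an existing one (possibly merging) instead of being placed
#'   without overlap.
#' @param tears,lumina Artifact counts for the H&E phantom.
#' @param tear_area,lumen_area Sampled area ranges (px) for the artifacts;
#'   tears exceed the hard background cap, lumina fall in the soft
#'   size-and-elongation rule.
#' @param border If `TRUE`, the image is restricted to a circular field with a
#'   black vignette outside.
#' @param seed Integer seed; every draw in a phantom derives from it.
#' @return A validated list of class `phantom_spec`.
#' @export
phantom_spec <- function(width = 640, height = 480,
                         droplet_count = 40, radius_range = c(4, 11),
                         target_fat_fraction = NULL, clustering = 0,
                         tears = 0, lumina = 0,
                         tear_area = c(2500, 4000),
                         lumen_area = c(800, 1600),
                         border = TRUE, seed = 1) {
  stopifnot(width >= 64, height >= 64,
            droplet_count >= 0,
            length(radius_range) == 2L, radius_range[1] >= 2,
            radius_range[2] >= radius_range[1],
            clustering >= 0, clustering <= 1,
            tears >= 0, lumina >= 0,
            is.logical(border), length(seed) == 1L)
  if (!is.null(target_fat_fraction)) {
    stopifnot(target_fat_fraction >= 0, target_fat_fraction <= 1)
    if (target_fat_fraction > 0.6)
      stop("infeasible target fraction: more than 60% is not reachable ",
           "with non-overlapping droplets")
  }
  structure(list(width = width, height = height,
                 droplet_count = droplet_count, radius_range = radius_range,
                 target_fat_fraction = target_fat_fraction,
                 clustering = clustering, tears = tears, lumina = lumina,
                 tear_area = tear_area, lumen_area = lumen_area,
                 border = border, seed = as.integer(seed)),
            class = "phantom_spec")
}

# --- shared internals -------------------------------------------------------

disk_indices <- function(cx, cy, r, nx, ny) {
  xr <- max(1L, floor(cx - r)):min(nx, ceiling(cx + r))
  yr <- max(1L, floor(cy - r)):min(ny, ceiling(cy + r))
  g <- expand.grid(x = xr, y = yr)
  sel <- (g$x - cx)^2 + (g$y - cy)^2 <= r^2
  (g$y[sel] - 1L) * nx + g$x[sel]
}

ellipse_indices <- function(cx, cy, a, b, theta, nx, ny) {
  r <- max(a, b)
  xr <- max(1L, floor(cx - r)):min(nx, ceiling(cx + r))
  yr <- max(1L, floor(cy - r)):min(ny, ceiling(cy + r))
  g <- expand.grid(x = xr, y = yr)
  dx <- g$x - cx; dy <- g$y - cy
  u <- dx * cos(theta) + dy * sin(theta)
  v <- -dx * sin(theta) + dy * cos(theta)
  sel <- (u / a)^2 + (v / b)^2 <= 1
  (g$y[sel] - 1L) * nx + g$x[sel]
}

# place droplets onto an occupancy state; returns centres/radii and the
# droplet mask (logical vector over pixels). `allowed` marks pixels a droplet
# may cover; `occ` marks pixels already taken by artifacts (never covered).
place_droplets <- function(spec, allowed, occ, denom) {
  nx <- spec$width; ny <- spec$height
  droplet <- logical(nx * ny)
  centers <- list(); radii <- numeric(0)
  paired <- logical(0)  # droplets already in a merged pair
  target_n <- if (is.null(spec$target_fat_fraction)) spec$droplet_count else Inf
  target_px <- if (is.null(spec$target_fat_fraction)) Inf else
    spec$target_fat_fraction * denom
  n_placed <- 0L
  failures <- 0L
  while (n_placed < target_n && sum(droplet) < target_px) {
    r <- stats::runif(1, spec$radius_range[1], spec$radius_range[2])
    placed <- FALSE
    free <- which(!paired)
    cluster_try <- length(free) > 0L && stats::runif(1) < spec$clustering
    for (try in 1:200) {
      base_i <- NA_integer_
      if (cluster_try) {
        # merged-pair geometry: partial overlap with two distinct lobes, as
        # in tightly clustered but individually rendered lipid droplets;
        # clumps stay pairs so they remain within the droplet size gates
        base_i <- free[sample.int(length(free), 1)]
        base <- centers[[base_i]]; rb <- radii[base_i]
        # partner of similar size, overlapping but with two resolvable lobes
        r <- min(max(rb * stats::runif(1, 0.85, 1.18), spec$radius_range[1]),
                 spec$radius_range[2])
        ang <- stats::runif(1, 0, 2 * pi)
        d <- stats::runif(1, 0.80, 0.97) * (rb + r)
        cx <- base[1] + cos(ang) * d
        cy <- base[2] + sin(ang) * d
        if (cx < r + 2 || cx > nx - r - 2 || cy < r + 2 || cy > ny - r - 2) next
        # stay clear of every droplet other than the chosen partner
        others <- setdiff(seq_len(n_placed), base_i)
        if (length(others)) {
          dd <- vapply(others, function(i) {
            sqrt(sum((centers[[i]] - c(cx, cy))^2)) - (radii[i] + r + 2)
          }, numeric(1))
          if (any(dd < 0)) next
        }
      } else {
        cx <- stats::runif(1, r + 2, nx - r - 2)
        cy <- stats::runif(1, r + 2, ny - r - 2)
      }
      idx <- disk_indices(cx, cy, r, nx, ny)
      if (!length(idx) || !all(allowed[idx]) || any(occ[idx])) next
      if (!cluster_try && any(droplet[idx])) next
      droplet[idx] <- TRUE
      centers[[n_placed + 1L]] <- c(cx, cy); radii <- c(radii, r)
      paired <- c(paired, cluster_try)
      if (cluster_try) paired[base_i] <- TRUE
      n_placed <- n_placed + 1L
      placed <- TRUE
      break
    }
    if (!placed) {
      failures <- failures + 1L
      if (failures > 50L)
        stop("infeasible phantom: could not place droplets without overlap")
    }
  }
  list(mask = droplet, centers = centers, radii = radii)
}

clip255 <- function(x) pmin(pmax(x, 0), 255)

# --- control phantom (three-colour ground-truth image) ----------------------

#' Generate a three-colour control phantom
#'
#' Renders green fat disks on black tissue with gray non-tissue patches, the
#' colour convention of manually generated control images used to benchmark
#' rater agreement. The ground-truth fat fraction, green / (green + black), is
#' recorded exactly from the rendered pixel counts, so
#' [strict_estimate_from_control()] recovers it exactly.
#'
#' @param spec A [phantom_spec()].
#' @return List with `image` (0-255 RGB array) and `truth` (list: `mask`
#'   logical matrix of fat pixels, `fat_fraction_percent`, `centers`, `radii`,
#'   `seed`, `spec`).
#' @export
generate_control_phantom <- function(spec = phantom_spec()) {
  stopifnot(inherits(spec, "phantom_spec"))
  set.seed(spec$seed)
  nx <- spec$width; ny <- spec$height
  npix <- nx * ny
  cols <- control_colors()

  gray <- logical(npix)
  if (spec$border) {
    cx0 <- (nx + 1) / 2; cy0 <- (ny + 1) / 2
    rfield <- min(nx, ny) / 2 - 6
    g <- expand.grid(x = seq_len(nx), y = seq_len(ny))
    gray[(g$x - cx0)^2 + (g$y - cy0)^2 > rfield^2] <- TRUE
  }
  # a few gray non-tissue patches inside the field
  for (i in seq_len(2 + stats::rpois(1, 1))) {
    a <- stats::runif(1, 15, 45); b <- stats::runif(1, 10, 35)
    idx <- ellipse_indices(stats::runif(1, 40, nx - 40),
                           stats::runif(1, 40, ny - 40),
                           a, b, stats::runif(1, 0, pi), nx, ny)
    gray[idx] <- TRUE
  }
  denom <- npix - sum(gray)  # green + black is constant
  pl <- place_droplets(spec, allowed = !gray, occ = logical(npix), denom = denom)

  img <- array(0, dim = c(nx, ny, 3))
  for (ch in 1:3) {
    plane <- rep(cols$black[ch], npix)
    plane[gray] <- cols$gray[ch]
    plane[pl$mask] <- cols$green[ch]
    img[, , ch] <- plane
  }
  storage.mode(img) <- "integer"

  green_n <- sum(pl$mask)
  truth_mask <- matrix(pl$mask, nx, ny)
  list(image = img,
       truth = list(mask = truth_mask,
                    fat_fraction_percent = 100 * green_n / denom,
                    centers = pl$centers, radii = pl$radii,
                    seed = spec$seed, spec = spec))
}

# --- H&E-like phantom -------------------------------------------------------

#' Generate an H&E-like phantom with exact ground truth
#'
#' Renders a pink-tissue field with per-image colour jitter (to exercise the
#' per-image adaptive thresholding), white steatotic droplets, dark nuclei
#' speckle, sparse single-pixel white noise, optional large irregular white
#' tears (area above the hard background cap) and elongated white lumina
#' (large and non-circular), and an optional black circular vignette. The
#' truth mask marks droplet pixels only; the true fat fraction is
#' droplets / (droplets + tissue), with artifact and border pixels excluded
#' from the denominator, mirroring the pipeline's tissue definition.
#'
#' @param spec A [phantom_spec()].
#' @return List with `image` and `truth` as in [generate_control_phantom()];
#'   `truth` additionally carries `artifact_mask`.
#' @export
generate_he_phantom <- function(spec = phantom_spec()) {
  stopifnot(inherits(spec, "phantom_spec"))
  set.seed(spec$seed)
  nx <- spec$width; ny <- spec$height
  npix <- nx * ny

  outside <- logical(npix)
  if (spec$border) {
    cx0 <- (nx + 1) / 2; cy0 <- (ny + 1) / 2
    rfield <- min(nx, ny) / 2 - 6
    g <- expand.grid(x = seq_len(nx), y = seq_len(ny))
    outside[(g$x - cx0)^2 + (g$y - cy0)^2 > rfield^2] <- TRUE
  }
  field <- !outside

  artifact <- logical(npix)
  margin <- 40
  for (i in seq_len(spec$tears)) {
    # one big disk plus two satellites: irregular, always above the hard cap
    r0 <- stats::runif(1, 28, 35)
    for (try in 1:100) {
      cx <- stats::runif(1, margin, nx - margin)
      cy <- stats::runif(1, margin, ny - margin)
      if (spec$border &&
          (cx - (nx + 1) / 2)^2 + (cy - (ny + 1) / 2)^2 >
            (min(nx, ny) / 2 - 6 - r0 - 22)^2) next
      break
    }
    idx <- disk_indices(cx, cy, r0, nx, ny)
    for (k in 1:2) {
      ang <- stats::runif(1, 0, 2 * pi)
      rs <- stats::runif(1, 12, 18)
      idx <- c(idx, disk_indices(cx + cos(ang) * r0 * 0.9,
                                 cy + sin(ang) * r0 * 0.9, rs, nx, ny))
    }
    artifact[unique(idx)] <- TRUE
  }
  for (i in seq_len(spec$lumina)) {
    area <- stats::runif(1, spec$lumen_area[1], spec$lumen_area[2])
    aspect <- stats::runif(1, 5, 8)
    a <- sqrt(area * aspect / pi); b <- sqrt(area / (pi * aspect))
    for (try in 1:100) {
      cx <- stats::runif(1, a + 4, nx - a - 4)
      cy <- stats::runif(1, a + 4, ny - a - 4)
      if (spec$border &&
          (cx - (nx + 1) / 2)^2 + (cy - (ny + 1) / 2)^2 >
            (min(nx, ny) / 2 - 6 - a - 6)^2) next
      break
    }
    artifact[ellipse_indices(cx, cy, a, b, stats::runif(1, 0, pi), nx, ny)] <- TRUE
  }
  artifact <- artifact & field

  denom <- sum(field) - sum(artifact)
  pl <- place_droplets(spec, allowed = field, occ = artifact, denom = denom)
  droplet <- pl$mask

  tissue <- field & !artifact & !droplet

  # render: pink tissue with per-image jitter and per-pixel noise
  base <- c(200, 130, 150) + stats::runif(3, -25, 25)
  img <- array(0, dim = c(nx, ny, 3))
  nuclei <- which(tissue)[stats::runif(sum(tissue)) < 0.02]
  speckle <- which(tissue)[stats::runif(sum(tissue)) < 0.001]
  white_shade <- stats::runif(1, 246, 252)
  for (ch in 1:3) {
    plane <- rep(0, npix)
    plane[tissue] <- base[ch] + stats::rnorm(sum(tissue), 0, 6)
    plane[nuclei] <- c(80, 60, 110)[ch] + stats::rnorm(length(nuclei), 0, 5)
    plane[artifact] <- 250 + stats::rnorm(sum(artifact), 0, 2)
    plane[droplet] <- white_shade + stats::rnorm(sum(droplet), 0, 2)
    plane[speckle] <- 249
    plane[outside] <- 8 + abs(stats::rnorm(sum(outside), 0, 3))
    img[, , ch] <- clip255(round(plane))
  }
  storage.mode(img) <- "integer"

  truth_mask <- matrix(droplet, nx, ny)
  list(image = img,
       truth = list(mask = truth_mask,
                    fat_fraction_percent = 100 * sum(droplet) / denom,
                    centers = pl$centers, radii = pl$radii,
                    artifact_mask = matrix(artifact, nx, ny),
                    seed = spec$seed, spec = spec))
}

#' Write a phantom image and its ground-truth sidecar
#'
#' @param phantom A list from [generate_control_phantom()] or
#'   [generate_he_phantom()].
#' @param image_path Output PNG/TIFF path.
#' @param truth_path Output JSON sidecar path (defaults to
#'   `<image_path>.json`).
#' @export
write_phantom <- function(phantom, image_path,
                          truth_path = paste0(image_path, ".json")) {
  EBImage::writeImage(EBImage::Image(phantom$image / 255, colormode = "Color"),
                      image_path,
                      type = tolower(tools::file_ext(image_path)))
  truth <- phantom$truth
  sidecar <- list(
    fat_fraction_percent = truth$fat_fraction_percent,
    centers = if (length(truth$centers)) do.call(rbind, truth$centers) else NULL,
    radii = truth$radii,
    seed = truth$seed,
    spec = unclass(truth$spec)
  )
  jsonlite::write_json(sidecar, truth_path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(image_path)
}
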