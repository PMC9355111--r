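# Shape constructors and brute-force oracles shared across tests.

# logical matrix with a digital disk (pixels whose centre is within r)
disk_mask <- function(r, pad = 5, nx = 2 * r + 2 * pad, ny = nx,
                      cx = r + pad, cy = r + pad, base = NULL) {
  m <- if (is.null(base)) matrix(FALSE, nx, ny) else base
  xs <- row(m); ys <- col(m)
  m[(xs - cx)^2 + (ys - cy)^2 <= r^2] <- TRUE
  m
}

rect_mask <- function(w, h, pad = 5) {
  m <- matrix(FALSE, w + 2 * pad, h + 2 * pad)
  m[(pad + 1):(pad + w), (pad + 1):(pad + h)] <- TRUE
  m
}

mask_xy <- function(mask) {
  idx <- which(mask)
  cbind((idx - 1L) %% nrow(mask) + 1L, (idx - 1L) %/% nrow(mask) + 1L)
}

# minimal flat-colour H&E-like image: pink tissue, white where mask is TRUE,
# optional black outside a circular field
he_image <- function(white_mask, border_outside = NULL,
                     tissue = c(200, 130, 150), white = c(250, 250, 250)) {
  nx <- nrow(white_mask); ny <- ncol(white_mask)
  img <- array(0L, dim = c(nx, ny, 3))
  for (ch in 1:3) {
    plane <- matrix(tissue[ch], nx, ny)
    plane[white_mask] <- white[ch]
    if (!is.null(border_outside)) plane[border_outside] <- 10
    img[, , ch] <- as.integer(plane)
  }
  img
}

# Brute-force minimum enclosing circle: enumerate all pair (diametral) and
# triple (circumscribed) candidate circles over the convex hull of the point
# set and take the smallest one containing every point. Independent of the
# package's Welzl construction.
mec_brute <- function(pts) {
  pts <- unique(pts)
  if (nrow(pts) > 3) pts <- pts[grDevices::chull(pts), , drop = FALSE]
  n <- nrow(pts)
  if (n == 1) return(list(center = pts[1, ], radius = 0))
  contains_all <- function(cx, cy, r) {
    all(sqrt((pts[, 1] - cx)^2 + (pts[, 2] - cy)^2) <= r + 1e-7)
  }
  best <- NULL
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    cx <- (pts[i, 1] + pts[j, 1]) / 2; cy <- (pts[i, 2] + pts[j, 2]) / 2
    r <- sqrt(sum((pts[i, ] - pts[j, ])^2)) / 2
    if (contains_all(cx, cy, r) && (is.null(best) || r < best$radius))
      best <- list(center = c(cx, cy), radius = r)
  }
  if (n >= 3) for (i in seq_len(n - 2)) for (j in (i + 1):(n - 1)) for (k in (j + 1):n) {
    a <- pts[i, ]; b <- pts[j, ]; c <- pts[k, ]
    d <- 2 * (a[1] * (b[2] - c[2]) + b[1] * (c[2] - a[2]) + c[1] * (a[2] - b[2]))
    if (abs(d) < 1e-12) next
    a2 <- sum(a^2); b2 <- sum(b^2); c2 <- sum(c^2)
    ux <- (a2 * (b[2] - c[2]) + b2 * (c[2] - a[2]) + c2 * (a[2] - b[2])) / d
    uy <- (a2 * (c[1] - b[1]) + b2 * (a[1] - c[1]) + c2 * (b[1] - a[1])) / d
    r <- sqrt((a[1] - ux)^2 + (a[2] - uy)^2)
    if (contains_all(ux, uy, r) && (is.null(best) || r < best$radius))
      best <- list(center = c(ux, uy), radius = r)
  }
  best
}

# Brute-force 8-connected component sizes by repeated flood fill.
flood_sizes <- function(mask) {
  visited <- matrix(FALSE, nrow(mask), ncol(mask))
  nx <- nrow(mask); ny <- ncol(mask)
  sizes <- integer(0)
  for (start in which(mask & !visited)) {
    if (visited[start]) next
    queue <- start; visited[start] <- TRUE; size <- 0L
    while (length(queue)) {
      p <- queue[1]; queue <- queue[-1]; size <- size + 1L
      x <- (p - 1L) %% nx + 1L; y <- (p - 1L) %/% nx + 1L
      for (dx in -1:1) for (dy in -1:1) {
        if (dx == 0 && dy == 0) next
        x2 <- x + dx; y2 <- y + dy
        if (x2 < 1 || x2 > nx || y2 < 1 || y2 > ny) next
        q <- (y2 - 1L) * nx + x2
        if (mask[q] && !visited[q]) { visited[q] <- TRUE; queue <- c(queue, q) }
      }
    }
    sizes <- c(sizes, size)
  }
  sizes
}

# random small blobby mask: a few random disks on a small frame
random_blob_mask <- function(seed, nx = 40, ny = 40, ndisk = 3, rmax = 6) {
  set.seed(seed)
  m <- matrix(FALSE, nx, ny)
  for (i in seq_len(ndisk)) {
    r <- runif(1, 1.5, rmax)
    m <- disk_mask(r, base = m, nx = nx, ny = ny,
                   cx = runif(1, r + 2, nx - r - 2),
                   cy = runif(1, r + 2, ny - r - 2))
  }
  m
}
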