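#' Lesion geometry features
#'
#' Shape descriptors of the mask in physical units: area (pixel count times
#' pixel area, mm^2), perimeter (length of the 8-connected outer contour
#' traced through pixel centers, mm), circularity
#' `4 pi area / perimeter^2`, elongation (minor/major axis ratio,
#' `sqrt(lambda_min / lambda_max)` of the second-order central moments of
#' the pixel-center coordinates), and the maximal Feret diameter (largest
#' pixel-center to pixel-center distance, mm).
#'
#' @param mask a [roi_mask()].
#' @param spacing (row, col) pixel size in mm.
#' @return Named numeric vector `geo_*`.
#' @export
geometry_features <- function(mask, spacing = c(1, 1)) {
  m <- mask$mask
  sr <- spacing[1]; sc <- spacing[2]
  n <- sum(m)
  area <- n * sr * sc
  idx <- which(m, arr.ind = TRUE)
  pts <- cbind(idx[, 1] * sr, idx[, 2] * sc)

  per <- contour_perimeter(m, sr, sc)
  circ <- if (per > 0) 4 * pi * area / per^2 else NA_real_

  ctr <- sweep(pts, 2, colMeans(pts))
  cov2 <- crossprod(ctr) / n
  ev <- eigen(cov2, symmetric = TRUE, only.values = TRUE)$values
  elong <- if (ev[1] > 0) sqrt(max(ev[2], 0) / ev[1]) else 1

  feret <- max_feret(pts)

  c(geo_area_mm2 = area, geo_perimeter_mm = per, geo_circularity = circ,
    geo_elongation = elong, geo_feret_mm = feret)
}

# Maximal pairwise pixel-center distance, via the convex hull when the
# point set is large.
max_feret <- function(pts) {
  if (nrow(pts) > 20L) {
    h <- grDevices::chull(pts)
    pts <- pts[h, , drop = FALSE]
  }
  if (nrow(pts) < 2L) return(0)
  max(stats::dist(pts))
}

# Moore-neighbor contour tracing with Jacob's stopping criterion; returns
# the Euclidean length of the closed boundary path through pixel centers.
contour_perimeter <- function(m, sr = 1, sc = 1) {
  nr <- nrow(m); nc <- ncol(m)
  at <- function(i, j) i >= 1 && i <= nr && j >= 1 && j <= nc && m[i, j]
  # start: first foreground pixel in raster order (top row, then left col)
  idx <- which(t(m))  # row-major scan
  if (length(idx) == 0L) return(0)
  first <- idx[1L] - 1L
  si <- first %/% nc + 1L
  sj <- first %% nc + 1L
  # clockwise Moore neighborhood starting west
  dr <- c(0L, -1L, -1L, -1L, 0L, 1L, 1L, 1L)
  dc <- c(-1L, -1L, 0L, 1L, 1L, 1L, 0L, -1L)
  p <- c(si, sj)
  b_dir <- 1L  # direction (index into dr/dc) from p toward its backtrack (west)
  path_len <- 0
  start_state <- NULL
  max_iter <- 8L * (sum(m) + 4L)
  for (iter in seq_len(max_iter)) {
    found <- FALSE
    d <- b_dir
    for (step in 1:8) {
      d <- d %% 8L + 1L  # next clockwise from the backtrack direction
      ni <- p[1] + dr[d]; nj <- p[2] + dc[d]
      if (at(ni, nj)) { found <- TRUE; break }
    }
    if (!found) return(0)  # isolated pixel (cannot happen for valid ROIs)
    state <- c(p[1], p[2], d)
    if (is.null(start_state)) {
      start_state <- state
    } else if (identical(state, start_state)) {
      break
    }
    path_len <- path_len + sqrt((dr[d] * sr)^2 + (dc[d] * sc)^2)
    # new backtrack: the neighbor examined just before the hit, seen from
    # the new pixel
    prev <- d - 1L; if (prev == 0L) prev <- 8L
    bi <- p[1] + dr[prev]; bj <- p[2] + dc[prev]
    p <- c(ni, nj)
    # direction index from new p toward (bi, bj)
    ddr <- bi - p[1]; ddc <- bj - p[2]
    b_dir <- which(dr == ddr & dc == ddc)
    if (length(b_dir) != 1L) b_dir <- 1L
  }
  path_len
}
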