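#' Annotated 2-D image
#'
#' A rectangular grid of finite pixel intensities with physical pixel spacing
#' and a modality tag. This is the in-memory carrier for ADC maps, high
#' b-value diffusion-weighted images and b = 0 images throughout the package.
#'
#' @param pixels numeric matrix, at least 2 x 2, all values finite.
#' @param spacing numeric length-2 vector, (row, column) pixel size in mm;
#'   both components must be positive. Defaults to 1.4 mm isotropic, a
#'   typical reconstructed in-plane resolution for breast DWI.
#' @param modality one of `"ADC"`, `"DWI_HIGH_B"`, `"B0"`.
#' @param id lesion/slice identifier string.
#'
#' @return An object of class `annotated_image` with fields `pixels`,
#'   `spacing`, `modality`, `id`.
#' @export
annotated_image <- function(pixels, spacing = c(1.4, 1.4),
                            modality = c("ADC", "DWI_HIGH_B", "B0"),
                            id = "image") {
  modality <- match.arg(modality)
  pixels <- as.matrix(pixels)
  storage.mode(pixels) <- "double"
  attributes(pixels) <- list(dim = dim(pixels))  # strip foreign attributes
  if (nrow(pixels) < 2L || ncol(pixels) < 2L)
    stop("image must be at least 2 x 2 pixels", call. = FALSE)
  if (!all(is.finite(pixels)))
    stop("image contains non-finite pixel values", call. = FALSE)
  spacing <- as.numeric(spacing)
  if (length(spacing) == 1L) spacing <- rep(spacing, 2L)
  if (length(spacing) != 2L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("spacing must be two positive numbers (mm)", call. = FALSE)
  structure(list(pixels = pixels, spacing = spacing,
                 modality = modality, id = as.character(id)),
            class = "annotated_image")
}

#' @export
print.annotated_image <- function(x, ...) {
  cat(sprintf("<annotated_image '%s'> %d x %d %s, spacing %.3g x %.3g mm\n",
              x$id, nrow(x$pixels), ncol(x$pixels), x$modality,
              x$spacing[1], x$spacing[2]))
  invisible(x)
}

#' Binary region-of-interest mask
#'
#' A single-lesion binary mask on the same pixel grid as its image. A valid
#' ROI has at least 16 true pixels (the smallest region on which a two-level
#' co-occurrence matrix and one Haar scale are defined) and its true pixels
#' form a single 8-connected component, mirroring a freehand single-lesion
#' delineation.
#'
#' @param mask logical (or 0/1) matrix.
#' @param id lesion identifier string.
#' @param check validate the ROI invariants (default `TRUE`). Internal
#'   callers that construct windows or intermediate masks may disable it.
#'
#' @return An object of class `roi_mask` with fields `mask` and `id`.
#' @export
roi_mask <- function(mask, id = "roi", check = TRUE) {
  mask <- as.matrix(mask)
  if (is.numeric(mask)) mask <- mask != 0
  if (!is.logical(mask)) stop("mask must be logical or numeric", call. = FALSE)
  mask[is.na(mask)] <- FALSE
  if (isTRUE(check)) {
    n <- sum(mask)
    if (n < 16L)
      stop(sprintf("invalid ROI: %d pixels (minimum 16)", n), call. = FALSE)
    if (!is_single_component(mask))
      stop("invalid ROI: true pixels are not a single 8-connected component",
           call. = FALSE)
  }
  structure(list(mask = mask, id = as.character(id)), class = "roi_mask")
}

#' @export
print.roi_mask <- function(x, ...) {
  cat(sprintf("<roi_mask '%s'> %d x %d grid, %d pixels\n",
              x$id, nrow(x$mask), ncol(x$mask), sum(x$mask)))
  invisible(x)
}

# 8-connected single-component test via flood fill (masks are small).
is_single_component <- function(mask) {
  n_true <- sum(mask)
  if (n_true == 0L) return(FALSE)
  nr <- nrow(mask); nc <- ncol(mask)
  seen <- matrix(FALSE, nr, nc)
  start <- which(mask)[1L]
  queue <- integer(n_true)
  queue[1L] <- start
  seen[start] <- TRUE
  head <- 1L; tail <- 1L
  dr <- c(-1L, -1L, -1L, 0L, 0L, 1L, 1L, 1L)
  dc <- c(-1L, 0L, 1L, -1L, 1L, -1L, 0L, 1L)
  while (head <= tail) {
    idx <- queue[head]; head <- head + 1L
    i <- ((idx - 1L) %% nr) + 1L
    j <- ((idx - 1L) %/% nr) + 1L
    for (d in 1:8) {
      ii <- i + dr[d]; jj <- j + dc[d]
      if (ii >= 1L && ii <= nr && jj >= 1L && jj <= nc) {
        kk <- (jj - 1L) * nr + ii
        if (mask[kk] && !seen[kk]) {
          seen[kk] <- TRUE
          tail <- tail + 1L
          queue[tail] <- kk
        }
      }
    }
  }
  tail == n_true
}

check_congruent <- function(image, mask) {
  if (!identical(dim(image$pixels), dim(mask$mask)))
    stop(sprintf("mask (%d x %d) is not congruent with image (%d x %d)",
                 nrow(mask$mask), ncol(mask$mask),
                 nrow(image$pixels), ncol(image$pixels)), call. = FALSE)
  invisible(TRUE)
}
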