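#' Class specification for the synthetic lesion simulator
#'
#' Describes one lesion class: mean ADC level, intensity SD, spatial
#' texture correlation length, and the lesion radius range. ADC values are
#' carried in units of 1e-3 mm^2/s (so invasive-tumor values are near 1.0
#' and fluid-like background near 2.2). Optionally a 4-vector of causal AR
#' coefficients replaces the Gaussian-random-field texture, for
#' parameter-recovery experiments on the autoregressive family.
#'
#' @param label class label string.
#' @param mean_adc mean lesion ADC (1e-3 mm^2/s units).
#' @param sd_adc intensity standard deviation of the lesion texture.
#' @param corr_length texture correlation length in pixels: the lag at
#'   which the field autocorrelation falls to one half.
#' @param radius_range lesion radius range in pixels, `c(min, max)`.
#' @param ar_theta optional causal AR coefficients (length 4).
#' @return A list of class `class_spec`.
#' @export
class_spec <- function(label, mean_adc = 1.0, sd_adc = 0.15,
                       corr_length = 2, radius_range = c(6, 12),
                       ar_theta = NULL) {
  stopifnot(sd_adc >= 0, corr_length > 0, length(radius_range) == 2,
            radius_range[1] <= radius_range[2], radius_range[1] >= 2)
  structure(list(label = as.character(label), mean_adc = mean_adc,
                 sd_adc = sd_adc, corr_length = corr_length,
                 radius_range = as.numeric(radius_range),
                 ar_theta = ar_theta),
            class = "class_spec")
}

#' Default four-class specification set
#'
#' Four lesion classes mirroring the molecular breast-cancer subtype
#' labels, with invasive-tumor ADC levels around 0.9-1.15 (1e-3 mm^2/s)
#' and class-specific texture correlation lengths. These values stand in
#' for subtype-specific diffusivity heterogeneity; they are illustrative,
#' not calibrated to patient data.
#' @param radius_range lesion radius range in pixels.
#' @return Named list of [class_spec()]s.
#' @export
default_class_specs <- function(radius_range = c(6, 12)) {
  list(
    luminalA = class_spec("luminalA", 1.15, 0.12, 1.5, radius_range),
    luminalB = class_spec("luminalB", 0.95, 0.18, 2.5, radius_range),
    HER2     = class_spec("HER2",     1.05, 0.22, 3.0, radius_range),
    TN       = class_spec("TN",       0.90, 0.15, 2.0, radius_range)
  )
}

# Gaussian random field: white noise convolved with a Gaussian kernel and
# empirically standardized. corr_length is the lag at which the field
# autocorrelation drops to 1/2; for a Gaussian kernel of width s the
# autocorrelation is exp(-x^2 / (4 s^2)), so s = corr_length / (2 sqrt(ln 2)).
gaussian_random_field <- function(nr, nc, corr_length) {
  s <- corr_length / (2 * sqrt(log(2)))
  half <- max(1L, as.integer(ceiling(3 * s)))
  kern <- stats::dnorm(seq(-half, half), sd = s)
  kern <- kern / sqrt(sum(kern^2))
  z <- matrix(stats::rnorm((nr + 2L * half) * (nc + 2L * half)),
              nr + 2L * half)
  z <- apply(z, 2, function(col) stats::convolve(col, kern, type = "filter"))
  z <- t(apply(z, 1, function(row) stats::convolve(row, kern, type = "filter")))
  (z - mean(z)) / stats::sd(z)
}

# Causal AR(4-neighbor) field for ARM-recovery experiments, standardized.
causal_ar_field <- function(nr, nc, theta) {
  x <- matrix(stats::rnorm(nr * nc), nr, nc)
  for (i in 2:nr) for (j in 2:(nc - 1)) {
    x[i, j] <- theta[1] * x[i, j - 1] + theta[2] * x[i - 1, j] +
      theta[3] * x[i - 1, j - 1] + theta[4] * x[i - 1, j + 1] +
      stats::rnorm(1)
  }
  (x - mean(x)) / stats::sd(x)
}

#' Simulate a star-convex lesion mask
#'
#' Radius profile `r(theta) = R (1 + sum_m a_m cos(m theta + phi_m))`,
#' m = 2..4, with perturbation amplitudes bounded so the total deviation is
#' at most 30 % of R, rasterized at pixel centers; emulates a freehand
#' lesion outline. Resamples (bounded retries) until the mask is a single
#' 8-connected component with at least 16 pixels.
#'
#' @param radius_range `c(min, max)` base radius R in pixels.
#' @param image_size image side length (square grid).
#' @param max_amplitude total boundary perturbation bound (default 0.3).
#' @param center optional `c(row, col)`; default image center with small
#'   jitter.
#' @return A [roi_mask()].
#' @export
make_lesion_mask <- function(radius_range, image_size = 48L,
                             max_amplitude = 0.3, center = NULL) {
  for (try in 1:25) {
    R <- stats::runif(1, radius_range[1], radius_range[2])
    if (is.null(center)) {
      ctr <- (image_size + 1) / 2 + stats::runif(2, -1.5, 1.5)
    } else ctr <- center
    amp <- stats::runif(3, 0, max_amplitude / 3)
    phi <- stats::runif(3, 0, 2 * pi)
    ii <- matrix(seq_len(image_size), image_size, image_size)
    jj <- t(ii)
    dy <- ii - ctr[1]; dx <- jj - ctr[2]
    r <- sqrt(dy^2 + dx^2)
    th <- atan2(dy, dx)
    rad <- R * (1 + amp[1] * cos(2 * th + phi[1]) +
                  amp[2] * cos(3 * th + phi[2]) +
                  amp[3] * cos(4 * th + phi[3]))
    m <- r <= pmax(rad, 1)
    if (sum(m) >= 16L && is_single_component(m))
      return(roi_mask(m, id = "lesion"))
  }
  stop("could not generate a valid lesion mask", call. = FALSE)
}

# Chessboard dilation by r pixels (r-fold 8-neighbor dilation).
dilate_mask <- function(m, r) {
  nr <- nrow(m); nc <- ncol(m)
  for (step in seq_len(r)) {
    out <- m
    out[-1, ] <- out[-1, ] | m[-nr, ]
    out[-nr, ] <- out[-nr, ] | m[-1, ]
    out[, -1] <- out[, -1] | m[, -nc]
    out[, -nc] <- out[, -nc] | m[, -1]
    out[-1, -1] <- out[-1, -1] | m[-nr, -nc]
    out[-1, -nc] <- out[-1, -nc] | m[-nr, -1]
    out[-nr, -1] <- out[-nr, -1] | m[-1, -nc]
    out[-nr, -nc] <- out[-nr, -nc] | m[-1, -1]
    m <- out
  }
  m
}

#' Simulate the b = 0 / high b-value signal pair and ADC map of one lesion
#'
#' The latent ADC field is `mean + SD * GRF(corr_length)` inside the
#' lesion, a fluid-like background (higher ADC, its own texture) outside,
#' and intermediate peritumoral values in a rim of width `rim_width` around
#' the lesion, so that a mask propagated from the high b-value image (the
#' dilated variant) imports off-lesion statistics. Signals follow
#' monoexponential decay: `S0 = signal + noise`,
#' `Sb = signal * exp(-b * ADC) + noise` with additive Gaussian noise at
#' the given SNR; the reported ADC map is recomputed from the noisy signal
#' pair as `ln(S0/Sb)/b`, so signal noise propagates into it. Non-positive
#' signals are clipped at a small floor before the logarithm (count
#' recorded in the `clipped` attribute).
#'
#' @param mask a [roi_mask()] (the true lesion mask).
#' @param spec a [class_spec()].
#' @param rim_width peritumoral rim width in pixels (default 2).
#' @param b diffusion weighting in s/mm^2 (default 1000).
#' @param s0 baseline signal (default 1000).
#' @param snr signal-to-noise ratio of the additive noise (default 50).
#' @param spacing pixel spacing in mm.
#' @param id lesion identifier.
#' @return List with `b0`, `dwi`, `adc` ([annotated_image()]s), `mask`,
#'   `mask_dilated`, `adc_latent`.
#' @export
simulate_lesion_images <- function(mask, spec, rim_width = 2L, b = 1000,
                                   s0 = 1000, snr = 50, spacing = c(1.4, 1.4),
                                   id = "lesion") {
  m <- mask$mask
  nr <- nrow(m); nc <- ncol(m)
  bg_mean <- 2.2; bg_sd <- 0.15; bg_len <- 3
  rim_mean <- (spec$mean_adc + bg_mean) / 2
  rim_sd <- (spec$sd_adc + bg_sd) / 2

  bg_field <- gaussian_random_field(nr, nc, bg_len)
  rim_field <- gaussian_random_field(nr, nc, 2)
  lesion_field <- if (is.null(spec$ar_theta))
    gaussian_random_field(nr, nc, spec$corr_length)
  else causal_ar_field(nr, nc, spec$ar_theta)

  dil <- dilate_mask(m, rim_width)
  rim <- dil & !m
  adc <- bg_mean + bg_sd * bg_field
  adc[rim] <- rim_mean + rim_sd * rim_field[rim]
  adc[m] <- spec$mean_adc + spec$sd_adc * lesion_field[m]
  adc <- pmax(adc, 0.05)

  noise_sd <- s0 / snr
  b0 <- s0 + matrix(stats::rnorm(nr * nc, sd = noise_sd), nr)
  sb <- s0 * exp(-b * adc * 1e-3) +
    matrix(stats::rnorm(nr * nc, sd = noise_sd), nr)
  floor_val <- s0 * 1e-4
  clipped <- sum(b0 < floor_val) + sum(sb < floor_val)
  b0 <- pmax(b0, floor_val)
  sb <- pmax(sb, floor_val)
  adc_map <- log(b0 / sb) / b * 1e3  # back to 1e-3 mm^2/s units

  out <- list(
    b0 = annotated_image(b0, spacing, "B0", paste0(id, "_b0")),
    dwi = annotated_image(sb, spacing, "DWI_HIGH_B", paste0(id, "_dwi")),
    adc = annotated_image(adc_map, spacing, "ADC", paste0(id, "_adc")),
    mask = roi_mask(m, id = id),
    mask_dilated = roi_mask(dil, id = paste0(id, "_dwiSeg")),
    adc_latent = adc, label = spec$label, id = id
  )
  attr(out, "clipped") <- clipped
  out
}

#' Generate a synthetic DWI/ADC lesion cohort
#'
#' Draws `n_per_class` lesions per class specification, each with a b = 0
#' image, a high b-value image, the derived ADC map, the exact lesion mask
#' (the "segmented on the ADC map" variant) and a dilated mask including a
#' peritumoral rim (the "propagated from high b-value DWI" variant). Fully
#' reproducible from `seed`.
#'
#' @param specs list of [class_spec()]s.
#' @param n_per_class integer vector (recycled) of lesions per class;
#'   defaults to the subtype mix 49/8/11/23 when four specs are given.
#' @param seed integer RNG seed (mandatory for provenance).
#' @param image_size square image side (default 48).
#' @param rim_width dilation width in pixels (default 2).
#' @param snr signal-to-noise ratio (default 50).
#' @param spacing pixel spacing mm (default 1.4 isotropic).
#' @return Object of class `synthetic_cohort`: `lesions` (list), `classes`,
#'   `params`.
#' @export
make_cohort <- function(specs, n_per_class = NULL, seed = 1L,
                        image_size = 48L, rim_width = 2L, snr = 50,
                        spacing = c(1.4, 1.4)) {
  if (length(specs) < 2L) stop("need at least 2 class specs", call. = FALSE)
  if (is.null(n_per_class))
    n_per_class <- if (length(specs) == 4L) c(49L, 8L, 11L, 23L)
                   else rep(25L, length(specs))
  n_per_class <- rep_len(as.integer(n_per_class), length(specs))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  lesions <- list()
  for (ci in seq_along(specs)) {
    sp <- specs[[ci]]
    for (li in seq_len(n_per_class[ci])) {
      id <- sprintf("%s_%03d", sp$label, li)
      mk <- make_lesion_mask(sp$radius_range, image_size)
      lesions[[id]] <- simulate_lesion_images(mk, sp, rim_width = rim_width,
                                              snr = snr, spacing = spacing,
                                              id = id)
    }
  }
  structure(list(lesions = lesions,
                 classes = vapply(specs, function(s) s$label, character(1)),
                 params = list(seed = seed, image_size = image_size,
                               rim_width = rim_width, snr = snr,
                               spacing = spacing,
                               n_per_class = n_per_class,
                               specs = specs)),
            class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf("<synthetic_cohort> %d lesions, classes: %s (seed %d)\n",
              length(x$lesions), paste(x$classes, collapse = ", "),
              x$params$seed))
  invisible(x)
}

#' Write a synthetic cohort to disk (NIfTI + JSON manifest)
#'
#' @param cohort a [make_cohort()] result.
#' @param dir output directory (created if absent).
#' @return The manifest path, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  entries <- data.frame(id = character(), image = character(),
                        mask = character(), mask_dwi = character(),
                        label = character(), stringsAsFactors = FALSE)
  for (les in cohort$lesions) {
    img <- paste0(les$id, "_adc.nii.gz")
    mk <- paste0(les$id, "_mask.nii.gz")
    mkd <- paste0(les$id, "_mask_dwi.nii.gz")
    write_image(les$adc, file.path(dir, img))
    write_mask(les$mask, file.path(dir, mk))
    write_mask(les$mask_dilated, file.path(dir, mkd))
    entries <- rbind(entries, data.frame(id = les$id, image = img, mask = mk,
                                         mask_dwi = mkd, label = les$label,
                                         stringsAsFactors = FALSE))
  }
  man <- list(classes = cohort$classes, entries = entries,
              params = cohort$params[c("seed", "image_size", "rim_width",
                                       "snr")])
  path <- file.path(dir, "manifest.json")
  jsonlite::write_json(man, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, dataframe = "rows")
  invisible(path)
}

#' Load a cohort from a manifest written by [write_cohort()] (or assembled
#' by hand) into the in-memory cohort structure used by the pipeline.
#' @param manifest_path path to the manifest JSON.
#' @return A cohort list compatible with [extract_cohort()].
#' @export
load_cohort <- function(manifest_path) {
  man <- read_manifest(manifest_path)
  lesions <- list()
  for (r in seq_len(nrow(man$entries))) {
    e <- man$entries[r, ]
    adc <- read_image(e$image, "ADC", id = e$id)
    mk <- read_mask(e$mask, adc, id = e$id)
    mkd <- if (!is.null(e$mask_dwi) && !is.na(e$mask_dwi))
      read_mask(e$mask_dwi, adc, id = paste0(e$id, "_dwiSeg")) else NULL
    lesions[[e$id]] <- list(adc = adc, mask = mk, mask_dilated = mkd,
                            label = e$label, id = e$id)
  }
  structure(list(lesions = lesions, classes = man$classes,
                 params = list(manifest = manifest_path)),
            class = "synthetic_cohort")
}
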