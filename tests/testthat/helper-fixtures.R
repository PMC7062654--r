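# Shared fixtures: direct construction of quantized ROIs and random masks.

# Build a quantized_roi directly from an integer level matrix (NA outside
# the mask), bypassing normalization -- used to test matrix operations on
# exactly known levels.
quantized_from_levels <- function(levels, n_levels = max(levels, na.rm = TRUE)) {
  levels <- as.matrix(levels)
  storage.mode(levels) <- "integer"
  structure(list(levels = levels, mask = !is.na(levels),
                 n_levels = as.integer(n_levels),
                 params = list(n_levels = as.integer(n_levels)),
                 id = "fixture"),
            class = "quantized_roi")
}

# Random connected mask of size nr x nc with >= min_px pixels: full
# rectangle with a few pixels knocked out, resampled until connected.
random_small_mask <- function(nr, nc, n_off = sample(0:4, 1), min_px = 16) {
  n_off <- max(0L, min(n_off, nr * nc - min_px))
  repeat {
    m <- matrix(TRUE, nr, nc)
    if (n_off > 0) m[sample(nr * nc, n_off)] <- FALSE
    if (sum(m) >= min_px &&
        adcradiomics:::is_single_component(m)) return(m)
  }
}

random_roi_case <- function(nr = sample(4:8, 1), nc = sample(4:8, 1),
                            ng = sample(2:6, 1)) {
  m <- random_small_mask(nr, nc)
  lv <- matrix(NA_integer_, nr, nc)
  lv[m] <- sample(ng, sum(m), replace = TRUE)
  img <- annotated_image(matrix(rnorm(nr * nc), nr, nc), spacing = c(1, 1),
                         modality = "ADC")
  list(levels = lv, mask = m, ng = ng, image = img,
       q = quantized_from_levels(lv, ng),
       roi = roi_mask(m, check = FALSE))
}

# A small planted-feature table: n informative features shifted by delta
# pooled SDs between classes, the rest pure noise.
planted_table <- function(n_per_class = 25, n_features = 50,
                          n_informative = 10, delta = 2) {
  n <- 2 * n_per_class
  X <- matrix(rnorm(n * n_features), n, n_features)
  labels <- rep(c("A", "B"), each = n_per_class)
  inf_idx <- seq_len(n_informative)
  X[labels == "B", inf_idx] <- X[labels == "B", inf_idx] + delta
  colnames(X) <- sprintf("f%02d", seq_len(n_features))
  list(table = feature_table(X, labels), informative = colnames(X)[inf_idx])
}

# Two-class cohort generator used by classification/pipeline tests: small
# images and a reduced feature configuration keep replicate simulations
# fast while exercising every family.
test_config <- function(mode = "paper", mask_variant = "ADC_MASK") {
  pipeline_config(
    features = radiomics_config(glcm_distances = 1:2, wav_max_scale = 2),
    mode = mode, mask_variant = mask_variant)
}

two_class_cohort <- function(seed, len_a = 1, len_b = 3, n = 25,
                             mean_a = 1.0, mean_b = 1.0,
                             sd_a = 0.15, sd_b = 0.15,
                             radius = c(5, 8), image_size = 32,
                             snr = 50) {
  specs <- list(class_spec("A", mean_a, sd_a, len_a, radius),
                class_spec("B", mean_b, sd_b, len_b, radius))
  make_cohort(specs, n_per_class = n, seed = seed, image_size = image_size,
              snr = snr)
}
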