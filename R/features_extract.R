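#' Canonical feature catalogue
#'
#' The ordered names of every feature [extract_all()] produces under a
#' configuration. Selection results and feature tables always use these
#' names; ties in selection are broken by this order.
#'
#' @param config a [radiomics_config()].
#' @return Character vector of feature names.
#' @export
feature_catalogue <- function(config = radiomics_config()) {
  his <- paste0("his_", c("mean", "variance", "skewness", "kurtosis",
                          "perc01", "perc10", "perc50", "perc90", "perc99"))
  glcm_feats <- c("asm", "contrast", "correlation", "sum_of_squares", "idm",
                  "sum_average", "sum_variance", "sum_entropy", "entropy",
                  "difference_variance", "difference_entropy")
  com <- as.vector(sapply(config$glcm_distances, function(d)
    sapply(config$angles, function(a)
      sprintf("com_d%d_a%03d_%s", d, a, glcm_feats))))
  rlmn <- as.vector(sapply(config$angles, function(a)
    sprintf("rlm_a%03d_%s", a, c("sre", "lre", "gln", "rln", "fraction"))))
  grad <- paste0("grad_", c("mean", "variance", "skewness", "kurtosis",
                            "nonzero_fraction"))
  arm <- c(paste0("arm_theta", 1:4), "arm_sigma")
  wav <- as.vector(sapply(seq_len(config$wav_max_scale), function(s)
    sprintf("wav_s%d_%s", s, c("ll", "hl", "lh", "hh"))))
  geo <- c("geo_area_mm2", "geo_perimeter_mm", "geo_circularity",
           "geo_elongation", "geo_feret_mm")
  c(his, com, rlmn, grad, arm, wav, geo)
}

#' Extract the full radiomic feature vector of one lesion
#'
#' Computes all seven families on a single 2-D ROI. The histogram,
#' co-occurrence, run-length and autoregressive families operate on
#' quantized levels (after [normalize_roi()], with per-family Ng); the
#' gradient and Haar families operate on the raw intensities; geometry
#' operates on the mask alone. Incomputable features are returned as `NA`,
#' never dropped, so every lesion yields a vector of identical length and
#' order ([feature_catalogue()]).
#'
#' @param image an [annotated_image()] (typically the ADC map).
#' @param mask a [roi_mask()].
#' @param config a [radiomics_config()].
#' @return Named numeric vector in catalogue order.
#' @export
extract_all <- function(image, mask, config = radiomics_config()) {
  check_congruent(image, mask)
  q_his <- normalize_roi(image, mask, config$his_levels, config$clip_k)
  q_glcm <- if (config$glcm_levels == config$his_levels) q_his
            else normalize_roi(image, mask, config$glcm_levels, config$clip_k)
  q_rlm <- if (config$rlm_levels == config$glcm_levels) q_glcm
           else normalize_roi(image, mask, config$rlm_levels, config$clip_k)
  out <- c(
    his_features(q_his),
    com_block(q_glcm, config$glcm_distances, config$angles),
    rlm_block(q_rlm, config$angles),
    gradient_features(image, mask),
    arm_fit(q_glcm, config$arm_min_pixels),
    haar_features(image, mask, config$wav_max_scale),
    geometry_features(mask, image$spacing)
  )
  catalogue <- feature_catalogue(config)
  stopifnot(identical(names(out), catalogue))
  attr(out, "provenance") <- list(
    his_levels = config$his_levels, glcm_levels = config$glcm_levels,
    rlm_levels = config$rlm_levels, distances = config$glcm_distances,
    angles = config$angles, wav_max_scale = config$wav_max_scale,
    clip_k = config$clip_k)
  out
}

#' Extract features for every lesion of a cohort
#'
#' @param cohort a [make_cohort()] result or a loaded manifest cohort
#'   (see [load_cohort()]).
#' @param config a [pipeline_config()] (its `features` and `mask_variant`
#'   fields are used).
#' @return A [feature_table()]; lesions whose extraction fails are dropped
#'   and recorded in the `excluded` attribute.
#' @export
extract_cohort <- function(cohort, config = pipeline_config()) {
  fc <- config$features
  rows <- list(); labels <- character(); ids <- character()
  excluded <- list()
  for (les in cohort$lesions) {
    mk <- if (config$mask_variant == "ADC_MASK") les$mask else les$mask_dilated
    fv <- tryCatch(extract_all(les$adc, mk, fc), error = function(e) e)
    if (inherits(fv, "error")) {
      excluded[[les$id]] <- conditionMessage(fv)
      next
    }
    rows[[les$id]] <- fv
    labels <- c(labels, les$label)
    ids <- c(ids, les$id)
  }
  if (length(rows) == 0L) stop("no lesion could be analyzed", call. = FALSE)
  tab <- feature_table(do.call(rbind, rows), labels = labels, ids = ids)
  attr(tab, "excluded") <- excluded
  attr(tab, "config") <- config
  tab
}

#' Sliding-window feature map
#'
#' Recomputes one catalogue feature in a square window centered at every
#' mask pixel (window clipped to the mask), visualizing the spatial
#' distribution of the feature across the lesion. Pixels outside the mask
#' are `NA`.
#'
#' @param image an [annotated_image()].
#' @param mask a [roi_mask()].
#' @param feature_name one catalogue feature name.
#' @param window odd window side length >= 3 (default 9).
#' @param config a [radiomics_config()].
#' @return A matrix the size of the image with attributes `feature`,
#'   `window` and `spacing`; write with [write_image()].
#' @export
feature_map <- function(image, mask, feature_name, window = 9L,
                        config = radiomics_config()) {
  window <- as.integer(window)
  if (window < 3L || window %% 2L == 0L)
    stop("window must be an odd integer >= 3", call. = FALSE)
  if (!feature_name %in% feature_catalogue(config))
    stop("unknown feature: ", feature_name, call. = FALSE)
  check_congruent(image, mask)
  h <- window %/% 2L
  m <- mask$mask
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(NA_real_, nr, nc)
  px <- which(m, arr.ind = TRUE)
  for (r in seq_len(nrow(px))) {
    i <- px[r, 1]; j <- px[r, 2]
    ri <- max(1L, i - h):min(nr, i + h)
    ci <- max(1L, j - h):min(nc, j + h)
    subm <- matrix(FALSE, nr, nc)
    subm[ri, ci] <- m[ri, ci]
    val <- tryCatch(
      compute_single_feature(image, subm, feature_name, config),
      error = function(e) NA_real_)
    out[i, j] <- val
  }
  attr(out, "feature") <- feature_name
  attr(out, "window") <- window
  attr(out, "spacing") <- image$spacing
  out
}

# Compute one named feature on an arbitrary (possibly tiny, possibly
# disconnected) sub-mask; validity checks are bypassed because windows
# clipped to the mask need not satisfy the ROI invariants.
compute_single_feature <- function(image, submask, feature_name, config) {
  mk <- roi_mask(submask, id = "window", check = FALSE)
  if (sum(submask) < 2L) return(NA_real_)
  fam <- sub("_.*", "", feature_name)
  vec <- switch(fam,
    his = his_features(normalize_roi(image, mk, config$his_levels,
                                     config$clip_k)),
    com = {
      pr <- regmatches(feature_name,
                       regexec("^com_d(\\d+)_a(\\d+)_", feature_name))[[1]]
      d <- as.integer(pr[2]); a <- as.numeric(pr[3])
      q <- normalize_roi(image, mk, config$glcm_levels, config$clip_k)
      glcm_features(glcm(q, d = d, angle = a),
                    prefix = sprintf("com_d%d_a%03d", d, a))
    },
    rlm = {
      a <- as.numeric(regmatches(feature_name,
                                 regexec("^rlm_a(\\d+)_", feature_name))[[1]][2])
      q <- normalize_roi(image, mk, config$rlm_levels, config$clip_k)
      rlm_features(rlm(q, angle = a), prefix = sprintf("rlm_a%03d", a))
    },
    grad = gradient_features(image, mk),
    arm = arm_fit(normalize_roi(image, mk, config$glcm_levels, config$clip_k),
                  config$arm_min_pixels),
    wav = haar_features(image, mk, config$wav_max_scale),
    geo = geometry_features(mk, image$spacing),
    stop("unknown feature family: ", fam, call. = FALSE))
  unname(vec[feature_name])
}
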