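#' Texture feature configuration
#'
#' Controls the feature catalogue produced by [extract_all()]. The number of
#' gray levels Ng can be chosen per family (histogram, co-occurrence,
#' run-length); the clip factor of the gray-level normalization is fixed at
#' 3 (dynamics limited to mean +/- 3 SD) and exposed read-only.
#'
#' @param his_levels,glcm_levels,rlm_levels integer Ng >= 2 used to quantize
#'   the ROI for the histogram, co-occurrence and run-length families
#'   (default 64, i.e. 6 bits).
#' @param glcm_distances integer vector of pixel offsets for the
#'   co-occurrence matrix (default 1:5).
#' @param angles directions in degrees, subset of `c(0, 45, 90, 135)`,
#'   shared by the co-occurrence and run-length families.
#' @param wav_max_scale largest Haar scale reported (default 3; subbands
#'   whose support exceeds the lesion are reported as missing).
#' @param arm_min_pixels minimum number of usable pixels for the
#'   autoregressive fit (default 20).
#'
#' @return A list of class `radiomics_config`.
#' @export
radiomics_config <- function(his_levels = 64L, glcm_levels = 64L,
                             rlm_levels = 64L, glcm_distances = 1:5,
                             angles = c(0, 45, 90, 135),
                             wav_max_scale = 3L, arm_min_pixels = 20L) {
  stopifnot(his_levels >= 2, glcm_levels >= 2, rlm_levels >= 2,
            all(glcm_distances >= 1), all(angles %in% c(0, 45, 90, 135)),
            wav_max_scale >= 1, arm_min_pixels >= 5)
  structure(list(
    his_levels = as.integer(his_levels),
    glcm_levels = as.integer(glcm_levels),
    rlm_levels = as.integer(rlm_levels),
    glcm_distances = as.integer(glcm_distances),
    angles = as.numeric(angles),
    wav_max_scale = as.integer(wav_max_scale),
    arm_min_pixels = as.integer(arm_min_pixels),
    clip_k = 3.0
  ), class = "radiomics_config")
}

#' Pipeline configuration
#'
#' Bundles every tunable of the analysis pipeline: the feature
#' configuration, the selection parameters, the classifier, and which mask
#' variant of a cohort is analyzed. The configuration is serialized verbatim
#' into every report so that no result is emitted without provenance.
#'
#' @param features a [radiomics_config()].
#' @param select_k number of features retained per selection criterion
#'   (default 10, one set of ten per criterion).
#' @param mi_bins number of equal-frequency bins for the mutual-information
#'   criterion (default 8).
#' @param k odd positive integer, the k of k-nearest-neighbor (default 1).
#' @param mode `"paper"` (selection and LDA fit once on the full table,
#'   leave-one-out applied to the k-NN vote only) or `"nested"` (selection
#'   and LDA refit inside every leave-one-out fold).
#' @param mask_variant `"ADC_MASK"` (exact lesion mask, drawn on the ADC
#'   map) or `"DWI_MASK"` (dilated mask propagated from the high b-value
#'   image, including a peritumoral rim).
#' @param clinical_threshold accuracy (%) at or above which a task is
#'   flagged as clinically relevant (default 80).
#'
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(features = radiomics_config(),
                            select_k = 10L, mi_bins = 8L, k = 1L,
                            mode = c("paper", "nested"),
                            mask_variant = c("ADC_MASK", "DWI_MASK"),
                            clinical_threshold = 80) {
  mode <- match.arg(mode)
  mask_variant <- match.arg(mask_variant)
  k <- as.integer(k)
  if (k < 1L || k %% 2L == 0L)
    stop("k must be an odd positive integer", call. = FALSE)
  stopifnot(inherits(features, "radiomics_config"),
            select_k >= 1, mi_bins >= 2)
  structure(list(features = features, select_k = as.integer(select_k),
                 mi_bins = as.integer(mi_bins), k = k, mode = mode,
                 mask_variant = mask_variant,
                 clinical_threshold = as.numeric(clinical_threshold),
                 lda_shrinkage = 1e-3),
            class = "pipeline_config")
}
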