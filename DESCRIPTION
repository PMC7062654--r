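Package: adcradiomics
Title: Texture Radiomics of Apparent Diffusion Coefficient Maps
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Radiomic texture analysis of 2-D lesion regions of interest on
    apparent diffusion coefficient (ADC) maps derived from diffusion-weighted
    MRI. Implements MaZda-style gray-level normalization (dynamics limited to
    the ROI mean plus or minus three standard deviations), seven texture
    feature families (first-order histogram, gray-level co-occurrence matrix,
    run-length matrix, absolute gradient, causal autoregressive model, Haar
    wavelet subband energies, and lesion geometry), three univariate feature
    selection criteria (Fisher coefficient, probability of classification
    error with average correlation, and mutual information), linear
    discriminant reduction to most-discriminatory features, and k-nearest
    neighbor classification with leave-one-out cross-validation for pairwise
    and one-versus-rest contrasts between lesion classes. A synthetic
    DWI/ADC lesion-cohort simulator with class-specific texture and two
    segmentation variants (exact lesion mask and peritumorally dilated mask)
    makes every pipeline stage testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    RNifti,
    jsonlite,
    png,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    MASS,
    withr,
    knitr
Config/testthat/edition: 3
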