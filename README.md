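# adcradiomics

Texture radiomics of apparent diffusion coefficient (ADC) maps from
diffusion-weighted MRI (DWI), for researchers who want to test whether the
spatial heterogeneity of tissue diffusivity separates lesion classes (for
example breast-cancer molecular subtypes or receptor status) from a single
2-D region of interest per lesion.

The package implements the full MaZda-style analysis chain as tested,
reusable R functions:

1. **Gray-level normalization** of each ROI: dynamics limited to
   μ ± 3σ (ROI mean and population SD), then quantization to Ng levels
   (default 64).
2. **Seven texture-feature families** on the ROI: first-order histogram
   (HIS), gray-level co-occurrence matrices (COM; d = 1..5, four
   directions, 11 Haralick-style descriptors each), run-length matrices
   (RLM; Galloway set), absolute gradient, causal autoregressive model
   (ARM), Haar wavelet subband energies (WAV), and lesion geometry —
   276 named features under the default configuration, plus
   sliding-window feature maps for visualization.
3. **Feature selection**, ten features per criterion and binary task:
   Fisher coefficient (between/within-class variance ratio), POE + ACC
   (probability of single-threshold classification error plus average
   correlation, greedy), and mutual information (equal-frequency bins).
4. **LDA reduction** of each selected set to its most discriminatory
   feature (MDF), w = S_w⁻¹(m₁ − m₀) with shrinkage for singular scatter.
5. **k-NN classification (k = 1 default) with leave-one-out
   cross-validation** for every pairwise and one-vs-rest task, reporting
   the misclassification percentage per criterion, the best criterion per
   task, and an accuracy grid with a configurable 80 % clinical-relevance
   flag. Both the classical *paper* protocol (selection + LDA on the full
   table, LOOCV over the k-NN vote only) and an honest *nested* protocol
   (selection + LDA refit per fold) are available and labeled.

Because clinical ADC data cannot ship with the package, a **synthetic
DWI/ADC cohort generator** produces star-convex lesions with
class-specific texture (Gaussian random fields with controlled correlation
length) from simulated b = 0 / b = 1000 signal pairs — ADC = ln(S0/Sb)/b,
recomputed from the noisy signals — with two segmentation variants per
lesion: the exact lesion mask ("drawn on the ADC map") and a dilated mask
including a peritumoral rim ("propagated from high b-value DWI").

Inputs: NIfTI (`.nii`/`.nii.gz`), 16-bit PNG or CSV-grid images and masks,
a JSON cohort manifest, CSV feature tables, JSON reports. See the methods
vignette (`vignettes/adc-radiomics-methods.Rmd`) for every convention and
design decision.

## Worked example

Simulate a 25 + 25 lesion cohort in which the two classes differ only in
texture correlation length (1 vs 3 pixels — "solid" vs "mixed"
architecture at identical mean ADC), then run the full pipeline:

```r
library(adcradiomics)

specs <- list(
  class_spec("solid", mean_adc = 0.95, sd_adc = 0.15, corr_length = 1,
             radius_range = c(5, 8)),
  class_spec("mixed", mean_adc = 0.95, sd_adc = 0.15, corr_length = 3,
             radius_range = c(5, 8)))
cohort <- make_cohort(specs, n_per_class = 25, seed = 42, image_size = 32)

cfg <- pipeline_config(
  features = radiomics_config(glcm_distances = 1:2, wav_max_scale = 2))
res <- run_pipeline(cohort, cfg)
res
#> <pipeline_result> 50 lesions x 140 features, variant ADC_MASK
#> <classification_report> 2 classes, 3 tasks, mode paper, k = 1
#>   solid vs mixed               n= 50  100.0 % (FISHER) *
#>   solid vs others              n= 50  100.0 % (FISHER) *
#>   mixed vs others              n= 50  100.0 % (FISHER) *
```

Each grid line is one binary task: `n` lesions entered the task, the
accuracy is 100 − misclassification % under LOOCV, the tag names the
selection criterion that achieved it, and `*` flags accuracies at or above
the 80 % threshold. A pure correlation-length contrast of 3:1 is separated
perfectly, and the features doing the work are exactly where texture
theory puts them — co-occurrence contrast/correlation at short distances:

```r
select_features(res$feature_table, "FISHER", k = 5)
#> <selected_features> criterion FISHER, 5 features
#>    1. com_d1_a045_difference_variance  9.152
#>    2. com_d1_a045_correlation          8.56
#>    3. com_d1_a045_contrast             8.317
#>    4. com_d1_a000_contrast             7.799
#>    5. com_d1_a135_contrast             7.646
```

`compare_mask_variants(cohort, cfg)` repeats the run with the rim-dilated
masks and tabulates both grids side by side; `run_pipeline(..., out_dir =
"out")` writes `features.csv`, `grid.csv` and `report.json` with the full
configuration embedded.

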