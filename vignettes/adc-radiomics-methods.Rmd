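---
title: "Texture radiomics of ADC maps: models, conventions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Texture radiomics of ADC maps: models, conventions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(adcradiomics)
```

## The analysis problem

Diffusion-weighted MRI (DWI) measures how freely water diffuses through
tissue. From a signal pair acquired at two diffusion weightings --- $S_0$ at
$b = 0$ and $S_b$ at $b = 1000\ \mathrm{s/mm^2}$ --- the apparent diffusion
coefficient map is

$$\mathrm{ADC} = \frac{\ln(S_0 / S_b)}{b},$$

a quantitative image in which densely cellular tumor tissue appears dark
(hindered diffusion) and fluid bright. The working hypothesis behind this
package is that the *spatial heterogeneity* of diffusivity inside a breast
lesion carries information about its biology, and that texture statistics
computed over a lesion region of interest (ROI) on the ADC map can separate
lesion classes (for example molecular subtypes defined by receptor status).

The pipeline is: delineate one 2-D ROI per lesion on the slice with the
largest lesion diameter; normalize the ROI gray levels; compute seven
families of texture features; select ten features per selection criterion
for each binary contrast; reduce each selected set to a single most
discriminatory feature (MDF) by linear discriminant analysis; and classify
with a k-nearest-neighbor rule under leave-one-out cross-validation
(LOOCV), reporting the percentage of misclassified lesions. Because
clinical ADC data cannot ship with the package, a synthetic DWI/ADC cohort
generator produces lesions with class-specific texture so that every stage
is exercisable and testable.

## Gray-level normalization

Texture statistics on raw scanner units would confound texture with
brightness and contrast. Each ROI is therefore normalized independently:
with $\mu$ and $\sigma$ the ROI mean and *population* standard deviation
(divisor $N$ --- this is a dynamics limit, not an inferential estimate),
intensities are clipped to $[\mu - 3\sigma,\ \mu + 3\sigma]$ and mapped
linearly onto integer levels $1..N_g$ with half-open bins whose top edge is
closed, so exactly $N_g$ levels are reachable and the upper clip bound maps
to $N_g$. A degenerate ROI with $\sigma = 0$ maps to level 1 everywhere so
that downstream matrices stay well defined rather than erroring. The
default $N_g = 64$ (6 bits) is configurable per family
(`radiomics_config()`); the clip factor 3 is fixed and exposed read-only.
Consequences that the test suite asserts: the quantized levels are
invariant under positive affine intensity rescaling, always lie in
$[1, N_g]$, and their histogram has exactly the ROI's pixel count.

## The seven feature families

Quantized-level families (histogram, co-occurrence, run-length,
autoregressive) operate on the normalized levels; the gradient and wavelet
families operate on raw intensities (their statistics are differences, so
global offset cancels); geometry uses the mask alone.

* **HIS** --- mean, population variance, skewness, excess kurtosis and the
  nearest-rank percentiles 1/10/50/90/99 of the level distribution.
  Nearest-rank is used deliberately: it is the literal "smallest value with
  at least $p\%$ of the sample at or below it", so an independent oracle
  can be written directly from the definition.
* **COM** --- gray-level co-occurrence matrices for distances $d = 1..5$ and
  directions $0/45/90/135^\circ$, symmetrized (both opposite offsets) and
  normalized, restricted to pixel pairs entirely inside the mask. Eleven
  classical descriptors per matrix (angular second moment, contrast,
  correlation, sum of squares, inverse difference moment, sum average, sum
  variance, sum entropy, entropy, difference variance, difference
  entropy). All entropies use the natural logarithm with $0 \log 0 := 0$;
  the base only rescales features and downstream selection/classification
  are scale-tolerant, but it is fixed and documented. Sum variance is
  taken about the sum average (the commonly accepted reading; the
  historical formula that references sum entropy instead is widely
  considered a typo). Correlation is missing when a marginal has zero
  variance.
* **RLM** --- run-length matrices in the four directions; a run is a maximal
  collinear sequence of equal levels that ends at a level change or at the
  mask boundary. Features: short- and long-run emphasis, gray-level and
  run-length nonuniformity, and the fraction of the ROI in runs (total
  runs / pixel count). The suite asserts the conservation identity
  $\sum_g \sum_r r\,R(g,r) = $ pixel count in every direction.
* **Absolute gradient** --- central-difference magnitude
  $g = \tfrac12\sqrt{(x_{i+1,j}-x_{i-1,j})^2 + (x_{i,j+1}-x_{i,j-1})^2}$
  at every pixel whose 4-neighborhood lies inside the mask; moments of $g$
  plus the nonzero fraction.
* **ARM** --- least-squares fit of the causal prediction
  $x_{i,j} = \theta_1 x_{i,j-1} + \theta_2 x_{i-1,j} + \theta_3 x_{i-1,j-1}
  + \theta_4 x_{i-1,j+1} + e$ on mean-centered levels (centering removes
  the intercept), using pixels whose four causal neighbors are in the
  mask; at least 20 such pixels are required, otherwise the family is
  missing. Rank-deficient systems take the minimum-norm SVD solution, so a
  constant ROI gives $\theta = 0$ exactly. Reported: $\theta_{1..4}$ and
  the residual standard deviation. A recovery test generates a causal
  field with known $\theta$ and checks the estimate to $\pm 0.1$.
* **WAV** --- non-standard (Mallat) separable Haar transform on the mask's
  bounding box, outside-mask pixels filled with the ROI mean. At each
  scale the four orthonormal subband energies are the means of squared
  coefficients whose $2^s \times 2^s$ support lies *entirely inside the
  mask*; subbands with no fully supported coefficient are missing. The
  masked-coefficient rule was chosen over cropping to an inscribed dyadic
  square because it uses irregular freehand-style ROIs maximally.
  Orientation convention (fixed in the documentation): HL is the
  vertical-difference subband (high-pass along rows). On full dyadic boxes
  the transform satisfies Parseval's identity, which the suite asserts to
  $10^{-9}$.
* **Geometry** --- area (pixel count times pixel area), perimeter (length of
  the 8-connected outer contour traced through pixel centers,
  Moore-neighbor tracing with Jacob's stopping criterion), circularity
  $4\pi A / P^2$, elongation $\sqrt{\lambda_{\min}/\lambda_{\max}}$ from
  the second-order central moments, and the maximal Feret diameter. All
  are invariant under $90^\circ$ rotations at isotropic spacing.

`extract_all()` concatenates the families into one vector per lesion whose
names come from a frozen catalogue (`feature_catalogue()`); incomputable
features are reported as missing, never dropped, so every lesion yields a
vector of identical length and order. `feature_map()` recomputes any single
catalogue feature in a sliding window clipped to the mask, for visualizing
spatial heterogeneity; maps are illustrative and feed nothing downstream.

## Feature selection

Each criterion scores features individually for one binary task and
returns the ten best; features with missing values or zero variance are
excluded from candidacy and recorded with reasons. Ties are broken by
canonical catalogue order so results are reproducible.

* **Fisher coefficient** --- between-class over within-class variance with
  population class variances; a perfectly separating feature scores
  $+\infty$ and ranks above all finite scores.
* **POE + ACC** --- greedy: the first feature minimizes the probability of
  error of the best single-threshold classifier (exhaustive scan over
  thresholds midway between consecutive distinct values, both polarities
  --- deterministic and parameter-free); each later feature minimizes
  POE plus the mean absolute Pearson correlation with the already selected
  features, weighted 1:1.
* **MI** --- mutual information (nats) between the class label and the
  feature discretized into 8 equal-frequency bins (duplicate quantile
  edges merged), which makes the score invariant under strictly monotone
  transforms.

A property worth understanding when interpreting recovery experiments:
features that all carry the same class contrast are mutually correlated
*through the label* (two features shifted by $\Delta$ pooled SDs
cross-correlate at $r = (\Delta^2/4)/(1 + \Delta^2/4)$, i.e. $r = 0.5$ at
$\Delta = 2$). The average-correlation penalty therefore deliberately
trades some genuinely informative but redundant features for uncorrelated
ones once a few have been selected. On planted-feature tables the first
POE+ACC pick is reliably informative and overall recovery sits clearly
above chance but below Fisher and MI --- by design of the criterion, not by
defect. Fisher and MI, which score features independently, recover
essentially all planted features at $\Delta = 2$.

## LDA reduction and k-NN with LOOCV

For each criterion's ten features, a Fisher discriminant
$w = S_w^{-1}(m_1 - m_0)$ is computed on z-scored features (training
statistics), with pooled within-class scatter $S_w$. Because class sizes
as small as 8 with 10 features make $S_w$ ill-conditioned, a singular
scatter receives diagonal shrinkage $S_w + \lambda\,\mathrm{tr}(S_w)/p\,I$
with $\lambda = 10^{-3}$ (reported in the output), then a minimum-norm
pseudo-inverse if still singular. The projected coordinate $w \cdot x$ is
the MDF; the sign convention puts the second-listed class at the higher
projected mean.

k-NN (default $k = 1$, configurable odd $k$) with LOOCV predicts each
lesion from its $k$ nearest remaining lesions by Euclidean distance on the
MDF coordinate. Every tie is specified: distance ties prefer the lower
lesion index; even vote splits go to the larger class, then to the lower
label order. Fixed input therefore yields a bit-identical report.

Two protocols are implemented and labeled rather than silently choosing
one:

* **paper mode** (default): selection and LDA are fit once on the full
  table; LOOCV wraps only the k-NN vote. This mirrors the protocol as
  classically described for this tool chain, and it is *optimistic*: with
  a couple hundred candidate features and $n \approx 50$, chance
  separations found on the full data survive into the held-out
  prediction.
* **nested mode**: selection and LDA are refit inside every fold and the
  held-out lesion is projected by the fold's model. This is the honest
  protocol for small cohorts.

The replicate experiments in the acceptance suite and
`scripts/acceptance.R` quantify both effects on null cohorts (identical
class generators): nested per-fold prediction is unbiased, the *best of
three criteria* adds a multiplicity lift above 50 %, and paper mode adds a
substantially larger selection-optimism lift on top. The suite asserts the
direction (paper-mode mean $\ge$ nested-mode mean); the script reports the
computed magnitudes. This is why reported task grids always carry their
mode label.

`run_all_tasks()` enumerates all unordered class pairs and each class
against the pooled rest (plus any user-declared label contrasts), reports
all three criteria per task with the best criterion tagged, and flags
accuracies at or above the configurable 80 % threshold;
`report_grid_matrix()` renders the symmetric accuracy grid.

## The synthetic cohort generator

The generator emulates exactly what the pipeline consumes --- per-class ADC
lesions derived from a simulated $b=0$ / $b=1000$ signal pair with two
mask variants --- without claiming anatomical realism.

* **Masks**: star-convex blobs, radius profile
  $R(1 + \sum_{m=2}^{4} a_m \cos(m\theta + \phi_m))$ with total
  perturbation bounded by 30 %, rasterized at pixel centers; zero
  perturbation gives an exact rasterized disk (tested). Resampling with
  bounded retries guarantees a valid single-component ROI.
* **Texture**: the latent lesion ADC field is mean + SD $\times$ a
  Gaussian random field (white noise convolved with a Gaussian kernel,
  standardized). The correlation length $\ell$ is *defined* as the lag at
  which the field autocorrelation falls to $1/2$; the kernel width is
  derived from that definition ($s = \ell / (2\sqrt{\ln 2})$), making the
  construction self-consistently testable (the suite checks the empirical
  half-correlation lag to $\pm 30\%$). An optional causal-AR texture
  supports ARM parameter-recovery experiments.
* **Signals**: $S_0$ at 1000 with additive Gaussian noise at SNR 50
  (default), $S_b = S_0 e^{-b \cdot \mathrm{ADC}}$ plus noise, floors
  applied before the logarithm (clip count recorded). The reported ADC
  map is recomputed from the noisy pair, so signal noise propagates into
  it --- ADC maps are derived, noisy quantities. ADC values are carried in
  units of $10^{-3}\ \mathrm{mm^2/s}$: lesion means 0.90--1.15 in the
  default four-class specification (invasive-tumor range), fluid-like
  background at 2.2. These class parameters are illustrative stand-ins
  for subtype-specific diffusivity heterogeneity, not values calibrated
  to patient data; recovery experiments are therefore parameterized by
  effect size (correlation-length ratio), not by subtype identity.
* **Two segmentation variants**: the exact lesion mask plays the role of a
  delineation drawn directly on the ADC map; an 8-neighbor dilation of
  width 2 (configurable) plays the role of a delineation propagated from
  the high b-value image, and the band between them receives intermediate
  "peritumoral" intensities with their own texture, common across
  classes. Because the rim statistics are class-independent, dilated
  masks dilute class contrast --- which is exactly the qualitative
  mechanism behind the expectation that exact masks classify at least as
  well as dilated ones on average, asserted as a replicate-mean
  inequality (never as specific percentages).
* The default class-size vector for a four-class cohort is 49/8/11/23
  (total 91), preserving the strong imbalance that makes small-class
  behavior (a class of 8 with 10 selected features) a first-class test
  case.

What the generator does *not* emulate: breast anatomy, coil/bias fields,
EPI distortion, perfusion effects, multi-slice structure, or
reader-dependent delineation. Passing tests on synthetic cohorts show the
pipeline's statistical machinery behaves correctly under known ground
truth; they do not certify classification accuracy on clinical data.

## Problem sizes and numerical choices

Replicate-heavy experiments (null calibration, effect recovery,
mask-variant comparison) use 32 x 32 images, lesion radii 5--8 px, 25
lesions per class and a reduced feature configuration (co-occurrence
distances 1--2, two Haar scales, about 140 features) --- large enough that
every family contributes and selection has a realistic candidate pool,
small enough that a hundred replicate cohorts run in minutes. The
single-cohort demonstrations use the full configuration (distances 1--5,
276 features) at 48 x 48. Other fixed numerics: natural logarithms
throughout; $0 \log 0 := 0$; LDA shrinkage $\lambda = 10^{-3}$; SVD
singular-value cutoff $10^{-10}$ relative; signal floor $10^{-4} S_0$
before the ADC logarithm; minimum analyzable ROI 16 pixels (the smallest
region supporting a two-level co-occurrence matrix and one Haar scale);
default pixel spacing 1.4 mm when a format carries none.

## Known limitations

Single-slice 2-D analysis only; binary tasks only (pairwise and
one-vs-rest; no simultaneous multiclass); no ROC/AUC (accuracy is the
outcome, as in the protocol this mirrors); the feature catalogue follows
the MaZda-style conventions documented here rather than IBSI definitions;
and paper-mode results must be read as optimistic by construction ---
nested mode exists precisely so the two can be compared on equal terms.
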