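test_that("histogram features match direct moment computation", {
  q <- quantized_from_levels(matrix(c(1L, 1L, 2L, 2L, rep(1L, 12)), 4, 4))
  # constant sub-case
  qc <- quantized_from_levels(matrix(3L, 4, 4), 4)
  f <- his_features(qc)
  expect_equal(unname(f["his_mean"]), 3)
  expect_equal(unname(f["his_variance"]), 0)
  expect_true(is.na(f["his_skewness"]) && is.na(f["his_kurtosis"]))
  # {1,1,2,2}
  q2 <- quantized_from_levels(matrix(c(1L, 1L, 2L, 2L), 2, 2), 2)
  f2 <- his_features(q2)
  expect_equal(unname(f2["his_mean"]), 1.5)
  expect_equal(unname(f2["his_variance"]), 0.25)
  expect_equal(unname(f2["his_skewness"]), 0)
})

test_that("GLCM of [[1,1],[2,2]] at d=1, 0 deg has the closed-form entries", {
  q <- quantized_from_levels(matrix(c(1L, 2L, 1L, 2L), 2, 2), 2)
  P <- glcm(q, 1, 0)
  expect_equal(P, matrix(c(0.5, 0, 0, 0.5), 2, 2))
  f <- glcm_features(P)
  expect_equal(unname(f["glcm_asm"]), 0.5)
  expect_equal(unname(f["glcm_contrast"]), 0)
  expect_equal(unname(f["glcm_entropy"]), log(2))
})

test_that("a single-entry GLCM has ASM 1 and zero entropy/contrast", {
  q <- quantized_from_levels(matrix(2L, 3, 3), 4)
  f <- glcm_features(glcm(q, 1, 45))
  expect_equal(unname(f["glcm_asm"]), 1)
  expect_equal(unname(f["glcm_entropy"]), 0)
  expect_equal(unname(f["glcm_contrast"]), 0)
  expect_true(is.na(f["glcm_correlation"]))  # zero-variance marginal
})

test_that("every GLCM is symmetric, normalized and missing when no pair exists", {
  set.seed(5)
  for (rep in 1:15) {
    cs <- random_roi_case()
    for (a in c(0, 45, 90, 135)) {
      P <- glcm(cs$q, sample(1:2, 1), a)
      if (is.null(P)) next
      expect_equal(sum(P), 1, tolerance = 1e-12)
      expect_equal(P, t(P), tolerance = 1e-12)
      f <- glcm_features(P)
      expect_gt(f["glcm_asm"], 0)
      expect_gte(f["glcm_entropy"], 0)
    }
  }
  # a one-column ROI has no horizontal pair at d = 1
  thin <- quantized_from_levels(matrix(1L, 6, 1), 2)
  expect_null(glcm(thin, 1, 0))
  expect_true(all(is.na(glcm_features(NULL))))
})

test_that("constant-ROI run lengths: one full-width run per row at 0 deg", {
  q <- quantized_from_levels(matrix(2L, 4, 4), 4)
  R <- rlm(q, 0)
  expect_equal(sum(R), 4)
  expect_equal(R[2, 4], 4)
  f <- rlm_features(R)
  expect_equal(unname(f["rlm_sre"]), 1 / 16)
  expect_equal(unname(f["rlm_lre"]), 16)
  expect_equal(unname(f["rlm_fraction"]), 0.25)
})

test_that("checkerboard runs all have length 1 and total the pixel count", {
  lv <- 1L + (outer(1:6, 1:6, "+") %% 2L)
  q <- quantized_from_levels(lv, 2)
  for (a in c(0, 90)) {
    R <- rlm(q, a)
    expect_equal(ncol(R), 1)
    expect_equal(sum(R), 36)
    f <- rlm_features(R)
    expect_equal(unname(f["rlm_sre"]), 1)
    expect_equal(unname(f["rlm_lre"]), 1)
    expect_equal(unname(f["rlm_fraction"]), 1)
  }
})

test_that("run-length pixel conservation holds in every direction (property)", {
  set.seed(6)
  for (rep in 1:15) {
    cs <- random_roi_case()
    for (a in c(0, 45, 90, 135)) {
      R <- rlm(cs$q, a)
      expect_equal(sum(R * col(R)), sum(cs$mask))  # sum_g sum_r r R(g,r)
    }
  }
})

test_that("L-shaped masks split runs at the mask boundary like the brute-force enumeration", {
  m <- matrix(FALSE, 6, 6)
  m[1:6, 1:3] <- TRUE; m[5:6, 4:6] <- TRUE
  lv <- matrix(NA_integer_, 6, 6); lv[m] <- 1L
  q <- quantized_from_levels(lv, 2)
  for (a in c(0, 45, 90, 135))
    expect_equal(unname(rlm(q, a)),
                 unname(oracle_rlm(lv, a, 2)[, seq_len(ncol(rlm(q, a))),
                                             drop = FALSE]),
                 ignore_attr = TRUE)
})

test_that("gradient features: constant and linear-ramp closed forms", {
  mk <- roi_mask(matrix(TRUE, 6, 6))
  cst <- annotated_image(matrix(5, 6, 6), modality = "ADC")
  f <- gradient_features(cst, mk)
  expect_equal(unname(f["grad_mean"]), 0)
  expect_equal(unname(f["grad_nonzero_fraction"]), 0)
  ramp <- annotated_image(matrix(rep(1:6, each = 6), 6, 6), modality = "ADC")
  f2 <- gradient_features(ramp, mk)
  expect_equal(unname(f2["grad_mean"]), 1)
  expect_equal(unname(f2["grad_variance"]), 0)
  expect_equal(unname(f2["grad_nonzero_fraction"]), 1)
})

test_that("the AR fit recovers known causal parameters and handles degeneracy", {
  # constant ROI: minimum-norm solution is theta = 0, zero residual
  qc <- quantized_from_levels(matrix(1L, 8, 8), 4)
  f <- arm_fit(qc)
  expect_equal(unname(f[1:4]), rep(0, 4))
  expect_equal(unname(f["arm_sigma"]), 0)
  # parameter recovery on a simulated causal field
  set.seed(314)
  x <- matrix(rnorm(64 * 64), 64, 64)
  for (i in 2:64) for (j in 2:63)
    x[i, j] <- 0.4 * x[i, j - 1] + 0.4 * x[i - 1, j] + rnorm(1, sd = 0.3)
  img <- annotated_image(x, modality = "ADC")
  mk <- roi_mask(matrix(TRUE, 64, 64))
  q <- normalize_roi(img, mk, 64)
  f2 <- arm_fit(q)
  expect_lt(abs(f2["arm_theta1"] - 0.4), 0.1)
  expect_lt(abs(f2["arm_theta2"] - 0.4), 0.1)
  # white noise: coefficients near zero
  set.seed(315)
  qw <- normalize_roi(annotated_image(matrix(rnorm(900), 30, 30),
                                      modality = "ADC"),
                      roi_mask(matrix(TRUE, 30, 30)), 64)
  fw <- arm_fit(qw)
  expect_true(all(abs(fw[1:4]) < 3 / sqrt(28 * 28)))
  # too few usable pixels -> missing family
  tiny <- quantized_from_levels(matrix(1L, 4, 4), 2)
  expect_true(all(is.na(arm_fit(tiny, min_pixels = 20))))
})

test_that("Haar subbands: constant image, 2x2 vertical step, Parseval identity", {
  mk <- roi_mask(matrix(TRUE, 8, 8))
  cst <- annotated_image(matrix(4, 8, 8), modality = "ADC")
  f <- haar_features(cst, mk, 3)
  details <- f[grep("_(hl|lh|hh)$", names(f))]
  expect_equal(unname(details), rep(0, length(details)))

  # [[a,a],[b,b]] rows: HL (vertical difference) = a - b, LH = HH = 0
  m2 <- matrix(FALSE, 6, 6); m2[3:4, 3:4] <- TRUE
  step <- matrix(1, 6, 6); step[4, ] <- 5
  f2 <- haar_features(annotated_image(step, modality = "ADC"),
                      roi_mask(m2, check = FALSE), 1)
  expect_equal(unname(f2["wav_s1_hl"]), (1 - 5)^2)
  expect_equal(unname(f2["wav_s1_lh"]), 0)
  expect_equal(unname(f2["wav_s1_hh"]), 0)

  # Parseval on a full dyadic box: detail energies x counts sum to the
  # energy of the mean-removed image
  set.seed(12)
  n <- 16
  px <- matrix(rnorm(n * n), n, n)
  px <- px - mean(px)
  fh <- haar_features(annotated_image(px, modality = "ADC"),
                      roi_mask(matrix(TRUE, n, n)), 4)
  tot <- 0
  for (s in 1:4) {
    cnt <- (n / 2^s)^2
    tot <- tot + cnt * sum(fh[sprintf("wav_s%d_%s", s, c("hl", "lh", "hh"))])
  }
  tot <- tot + fh["wav_s4_ll"]  # final 1x1 approximation coefficient
  expect_equal(unname(tot), sum(px^2), tolerance = 1e-9)
})

test_that("geometry: solid square closed forms and 90-degree rotation invariance", {
  m <- matrix(FALSE, 12, 12); m[2:11, 2:11] <- TRUE
  f <- geometry_features(roi_mask(m), spacing = c(1, 1))
  expect_equal(unname(f["geo_area_mm2"]), 100)
  expect_equal(unname(f["geo_feret_mm"]), 9 * sqrt(2))
  expect_equal(unname(f["geo_perimeter_mm"]), 36)
  expect_equal(unname(f["geo_elongation"]), 1)

  set.seed(8)
  mk <- make_lesion_mask(c(4, 6), 20)
  f1 <- geometry_features(mk)
  rot <- roi_mask(t(mk$mask)[ncol(mk$mask):1, ], check = FALSE)
  f2 <- geometry_features(rot)
  expect_equal(f1, f2, tolerance = 1e-9)

  # isoperimetric direction: circularity no better than the equal-area disk
  disk <- make_lesion_mask(c(6, 6), 20, max_amplitude = 0)
  fd <- geometry_features(disk)
  expect_lte(f1[["geo_circularity"]], fd[["geo_circularity"]] + 1e-9)
})

test_that("extract_all returns the documented catalogue, deterministically", {
  set.seed(21)
  co <- two_class_cohort(seed = 21, n = 2, radius = c(6, 9), image_size = 32)
  les <- co$lesions[[1]]
  cfg <- radiomics_config()
  v1 <- extract_all(les$adc, les$mask, cfg)
  v2 <- extract_all(les$adc, les$mask, cfg)
  expect_identical(v1, v2)
  expect_identical(names(v1), feature_catalogue(cfg))
  expect_length(v1, 9 + 5 * 4 * 11 + 4 * 5 + 5 + 5 + 3 * 4 + 5)
  expect_false(any(is.infinite(v1)))
})

test_that("feature maps agree with window-level recomputation and see planted contrast", {
  # constant image: entropy-type map is 0 inside the mask
  img <- annotated_image(matrix(3, 10, 10), modality = "ADC")
  mk <- roi_mask(matrix(TRUE, 10, 10))
  mp <- feature_map(img, mk, "com_d1_a000_entropy", window = 3,
                    config = radiomics_config(glcm_distances = 1))
  expect_equal(unname(mp[mk$mask]), rep(0, 100))

  # two-texture composite: left/right map means differ
  set.seed(33)
  px <- cbind(matrix(rnorm(100, 0, 0.05), 10, 10),
              matrix(sample(c(0, 10), 100, TRUE), 10, 10))
  img2 <- annotated_image(px, modality = "ADC")
  mk2 <- roi_mask(matrix(TRUE, 10, 20))
  mp2 <- feature_map(img2, mk2, "his_variance", window = 5)
  expect_gt(mean(mp2[, 11:20]), mean(mp2[, 1:10]))

  # definitional consistency at one pixel
  i <- 5; j <- 5
  sub <- matrix(FALSE, 10, 20); sub[3:7, 3:7] <- TRUE
  ref <- his_features(normalize_roi(img2, roi_mask(sub, check = FALSE), 64))
  expect_equal(mp2[i, j], unname(ref["his_variance"]))

  expect_error(feature_map(img2, mk2, "not_a_feature"), "unknown feature")
})
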