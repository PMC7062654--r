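# Pixel offset for a direction in degrees, image rows increasing downward:
# 0 deg = east, 45 deg = north-east, 90 deg = north, 135 deg = north-west.
direction_offset <- function(angle, d = 1L) {
  d <- as.integer(d)
  switch(as.character(angle),
         "0"   = c(0L, d),
         "45"  = c(-d, d),
         "90"  = c(-d, 0L),
         "135" = c(-d, -d),
         stop("direction must be one of 0, 45, 90, 135", call. = FALSE))
}

#' Gray-level co-occurrence matrix (COM)
#'
#' Counts ordered level pairs at pixel offset `d` along `angle`, restricted
#' to pairs with both pixels inside the mask, accumulated in both opposite
#' offsets (symmetrization) and normalized to sum to 1.
#'
#' @param q a [normalize_roi()] result.
#' @param d pixel distance (>= 1).
#' @param angle direction in degrees: 0, 45, 90 or 135.
#' @return Ng x Ng normalized symmetric matrix, or `NULL` when the ROI has
#'   no valid pixel pair at this offset (missing-feature signal).
#' @export
glcm <- function(q, d = 1L, angle = 0) {
  ng <- q$n_levels
  off <- direction_offset(angle, d)
  pr <- shifted_pairs(q$levels, off)
  if (is.null(pr)) return(NULL)
  code <- (pr$a - 1L) * ng + pr$b
  code_t <- (pr$b - 1L) * ng + pr$a
  tab <- tabulate(c(code, code_t), nbins = ng * ng)
  P <- matrix(tab / sum(tab), ng, ng, byrow = TRUE)
  P
}

# All in-bounds, in-mask ordered pairs (a at (i,j), b at (i+dr, j+dc)).
shifted_pairs <- function(levels, off) {
  nr <- nrow(levels); nc <- ncol(levels)
  dr <- off[1]; dc <- off[2]
  rlo <- max(1L, 1L - dr); rhi <- min(nr, nr - dr)
  clo <- max(1L, 1L - dc); chi <- min(nc, nc - dc)
  if (rlo > rhi || clo > chi) return(NULL)
  ri <- rlo:rhi
  ci <- clo:chi
  a <- levels[ri, ci, drop = FALSE]
  b <- levels[ri + dr, ci + dc, drop = FALSE]
  ok <- !is.na(a) & !is.na(b)
  if (!any(ok)) return(NULL)
  list(a = a[ok], b = b[ok])
}

#' Haralick features of a normalized GLCM
#'
#' Eleven classical descriptors: angular second moment, contrast,
#' correlation, sum of squares (variance), inverse difference moment, sum
#' average, sum variance, sum entropy, entropy, difference variance and
#' difference entropy. All entropies use the natural logarithm with the
#' convention 0 log 0 = 0. Sum variance is taken about the sum average;
#' variance (sum of squares) is taken about the marginal mean. Correlation
#' of a zero-variance marginal is missing.
#'
#' @param P normalized symmetric co-occurrence matrix (entries sum to 1), or
#'   `NULL` (propagates a full-NA vector).
#' @param prefix name prefix for the returned vector.
#' @return Named numeric vector of the 11 features.
#' @export
glcm_features <- function(P, prefix = "glcm") {
  feats <- c("asm", "contrast", "correlation", "sum_of_squares", "idm",
             "sum_average", "sum_variance", "sum_entropy", "entropy",
             "difference_variance", "difference_entropy")
  out <- rep(NA_real_, length(feats))
  names(out) <- paste0(prefix, "_", feats)
  if (is.null(P)) return(out)
  if (abs(sum(P) - 1) > 1e-8)
    stop("GLCM is not normalized (entries must sum to 1)", call. = FALSE)
  ng <- nrow(P)
  i <- row(P); j <- col(P)
  p <- as.vector(P)
  xlogx <- function(x) ifelse(x > 0, x * log(x), 0)

  px <- rowSums(P)                      # == colSums by symmetry
  mu_x <- sum(seq_len(ng) * px)
  var_x <- sum((seq_len(ng) - mu_x)^2 * px)

  asm <- sum(p^2)
  contrast <- sum((i - j)^2 * p)
  correlation <- if (var_x > 0)
    (sum(i * j * p) - mu_x^2) / var_x else NA_real_
  sum_of_squares <- sum((i - mu_x)^2 * p)
  idm <- sum(p / (1 + (i - j)^2))

  # p_{x+y}(k), k = 2..2Ng and p_{x-y}(k), k = 0..Ng-1
  psum <- as.vector(rowsum(p, as.vector(i + j)))          # ordered k = 2..2Ng
  ks <- 2:(2 * ng)
  pdif <- as.vector(rowsum(p, as.vector(abs(i - j))))     # ordered k = 0..Ng-1
  kd <- 0:(ng - 1)

  sum_average <- sum(ks * psum)
  sum_variance <- sum((ks - sum_average)^2 * psum)
  sum_entropy <- -sum(xlogx(psum))
  entropy <- -sum(xlogx(p))
  dif_average <- sum(kd * pdif)
  difference_variance <- sum((kd - dif_average)^2 * pdif)
  difference_entropy <- -sum(xlogx(pdif))

  out[] <- c(asm, contrast, correlation, sum_of_squares, idm, sum_average,
             sum_variance, sum_entropy, entropy, difference_variance,
             difference_entropy)
  out
}

# The full COM block: every (distance, angle) combination of the config.
com_block <- function(q, distances, angles) {
  blocks <- lapply(distances, function(d) {
    inner <- lapply(angles, function(a) {
      glcm_features(glcm(q, d = d, angle = a),
                    prefix = sprintf("com_d%d_a%03d", d, a))
    })
    do.call(c, inner)
  })
  do.call(c, blocks)
}
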