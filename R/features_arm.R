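#' Causal autoregressive model (ARM) features
#'
#' Least-squares fit of the causal prediction
#' `x(i,j) = t1 x(i,j-1) + t2 x(i-1,j) + t3 x(i-1,j-1) + t4 x(i-1,j+1) + e`
#' on mean-centered quantized levels, using every pixel whose four causal
#' neighbors all lie inside the mask. Mean-centering removes the intercept.
#' Rank-deficient normal equations are solved by the minimum-norm
#' least-squares solution (SVD pseudo-inverse), so a constant ROI yields
#' theta = 0 and zero residual. Returns the four coefficients and the
#' residual standard deviation.
#'
#' @param q a [normalize_roi()] result.
#' @param min_pixels minimum number of usable pixels (default 20); with
#'   fewer the family is missing.
#' @return Named numeric vector `arm_theta1..4`, `arm_sigma`.
#' @export
arm_fit <- function(q, min_pixels = 20L) {
  out <- rep(NA_real_, 5)
  names(out) <- c(paste0("arm_theta", 1:4), "arm_sigma")
  L <- q$levels
  nr <- nrow(L); nc <- ncol(L)
  if (nr < 2L || nc < 3L) return(out)
  mu <- mean(L[q$mask])
  Z <- L - mu
  ri <- 2:nr; cj <- 2:(nc - 1)
  y  <- Z[ri, cj, drop = FALSE]
  x1 <- Z[ri, cj - 1, drop = FALSE]       # (i, j-1)
  x2 <- Z[ri - 1, cj, drop = FALSE]       # (i-1, j)
  x3 <- Z[ri - 1, cj - 1, drop = FALSE]   # (i-1, j-1)
  x4 <- Z[ri - 1, cj + 1, drop = FALSE]   # (i-1, j+1)
  ok <- !is.na(y) & !is.na(x1) & !is.na(x2) & !is.na(x3) & !is.na(x4)
  n <- sum(ok)
  if (n < min_pixels) return(out)
  X <- cbind(x1[ok], x2[ok], x3[ok], x4[ok])
  yv <- y[ok]
  theta <- lstsq_minnorm(X, yv)
  resid <- yv - X %*% theta
  out[1:4] <- theta
  out[5] <- sqrt(mean(resid^2))
  out
}

# Minimum-norm least squares via SVD with a relative singular-value cutoff.
lstsq_minnorm <- function(X, y, rtol = 1e-10) {
  s <- svd(X)
  keep <- s$d > rtol * max(s$d, 0)
  if (!any(keep)) return(rep(0, ncol(X)))
  dinv <- ifelse(keep, 1 / s$d, 0)
  as.vector(s$v %*% (dinv * crossprod(s$u, y)))
}
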