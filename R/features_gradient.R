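#' Absolute gradient features
#'
#' Central-difference gradient magnitude
#' `g(i,j) = sqrt((x(i+1,j) - x(i-1,j))^2 + (x(i,j+1) - x(i,j-1))^2) / 2`
#' evaluated on the raw (unquantized) intensities at every mask pixel whose
#' full 4-neighborhood lies inside the mask. Returns the population mean,
#' variance, skewness and excess kurtosis of g plus the fraction of
#' evaluated pixels with nonzero gradient. With no interior pixel the whole
#' family is missing.
#'
#' @param image an [annotated_image()].
#' @param mask a [roi_mask()].
#' @return Named numeric vector `grad_*`.
#' @export
gradient_features <- function(image, mask) {
  feats <- c("mean", "variance", "skewness", "kurtosis", "nonzero_fraction")
  out <- rep(NA_real_, 5)
  names(out) <- paste0("grad_", feats)
  check_congruent(image, mask)
  x <- image$pixels
  m <- mask$mask
  nr <- nrow(x); nc <- ncol(x)
  if (nr < 3L || nc < 3L) return(out)
  core_i <- 2:(nr - 1); core_j <- 2:(nc - 1)
  interior <- m[core_i, core_j, drop = FALSE] &
    m[core_i - 1, core_j, drop = FALSE] & m[core_i + 1, core_j, drop = FALSE] &
    m[core_i, core_j - 1, drop = FALSE] & m[core_i, core_j + 1, drop = FALSE]
  if (!any(interior)) return(out)
  gi <- (x[core_i + 1, core_j, drop = FALSE] -
           x[core_i - 1, core_j, drop = FALSE]) / 2
  gj <- (x[core_i, core_j + 1, drop = FALSE] -
           x[core_i, core_j - 1, drop = FALSE]) / 2
  g <- sqrt(gi^2 + gj^2)[interior]
  mom <- pop_moments(g)
  out[1:4] <- mom
  out[5] <- mean(g > 0)
  out
}
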