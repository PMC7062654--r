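# Population moments shared by the histogram and gradient families.
# Skewness m3/sd^3 and excess kurtosis m4/sd^4 - 3 are undefined (NA) when
# the variance is zero.
pop_moments <- function(v) {
  m <- mean(v)
  d <- v - m
  va <- mean(d^2)
  if (va == 0) {
    c(mean = m, variance = 0, skewness = NA_real_, kurtosis = NA_real_)
  } else {
    c(mean = m, variance = va,
      skewness = mean(d^3) / va^1.5,
      kurtosis = mean(d^4) / va^2 - 3)
  }
}

# Nearest-rank percentile: smallest value with at least p% of the sample at
# or below it.
nearest_rank_percentile <- function(sorted, p) {
  n <- length(sorted)
  sorted[max(1L, ceiling(p / 100 * n))]
}

#' First-order histogram (HIS) features
#'
#' Moments and percentiles of the quantized gray-level distribution inside
#' the ROI, ignoring spatial arrangement: mean, variance (population),
#' skewness, excess kurtosis, and the nearest-rank percentiles 1, 10, 50,
#' 90, 99. Skewness and kurtosis of a zero-variance ROI are missing.
#'
#' @param q a [normalize_roi()] result.
#' @return Named numeric vector `his_*`.
#' @export
his_features <- function(q) {
  v <- as.numeric(q$levels[q$mask])
  mom <- pop_moments(v)
  s <- sort(v)
  out <- c(mom["mean"], mom["variance"], mom["skewness"], mom["kurtosis"],
           nearest_rank_percentile(s, 1), nearest_rank_percentile(s, 10),
           nearest_rank_percentile(s, 50), nearest_rank_percentile(s, 90),
           nearest_rank_percentile(s, 99))
  names(out) <- paste0("his_", c("mean", "variance", "skewness", "kurtosis",
                                 "perc01", "perc10", "perc50", "perc90",
                                 "perc99"))
  out
}
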