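#' Run-length matrix (RLM)
#'
#' Counts maximal collinear runs of equal quantized level along one of the
#' four principal directions. A run ends at a mask boundary or at a level
#' change; runs are counted along every maximal in-mask line segment of the
#' direction.
#'
#' @param q a [normalize_roi()] result.
#' @param angle direction in degrees: 0 (rows), 45 (anti-diagonals), 90
#'   (columns), 135 (diagonals).
#' @return Integer matrix with `Ng` rows and `max run length` columns;
#'   entry (g, r) is the number of runs of level g with length exactly r.
#'   Carries attribute `n_pixels` (mask pixel count).
#' @export
rlm <- function(q, angle = 0) {
  L <- q$levels
  ng <- q$n_levels
  nr <- nrow(L); nc <- ncol(L)
  R <- row(L); C <- col(L)
  group <- switch(as.character(angle),
                  "0"   = R,
                  "90"  = C,
                  "45"  = R + C,
                  "135" = R - C,
                  stop("direction must be one of 0, 45, 90, 135",
                       call. = FALSE))
  ord <- order(group, C, R)  # within a line, advance along columns
  lines <- split(as.vector(L)[ord], as.vector(group)[ord])
  maxlen <- 1L
  mat <- matrix(0L, ng, max(nr, nc) + min(nr, nc))
  for (ln in lines) {
    x <- ln
    x[is.na(x)] <- 0L
    r <- rle(x)
    keep <- r$values > 0L
    if (!any(keep)) next
    lens <- r$lengths[keep]
    vals <- r$values[keep]
    for (t in seq_along(lens))
      mat[vals[t], lens[t]] <- mat[vals[t], lens[t]] + 1L
    maxlen <- max(maxlen, max(lens))
  }
  mat <- mat[, seq_len(maxlen), drop = FALSE]
  attr(mat, "n_pixels") <- sum(q$mask)
  mat
}

#' Run-length features (Galloway set)
#'
#' Short-run emphasis, long-run emphasis, gray-level nonuniformity,
#' run-length nonuniformity, and the fraction of the ROI in runs
#' (total number of runs / number of pixels).
#'
#' @param R run-length matrix from [rlm()].
#' @param n_pixels number of ROI pixels (defaults to the matrix attribute).
#' @param prefix name prefix.
#' @return Named numeric vector of the 5 features.
#' @export
rlm_features <- function(R, n_pixels = attr(R, "n_pixels"), prefix = "rlm") {
  feats <- c("sre", "lre", "gln", "rln", "fraction")
  out <- rep(NA_real_, length(feats))
  names(out) <- paste0(prefix, "_", feats)
  total <- sum(R)
  if (is.null(n_pixels) || total == 0) return(out)
  r <- col(R)
  out[1] <- sum(R / r^2) / total
  out[2] <- sum(R * r^2) / total
  out[3] <- sum(rowSums(R)^2) / total
  out[4] <- sum(colSums(R)^2) / total
  out[5] <- total / n_pixels
  out
}

rlm_block <- function(q, angles) {
  do.call(c, lapply(angles, function(a) {
    rlm_features(rlm(q, angle = a), prefix = sprintf("rlm_a%03d", a))
  }))
}
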