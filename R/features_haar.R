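#' Haar wavelet subband energies (WAV)
#'
#' Non-standard (Mallat) separable Haar transform on the mask's bounding
#' box, computed on raw intensities with outside-mask pixels filled by the
#' ROI mean. At every scale `s = 1..max_scale` the four subband energies
#' `E_LL, E_HL, E_LH, E_HH` are returned, each the mean of the squared
#' orthonormal coefficients whose `2^s x 2^s` spatial support lies entirely
#' inside the mask; a subband with no fully supported coefficient is
#' missing.
#'
#' Orientation convention (documented, fixed): `HL` is the
#' vertical-difference subband (high-pass along image rows), `LH` the
#' horizontal-difference subband (high-pass along columns), `HH` the
#' diagonal subband. For a 2 x 2 block with rows `(a, a)` and `(b, b)` the
#' single scale-1 detail is `HL = a - b` and `LH = HH = 0`.
#'
#' @param image an [annotated_image()].
#' @param mask a [roi_mask()].
#' @param max_scale largest scale reported (default 3).
#' @return Named numeric vector `wav_s{s}_{ll,hl,lh,hh}`.
#' @export
haar_features <- function(image, mask, max_scale = 3L) {
  max_scale <- as.integer(max_scale)
  bands <- c("ll", "hl", "lh", "hh")
  out <- rep(NA_real_, 4L * max_scale)
  names(out) <- as.vector(t(outer(seq_len(max_scale), bands,
                                  function(s, b) sprintf("wav_s%d_%s", s, b))))
  check_congruent(image, mask)
  m <- mask$mask
  rr <- range(which(rowSums(m) > 0))
  cc <- range(which(colSums(m) > 0))
  cur <- image$pixels[rr[1]:rr[2], cc[1]:cc[2], drop = FALSE]
  curm <- m[rr[1]:rr[2], cc[1]:cc[2], drop = FALSE]
  fill <- mean(image$pixels[m])
  cur[!curm] <- fill
  for (s in seq_len(max_scale)) {
    if (nrow(cur) < 2L || ncol(cur) < 2L) break
    # pad to even dimensions; padded pixels are outside the mask
    if (nrow(cur) %% 2L == 1L) {
      cur <- rbind(cur, fill)
      curm <- rbind(curm, FALSE)
    }
    if (ncol(cur) %% 2L == 1L) {
      cur <- cbind(cur, fill)
      curm <- cbind(curm, FALSE)
    }
    oi <- seq(1L, nrow(cur), by = 2L); ei <- oi + 1L
    oj <- seq(1L, ncol(cur), by = 2L); ej <- oj + 1L
    x11 <- cur[oi, oj, drop = FALSE]; x12 <- cur[oi, ej, drop = FALSE]
    x21 <- cur[ei, oj, drop = FALSE]; x22 <- cur[ei, ej, drop = FALSE]
    ll <- (x11 + x12 + x21 + x22) / 2
    hl <- (x11 + x12 - x21 - x22) / 2
    lh <- (x11 - x12 + x21 - x22) / 2
    hh <- (x11 - x12 - x21 + x22) / 2
    sup <- curm[oi, oj, drop = FALSE] & curm[oi, ej, drop = FALSE] &
      curm[ei, oj, drop = FALSE] & curm[ei, ej, drop = FALSE]
    if (any(sup)) {
      out[sprintf("wav_s%d_ll", s)] <- mean(ll[sup]^2)
      out[sprintf("wav_s%d_hl", s)] <- mean(hl[sup]^2)
      out[sprintf("wav_s%d_lh", s)] <- mean(lh[sup]^2)
      out[sprintf("wav_s%d_hh", s)] <- mean(hh[sup]^2)
    }
    cur <- ll
    curm <- sup
  }
  out
}
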