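# Independent literal-formula brute-force implementations of every texture
# family, written as naive loops directly from the definitions. These act
# as oracles for the vectorized package implementations and must stay
# independent of the code paths they check.

oracle_his <- function(levels_vec) {
  v <- as.numeric(levels_vec)
  n <- length(v)
  m <- sum(v) / n
  m2 <- sum((v - m)^2) / n
  m3 <- sum((v - m)^3) / n
  m4 <- sum((v - m)^4) / n
  sk <- if (m2 == 0) NA_real_ else m3 / m2^1.5
  ku <- if (m2 == 0) NA_real_ else m4 / m2^2 - 3
  s <- sort(v)
  pct <- function(p) s[max(1, ceiling(p / 100 * n))]
  c(his_mean = m, his_variance = m2, his_skewness = sk, his_kurtosis = ku,
    his_perc01 = pct(1), his_perc10 = pct(10), his_perc50 = pct(50),
    his_perc90 = pct(90), his_perc99 = pct(99))
}

oracle_offset <- function(angle, d) {
  switch(as.character(angle),
         "0" = c(0, d), "45" = c(-d, d), "90" = c(-d, 0), "135" = c(-d, -d))
}

oracle_glcm <- function(levels, d, angle, ng) {
  off <- oracle_offset(angle, d)
  nr <- nrow(levels); nc <- ncol(levels)
  counts <- matrix(0, ng, ng)
  npairs <- 0
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    ii <- i + off[1]; jj <- j + off[2]
    if (ii < 1 || ii > nr || jj < 1 || jj > nc) next
    a <- levels[i, j]; b <- levels[ii, jj]
    if (is.na(a) || is.na(b)) next
    counts[a, b] <- counts[a, b] + 1
    counts[b, a] <- counts[b, a] + 1
    npairs <- npairs + 2
  }
  if (npairs == 0) return(NULL)
  counts / npairs
}

oracle_glcm_features <- function(P) {
  ng <- nrow(P)
  lg <- function(x) if (x > 0) log(x) else 0
  asm <- 0; contrast <- 0; idm <- 0; ent <- 0; cor_num <- 0; ssq <- 0
  px <- rowSums(P)
  mu <- 0; for (i in 1:ng) mu <- mu + i * px[i]
  varx <- 0; for (i in 1:ng) varx <- varx + (i - mu)^2 * px[i]
  for (i in 1:ng) for (j in 1:ng) {
    p <- P[i, j]
    asm <- asm + p^2
    contrast <- contrast + (i - j)^2 * p
    idm <- idm + p / (1 + (i - j)^2)
    ent <- ent - p * lg(p)
    cor_num <- cor_num + i * j * p
    ssq <- ssq + (i - mu)^2 * p
  }
  correlation <- if (varx > 0) (cor_num - mu^2) / varx else NA_real_
  psum <- numeric(2 * ng); pdif <- numeric(ng)
  for (i in 1:ng) for (j in 1:ng) {
    psum[i + j] <- psum[i + j] + P[i, j]
    pdif[abs(i - j) + 1] <- pdif[abs(i - j) + 1] + P[i, j]
  }
  sa <- 0; for (k in 2:(2 * ng)) sa <- sa + k * psum[k]
  sv <- 0; for (k in 2:(2 * ng)) sv <- sv + (k - sa)^2 * psum[k]
  se <- 0; for (k in 2:(2 * ng)) se <- se - psum[k] * lg(psum[k])
  da <- 0; for (k in 0:(ng - 1)) da <- da + k * pdif[k + 1]
  dv <- 0; for (k in 0:(ng - 1)) dv <- dv + (k - da)^2 * pdif[k + 1]
  de <- 0; for (k in 0:(ng - 1)) de <- de - pdif[k + 1] * lg(pdif[k + 1])
  c(asm = asm, contrast = contrast, correlation = correlation,
    sum_of_squares = ssq, idm = idm, sum_average = sa, sum_variance = sv,
    sum_entropy = se, entropy = ent, difference_variance = dv,
    difference_entropy = de)
}

# Runs enumerated literally: a pixel starts a run if its predecessor along
# the direction is absent or has a different level; the run is walked
# forward to its end.
oracle_rlm <- function(levels, angle, ng) {
  step <- oracle_offset(angle, 1)
  nr <- nrow(levels); nc <- ncol(levels)
  get <- function(i, j) {
    if (i < 1 || i > nr || j < 1 || j > nc) NA else levels[i, j]
  }
  runs <- list()
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    v <- levels[i, j]
    if (is.na(v)) next
    prev <- get(i - step[1], j - step[2])
    if (!is.na(prev) && prev == v) next  # not a run start
    len <- 1
    ii <- i + step[1]; jj <- j + step[2]
    while (!is.na(get(ii, jj)) && get(ii, jj) == v) {
      len <- len + 1
      ii <- ii + step[1]; jj <- jj + step[2]
    }
    runs[[length(runs) + 1]] <- c(v, len)
  }
  maxlen <- max(1, vapply(runs, `[`, numeric(1), 2))
  R <- matrix(0, ng, maxlen)
  for (r in runs) R[r[1], r[2]] <- R[r[1], r[2]] + 1
  R
}

oracle_rlm_features <- function(R, n_pixels) {
  total <- sum(R)
  sre <- 0; lre <- 0
  for (g in seq_len(nrow(R))) for (r in seq_len(ncol(R))) {
    sre <- sre + R[g, r] / r^2
    lre <- lre + R[g, r] * r^2
  }
  gln <- 0
  for (g in seq_len(nrow(R))) gln <- gln + sum(R[g, ])^2
  rln <- 0
  for (r in seq_len(ncol(R))) rln <- rln + sum(R[, r])^2
  c(sre = sre / total, lre = lre / total, gln = gln / total,
    rln = rln / total, fraction = total / n_pixels)
}

oracle_gradient <- function(pixels, mask) {
  nr <- nrow(pixels); nc <- ncol(pixels)
  g <- c()
  for (i in 2:(nr - 1)) for (j in 2:(nc - 1)) {
    if (mask[i, j] && mask[i - 1, j] && mask[i + 1, j] &&
        mask[i, j - 1] && mask[i, j + 1]) {
      gi <- pixels[i + 1, j] - pixels[i - 1, j]
      gj <- pixels[i, j + 1] - pixels[i, j - 1]
      g <- c(g, sqrt(gi^2 + gj^2) / 2)
    }
  }
  if (length(g) == 0) return(rep(NA_real_, 5))
  n <- length(g)
  m <- mean(g); m2 <- sum((g - m)^2) / n
  sk <- if (m2 == 0) NA_real_ else (sum((g - m)^3) / n) / m2^1.5
  ku <- if (m2 == 0) NA_real_ else (sum((g - m)^4) / n) / m2^2 - 3
  c(m, m2, sk, ku, sum(g > 0) / n)
}

oracle_arm <- function(levels, mask, min_pixels = 20) {
  nr <- nrow(levels); nc <- ncol(levels)
  mu <- mean(levels[mask])
  rows <- list(); ys <- c()
  for (i in 2:nr) for (j in 2:(nc - 1)) {
    if (j < 2) next
    if (mask[i, j] && mask[i, j - 1] && mask[i - 1, j] &&
        mask[i - 1, j - 1] && mask[i - 1, j + 1]) {
      rows[[length(rows) + 1]] <- c(levels[i, j - 1], levels[i - 1, j],
                                    levels[i - 1, j - 1], levels[i - 1, j + 1]) - mu
      ys <- c(ys, levels[i, j] - mu)
    }
  }
  if (length(ys) < min_pixels) return(rep(NA_real_, 5))
  X <- do.call(rbind, rows)
  theta <- MASS::ginv(t(X) %*% X) %*% t(X) %*% ys
  res <- ys - X %*% theta
  c(theta, sqrt(mean(res^2)))
}

# Literal Haar coefficient at scale s: inner product of the image block
# with the separable composite filters; L_s = 2^{-s/2} * ones(2^s),
# H_s = 2^{-s/2} * (+1 on the first half, -1 on the second half).
oracle_haar <- function(pixels, mask, max_scale) {
  rr <- range(which(apply(mask, 1, any)))
  cc <- range(which(apply(mask, 2, any)))
  box <- pixels[rr[1]:rr[2], cc[1]:cc[2], drop = FALSE]
  boxm <- mask[rr[1]:rr[2], cc[1]:cc[2], drop = FALSE]
  fill <- mean(pixels[mask])
  box[!boxm] <- fill
  out <- c()
  for (s in seq_len(max_scale)) {
    w <- 2^s
    lf <- rep(2^(-s / 2), w)
    hf <- c(rep(2^(-s / 2), w / 2), rep(-2^(-s / 2), w / 2))
    nbr <- floor(nrow(box) / w); nbc <- floor(ncol(box) / w)
    e <- list(ll = c(), hl = c(), lh = c(), hh = c())
    if (nbr >= 1 && nbc >= 1) {
      for (p in seq_len(nbr)) for (q in seq_len(nbc)) {
        ri <- ((p - 1) * w + 1):(p * w)
        ci <- ((q - 1) * w + 1):(q * w)
        if (!all(boxm[ri, ci])) next
        blk <- box[ri, ci]
        coef <- function(fr, fc) sum(blk * outer(fr, fc))
        e$ll <- c(e$ll, coef(lf, lf)^2)
        e$hl <- c(e$hl, coef(hf, lf)^2)
        e$lh <- c(e$lh, coef(lf, hf)^2)
        e$hh <- c(e$hh, coef(hf, hf)^2)
      }
    }
    for (b in c("ll", "hl", "lh", "hh"))
      out[sprintf("wav_s%d_%s", s, b)] <-
        if (length(e[[b]]) == 0) NA_real_ else mean(e[[b]])
  }
  out
}

# Independent Moore contour trace written from the textbook description.
oracle_perimeter <- function(mask, sr = 1, sc = 1) {
  nr <- nrow(mask); nc <- ncol(mask)
  inm <- function(p) p[1] >= 1 && p[1] <= nr && p[2] >= 1 && p[2] <= nc &&
    mask[p[1], p[2]]
  start <- NULL
  for (i in seq_len(nr)) {
    for (j in seq_len(nc)) if (mask[i, j]) { start <- c(i, j); break }
    if (!is.null(start)) break
  }
  # clockwise ring starting west
  ring <- list(c(0, -1), c(-1, -1), c(-1, 0), c(-1, 1),
               c(0, 1), c(1, 1), c(1, 0), c(1, -1))
  p <- start
  back <- 1  # ring index pointing at the backtrack neighbor (west of start)
  first_state <- NULL
  len <- 0
  repeat {
    hit <- NULL
    k <- back
    for (t in 1:8) {
      k <- if (k == 8) 1 else k + 1
      q <- c(p[1] + ring[[k]][1], p[2] + ring[[k]][2])
      if (inm(q)) { hit <- k; break }
    }
    if (is.null(hit)) return(0)
    state <- c(p, hit)
    if (is.null(first_state)) first_state <- state
    else if (all(state == first_state)) break
    len <- len + sqrt((ring[[hit]][1] * sr)^2 + (ring[[hit]][2] * sc)^2)
    newp <- c(p[1] + ring[[hit]][1], p[2] + ring[[hit]][2])
    bk <- if (hit == 1) 8 else hit - 1
    bpix <- c(p[1] + ring[[bk]][1], p[2] + ring[[bk]][2])
    p <- newp
    for (k2 in 1:8)
      if (p[1] + ring[[k2]][1] == bpix[1] &&
          p[2] + ring[[k2]][2] == bpix[2]) { back <- k2; break }
  }
  len
}

oracle_geometry <- function(mask, spacing = c(1, 1)) {
  sr <- spacing[1]; sc <- spacing[2]
  n <- sum(mask)
  area <- n * sr * sc
  per <- oracle_perimeter(mask, sr, sc)
  circ <- if (per > 0) 4 * pi * area / per^2 else NA_real_
  pts <- which(mask, arr.ind = TRUE)
  pts <- cbind(pts[, 1] * sr, pts[, 2] * sc)
  mx <- mean(pts[, 1]); my <- mean(pts[, 2])
  m20 <- 0; m02 <- 0; m11 <- 0
  for (r in seq_len(nrow(pts))) {
    m20 <- m20 + (pts[r, 1] - mx)^2
    m02 <- m02 + (pts[r, 2] - my)^2
    m11 <- m11 + (pts[r, 1] - mx) * (pts[r, 2] - my)
  }
  m20 <- m20 / n; m02 <- m02 / n; m11 <- m11 / n
  tr <- m20 + m02; det <- m20 * m02 - m11^2
  l1 <- tr / 2 + sqrt(max(tr^2 / 4 - det, 0))
  l2 <- tr / 2 - sqrt(max(tr^2 / 4 - det, 0))
  elong <- if (l1 > 0) sqrt(max(l2, 0) / l1) else 1
  feret <- 0
  for (a in seq_len(nrow(pts))) for (b in seq_len(nrow(pts)))
    feret <- max(feret, sqrt(sum((pts[a, ] - pts[b, ])^2)))
  c(area = area, perimeter = per, circularity = circ, elongation = elong,
    feret = feret)
}
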