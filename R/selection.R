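#' Fisher coefficient of a single feature
#'
#' Ratio of between-class to within-class variance,
#' `F = Var_between / Var_within` with
#' `Var_between = sum_c n_c (m_c - m)^2 / n` and
#' `Var_within = sum_c n_c s_c^2 / n` (population class variances). A
#' feature that separates perfectly (`Var_within = 0`, `Var_between > 0`)
#' scores `Inf` and ranks above every finite score; a globally constant
#' feature scores 0.
#'
#' @param values numeric vector, one value per lesion.
#' @param labels binary class labels.
#' @return Nonnegative scalar (possibly `Inf`).
#' @export
fisher_coefficient <- function(values, labels) {
  labels <- as.factor(labels)
  if (nlevels(droplevels(labels)) != 2L)
    stop("Fisher coefficient requires exactly two classes", call. = FALSE)
  labels <- droplevels(labels)
  n <- length(values)
  m <- mean(values)
  vb <- 0; vw <- 0
  for (cl in levels(labels)) {
    v <- values[labels == cl]
    nc <- length(v)
    if (nc < 2L) stop("each class needs at least 2 lesions", call. = FALSE)
    mc <- mean(v)
    vb <- vb + nc * (mc - m)^2 / n
    vw <- vw + nc * mean((v - mc)^2) / n
  }
  if (vw == 0) {
    if (vb > 0) Inf else 0
  } else vb / vw
}

#' Probability of classification error of the best single threshold
#'
#' Minimum misclassification fraction over all thresholds placed midway
#' between consecutive sorted unique feature values, trying both polarities.
#' A perfectly separated feature scores 0; with fewer than two distinct
#' values the error of the majority vote is returned.
#'
#' @inheritParams fisher_coefficient
#' @return Scalar in `[0, 0.5]`.
#' @export
poe_single <- function(values, labels) {
  labels <- droplevels(as.factor(labels))
  if (nlevels(labels) != 2L)
    stop("POE requires exactly two classes", call. = FALSE)
  y <- as.integer(labels) - 1L  # 0/1
  n <- length(y)
  if (length(unique(values)) < 2L)
    return(min(sum(y == 0), sum(y == 1)) / n)
  # cumulative class counts along the sorted values give every threshold's
  # error in one pass; thresholds sit between consecutive distinct values
  ord <- order(values)
  vs <- values[ord]; ys <- y[ord]
  n1 <- sum(ys); n0 <- n - n1
  below1 <- cumsum(ys)            # class-1 samples at or below position i
  below0 <- seq_len(n) - below1
  cut_ok <- vs[-n] < vs[-1]       # positions where a threshold can sit
  errA <- (below1[-n] + (n0 - below0[-n])) / n  # predict 0 below, 1 above
  errB <- (below0[-n] + (n1 - below1[-n])) / n  # reverse polarity
  min(errA[cut_ok], errB[cut_ok])
}

#' Mutual information between a discretized feature and the class label
#'
#' The feature is discretized into `n_bins` equal-frequency bins (duplicate
#' quantile edges merged); MI is computed over the bin-by-class
#' contingency table in nats, with the convention 0 log 0 = 0. Because the
#' binning is rank-based, MI is invariant under strictly monotone
#' transformations of the feature. A constant feature scores 0.
#'
#' @inheritParams fisher_coefficient
#' @param n_bins number of equal-frequency bins (default 8).
#' @return Nonnegative scalar (nats).
#' @export
mutual_information <- function(values, labels, n_bins = 8L) {
  labels <- droplevels(as.factor(labels))
  if (nlevels(labels) < 2L)
    stop("mutual information requires two classes", call. = FALSE)
  edges <- unique(stats::quantile(values, probs = seq(0, 1, length.out = n_bins + 1),
                                  type = 7, names = FALSE))
  if (length(edges) < 3L) return(0)  # fewer than 2 distinct bins
  bins <- cut(values, breaks = edges, include.lowest = TRUE)
  tab <- table(bins, labels)
  pj <- tab / sum(tab)
  pb <- rowSums(pj); pc <- colSums(pj)
  expected <- outer(pb, pc)
  terms <- pj * log(pj / expected)
  terms[pj == 0] <- 0
  max(0, sum(terms))
}

# Candidate features: numeric columns with no missing value and nonzero
# variance. Returns names plus the exclusion record.
candidate_features <- function(table) {
  feats <- feature_names(table)
  excluded <- list()
  keep <- character()
  for (nm in feats) {
    v <- table[[nm]]
    if (anyNA(v)) {
      excluded[[nm]] <- "missing values"
    } else if (stats::var(v) == 0) {
      excluded[[nm]] <- "zero variance"
    } else keep <- c(keep, nm)
  }
  list(keep = keep, excluded = excluded)
}

#' Select the top-k features by one MaZda criterion
#'
#' `criterion = "FISHER"` and `"MI"` rank each candidate feature
#' independently by its [fisher_coefficient()] or [mutual_information()]
#' score and keep the k best (descending, ties broken by canonical
#' catalogue order, i.e. table column order). `"POE_ACC"` selects greedily:
#' the first feature minimizes the probability of error ([poe_single()]);
#' each subsequent feature minimizes
#' `POE(f) + mean(|Pearson r(f, s)|)` over the already selected `s`,
#' penalizing redundancy (Mucciardi-Gose). Features with missing values or
#' zero variance are excluded from candidacy and recorded.
#'
#' @param table a [feature_table()] restricted to one binary task.
#' @param criterion `"FISHER"`, `"POE_ACC"` or `"MI"`.
#' @param k number of features to keep (default 10). When fewer candidates
#'   exist, all are returned with a warning.
#' @param n_bins bins for the MI criterion.
#' @return An object of class `selected_features`: `criterion`, `features`
#'   (ordered names), `scores`, `excluded`.
#' @export
select_features <- function(table, criterion = c("FISHER", "POE_ACC", "MI"),
                            k = 10L, n_bins = 8L) {
  criterion <- match.arg(criterion)
  cand <- candidate_features(table)
  feats <- cand$keep
  if (length(feats) == 0L) stop("no candidate features", call. = FALSE)
  if (length(feats) < k) {
    warning(sprintf("only %d candidate features for k = %d",
                    length(feats), k))
    k <- length(feats)
  }
  y <- table$label
  X <- as.matrix(table[, feats, drop = FALSE])
  if (criterion == "POE_ACC") {
    sel <- greedy_poe_acc(X, y, k)
  } else {
    scores <- switch(criterion,
      FISHER = fisher_scores(X, y),
      MI = apply(X, 2, function(v) mutual_information(v, y, n_bins)))
    ord <- order(-scores, seq_along(scores))
    sel <- list(features = feats[ord[seq_len(k)]],
                scores = unname(scores[ord[seq_len(k)]]))
  }
  structure(list(criterion = criterion, features = sel$features,
                 scores = sel$scores, excluded = cand$excluded,
                 k = k, n_bins = if (criterion == "MI") n_bins else NULL),
            class = "selected_features")
}

# Column-wise Fisher coefficients (identical to fisher_coefficient applied
# per column, vectorized for per-fold reuse in nested cross-validation).
fisher_scores <- function(X, y) {
  y <- droplevels(as.factor(y))
  n <- nrow(X)
  m <- colMeans(X)
  vb <- 0; vw <- 0
  for (cl in levels(y)) {
    Xi <- X[y == cl, , drop = FALSE]
    nc <- nrow(Xi)
    mc <- colMeans(Xi)
    vb <- vb + nc * (mc - m)^2 / n
    vw <- vw + nc * colMeans(sweep(Xi, 2, mc)^2) / n
  }
  out <- ifelse(vw == 0, ifelse(vb > 0, Inf, 0), vb / vw)
  unname(out)
}

greedy_poe_acc <- function(X, y, k) {
  p <- ncol(X)
  poe <- apply(X, 2, function(v) poe_single(v, y))
  selected <- integer()
  scores <- numeric()
  cormat <- NULL
  for (step in seq_len(k)) {
    remaining <- setdiff(seq_len(p), selected)
    if (length(selected) == 0L) {
      obj <- poe[remaining]
    } else {
      if (is.null(cormat)) cormat <- abs(stats::cor(X))
      acc <- rowMeans(cormat[remaining, selected, drop = FALSE])
      obj <- poe[remaining] + acc
    }
    pick <- remaining[order(obj, remaining)[1L]]
    selected <- c(selected, pick)
    scores <- c(scores, unname(obj[match(pick, remaining)]))
  }
  list(features = colnames(X)[selected], scores = scores)
}

#' @rdname select_features
#' @export
select_fisher <- function(table, k = 10L) select_features(table, "FISHER", k)

#' @rdname select_features
#' @export
select_poe_acc <- function(table, k = 10L) select_features(table, "POE_ACC", k)

#' @rdname select_features
#' @export
select_mi <- function(table, k = 10L, n_bins = 8L)
  select_features(table, "MI", k, n_bins)

#' @export
print.selected_features <- function(x, ...) {
  cat(sprintf("<selected_features> criterion %s, %d features\n",
              x$criterion, length(x$features)))
  for (i in seq_along(x$features))
    cat(sprintf("  %2d. %-32s %.4g\n", i, x$features[i], x$scores[i]))
  invisible(x)
}
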