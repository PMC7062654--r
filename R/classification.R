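#' Fisher linear discriminant projection (most discriminatory feature)
#'
#' Z-scores the selected features with training statistics and computes the
#' Fisher discriminant direction `w = S_w^{-1} (m_1 - m_0)` with pooled
#' within-class scatter `S_w`. A singular scatter is regularized by
#' diagonal shrinkage `S_w + lambda tr(S_w)/p I` (lambda = 1e-3); if still
#' singular the minimum-norm pseudo-inverse is used. The sign is fixed so
#' that the class listed second has the higher projected mean. The 1-D
#' projected coordinate is the most discriminatory feature (MDF) of the
#' selected set.
#'
#' @param table a [feature_table()] (rows of the binary task).
#' @param features feature names to use (at most ~10 selected names).
#' @param labels factor with two levels giving the class per row; defaults
#'   to `table$label`.
#' @param shrinkage shrinkage constant lambda (default 1e-3).
#' @return An object of class `mdf_projection` with the standardization
#'   parameters, the weight vector, and the training MDF `scores`.
#' @export
fit_lda <- function(table, features, labels = NULL, shrinkage = 1e-3) {
  if (is.null(labels)) labels <- table$label
  labels <- droplevels(as.factor(labels))
  if (nlevels(labels) != 2L) stop("fit_lda requires two classes", call. = FALSE)
  if (any(tabulate(labels) < 2L))
    stop("each class needs at least 2 lesions", call. = FALSE)
  X <- as.matrix(table[, features, drop = FALSE])
  center <- colMeans(X)
  scl <- apply(X, 2, stats::sd)
  scl[scl == 0 | !is.finite(scl)] <- 1
  Z <- sweep(sweep(X, 2, center), 2, scl, "/")
  p <- ncol(Z)
  m0 <- colMeans(Z[labels == levels(labels)[1], , drop = FALSE])
  m1 <- colMeans(Z[labels == levels(labels)[2], , drop = FALSE])
  Sw <- matrix(0, p, p)
  for (cl in levels(labels)) {
    Zi <- Z[labels == cl, , drop = FALSE]
    Zi <- sweep(Zi, 2, colMeans(Zi))
    Sw <- Sw + crossprod(Zi)
  }
  dm <- m1 - m0
  w <- tryCatch({
    if (rcond_est(Sw) < 1e-10) stop("singular")
    solve(Sw, dm)
  }, error = function(e) {
    lam <- shrinkage * sum(diag(Sw)) / p
    Sw2 <- Sw + diag(lam, p)
    tryCatch(solve(Sw2, dm), error = function(e2) pinv(Sw2) %*% dm)
  })
  w <- as.vector(w)
  nw <- sqrt(sum(w^2))
  if (nw > 0) w <- w / nw
  scores <- as.vector(Z %*% w)
  if (mean(scores[labels == levels(labels)[2]]) <
      mean(scores[labels == levels(labels)[1]])) {
    w <- -w
    scores <- -scores
  }
  structure(list(features = features, center = center, scale = scl, w = w,
                 scores = scores, labels = labels,
                 class_levels = levels(labels), shrinkage = shrinkage),
            class = "mdf_projection")
}

rcond_est <- function(A) {
  if (any(!is.finite(A))) return(0)
  tryCatch(1 / kappa(A, exact = FALSE), error = function(e) 0)
}

pinv <- function(A, rtol = 1e-10) {
  s <- svd(A)
  keep <- s$d > rtol * max(s$d, 0)
  dinv <- ifelse(keep, 1 / s$d, 0)
  s$v %*% (dinv * t(s$u))
}

#' Project new lesions onto a fitted MDF axis
#' @param proj an [fit_lda()] result.
#' @param table a [feature_table()] with the projection's features.
#' @return Numeric vector of MDF coordinates.
#' @export
project_mdf <- function(proj, table) {
  X <- as.matrix(table[, proj$features, drop = FALSE])
  Z <- sweep(sweep(X, 2, proj$center), 2, proj$scale, "/")
  as.vector(Z %*% proj$w)
}

#' k-nearest-neighbor classification with leave-one-out cross-validation
#'
#' Each lesion is predicted by the majority vote of its k nearest remaining
#' lesions (Euclidean distance on the MDF coordinates). Distance ties are
#' broken toward the lower lesion index; an even vote split is broken
#' toward the larger class overall, then toward the lower label order. All
#' tie-breaks are deterministic so a fixed input yields a bit-identical
#' report.
#'
#' @param coords numeric vector or matrix of MDF coordinates (rows =
#'   lesions).
#' @param labels factor with two levels.
#' @param k odd positive integer < n (default 1).
#' @return List with `misclassified_pct`, `accuracy`, `confusion` (2 x 2
#'   actual x predicted counts), `n`, `predicted`.
#' @export
knn_loocv <- function(coords, labels, k = 1L) {
  coords <- as.matrix(coords)
  labels <- droplevels(as.factor(labels))
  n <- nrow(coords)
  if (n < 3L) stop("need at least 3 lesions", call. = FALSE)
  if (k >= n) stop("k must be smaller than the number of lesions",
                   call. = FALSE)
  class_sizes <- table(labels)
  predicted <- factor(rep(levels(labels)[1], n), levels = levels(labels))
  for (i in seq_len(n)) {
    d <- sqrt(colSums((t(coords) - coords[i, ])^2))
    others <- setdiff(seq_len(n), i)
    ord <- others[order(d[others], others)]
    nn <- ord[seq_len(k)]
    votes <- table(factor(labels[nn], levels = levels(labels)))
    top <- which(votes == max(votes))
    if (length(top) > 1L) {
      # even split: larger class overall wins, then lower label order
      sizes <- class_sizes[top]
      top <- top[order(-sizes, top)][1L]
    }
    predicted[i] <- levels(labels)[top]
  }
  confusion <- table(actual = labels, predicted = predicted)
  errors <- sum(predicted != labels)
  list(misclassified_pct = 100 * errors / n,
       accuracy = 100 * (1 - errors / n),
       confusion = confusion, n = n, predicted = predicted)
}

#' Run one binary classification task
#'
#' For each of the three selection criteria: select up to ten features,
#' reduce them to the MDF by linear discriminant analysis, and classify by
#' k-NN with leave-one-out cross-validation. In `"paper"` mode selection
#' and LDA are fit once on the full table and LOOCV wraps the k-NN vote
#' only (the optimistic protocol of full-data selection); in `"nested"`
#' mode selection and LDA are refit inside every fold and the held-out
#' lesion is projected by the fold's model.
#'
#' @param table a [feature_table()].
#' @param group_a,group_b character vectors of class labels defining the
#'   two task groups (e.g. one label each for a pairwise task, or one label
#'   vs all remaining labels for one-vs-rest).
#' @param config a [pipeline_config()].
#' @param task_name optional display name.
#' @return List of class `task_result`: per-criterion accuracy, confusion,
#'   selected features, plus `best_criterion` / `best_accuracy`.
#' @export
run_task <- function(table, group_a, group_b, config = pipeline_config(),
                     task_name = NULL) {
  rows <- table$label %in% c(group_a, group_b)
  sub <- table[rows, , drop = FALSE]
  name_a <- paste(group_a, collapse = "+")
  name_b <- paste(group_b, collapse = "+")
  if (is.null(task_name)) task_name <- paste(name_a, "vs", name_b)
  y <- factor(ifelse(sub$label %in% group_a, name_a, name_b),
              levels = c(name_a, name_b))
  if (any(tabulate(y) < 2L))
    stop("each task group needs at least 2 lesions", call. = FALSE)
  criteria <- c("FISHER", "POE_ACC", "MI")
  per <- list()
  for (crit in criteria) {
    per[[crit]] <- tryCatch(
      run_task_criterion(sub, y, crit, config),
      error = function(e) list(accuracy = NA_real_,
                               misclassified_pct = NA_real_,
                               error = conditionMessage(e)))
  }
  accs <- vapply(per, function(z) z$accuracy %||% NA_real_, numeric(1))
  best <- if (all(is.na(accs))) NA_integer_ else which.max(accs)
  structure(list(task = task_name, group_a = name_a, group_b = name_b,
                 n = nrow(sub), criteria = per,
                 best_criterion = if (is.na(best[1])) NA_character_
                                  else criteria[best],
                 best_accuracy = if (all(is.na(accs))) NA_real_
                                 else max(accs, na.rm = TRUE),
                 mode = config$mode),
            class = "task_result")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

run_task_criterion <- function(sub, y, criterion, config) {
  k <- config$k
  if (config$mode == "paper") {
    sel <- suppressWarnings(
      select_features(sub, criterion, config$select_k, config$mi_bins))
    proj <- fit_lda(sub, sel$features, y, config$lda_shrinkage)
    res <- knn_loocv(proj$scores, y, k)
    c(res, list(selected = sel$features))
  } else {
    n <- nrow(sub)
    predicted <- factor(rep(levels(y)[1], n), levels = levels(y))
    sel_union <- character()
    for (i in seq_len(n)) {
      tr <- sub[-i, , drop = FALSE]
      ytr <- droplevels(y[-i])
      if (nlevels(ytr) != 2L || any(tabulate(ytr) < 2L))
        stop("fold with a degenerate class", call. = FALSE)
      sel <- suppressWarnings(
        select_features(tr, criterion, config$select_k, config$mi_bins))
      proj <- fit_lda(tr, sel$features, ytr, config$lda_shrinkage)
      test_coord <- project_mdf(proj, sub[i, , drop = FALSE])
      predicted[i] <- knn_predict(proj$scores, ytr, test_coord, k,
                                  class_sizes = table(ytr))
      sel_union <- union(sel_union, sel$features)
    }
    confusion <- table(actual = y, predicted = predicted)
    errors <- sum(predicted != y)
    list(misclassified_pct = 100 * errors / n,
         accuracy = 100 * (1 - errors / n),
         confusion = confusion, n = n, predicted = predicted,
         selected = sort(sel_union))
  }
}

# Predict one point from training coordinates (same tie-breaks as
# knn_loocv).
knn_predict <- function(train_coords, train_labels, x, k, class_sizes) {
  train_coords <- as.matrix(train_coords)
  d <- sqrt(colSums((t(train_coords) - x)^2))
  ord <- order(d, seq_along(d))
  nn <- ord[seq_len(k)]
  votes <- table(factor(train_labels[nn], levels = levels(train_labels)))
  top <- which(votes == max(votes))
  if (length(top) > 1L) {
    sizes <- class_sizes[top]
    top <- top[order(-sizes, top)][1L]
  }
  levels(train_labels)[top]
}

#' Run every pairwise and one-vs-rest task of a cohort
#'
#' Enumerates all unordered class pairs and each class against the pooled
#' rest, runs [run_task()] on each, and assembles the accuracy grid with
#' the best criterion per cell. Cells at or above the clinical threshold
#' (default 80 %) are flagged. Classes with fewer than 2 lesions yield
#' not-computable cells.
#'
#' @param table a [feature_table()].
#' @param classes ordered class labels (default: unique labels in table
#'   order).
#' @param config a [pipeline_config()].
#' @param contrasts optional named list of extra binary contrasts, each a
#'   list with `a` and `b` label vectors (e.g. hormone-receptor status).
#' @return Object of class `classification_report`: `tasks` (list of
#'   [run_task()] results), `grid` (data frame: one row per task with
#'   per-criterion accuracies, best criterion, flag).
#' @export
run_all_tasks <- function(table, classes = NULL, config = pipeline_config(),
                          contrasts = NULL) {
  if (is.null(classes)) classes <- unique(table$label)
  if (length(classes) < 2L) stop("need at least 2 classes", call. = FALSE)
  counts <- table(factor(table$label, levels = classes))
  tasks <- list()
  specs <- list()
  if (length(classes) >= 2L)
    for (i in seq_len(length(classes) - 1L))
      for (j in (i + 1L):length(classes))
        specs[[length(specs) + 1L]] <-
          list(a = classes[i], b = classes[j], type = "pairwise")
  for (cl in classes)
    specs[[length(specs) + 1L]] <-
      list(a = cl, b = setdiff(classes, cl), type = "one_vs_rest",
           name = paste(cl, "vs others"))
  for (nm in names(contrasts))
    specs[[length(specs) + 1L]] <-
      list(a = contrasts[[nm]]$a, b = contrasts[[nm]]$b, type = "contrast",
           name = nm)
  rows <- list()
  for (sp in specs) {
    nm <- sp$name %||% paste(paste(sp$a, collapse = "+"), "vs",
                             paste(sp$b, collapse = "+"))
    res <- tryCatch(
      run_task(table, sp$a, sp$b, config, task_name = nm),
      error = function(e) e)
    if (inherits(res, "error")) {
      rows[[nm]] <- data.frame(task = nm, type = sp$type,
                               group_a = paste(sp$a, collapse = "+"),
                               group_b = paste(sp$b, collapse = "+"),
                               n = NA_integer_, acc_fisher = NA_real_,
                               acc_poe_acc = NA_real_, acc_mi = NA_real_,
                               best_criterion = NA_character_,
                               best_accuracy = NA_real_, flagged = NA,
                               note = conditionMessage(res),
                               stringsAsFactors = FALSE)
      next
    }
    tasks[[nm]] <- res
    rows[[nm]] <- data.frame(
      task = nm, type = sp$type, group_a = res$group_a,
      group_b = res$group_b, n = res$n,
      acc_fisher = res$criteria$FISHER$accuracy %||% NA_real_,
      acc_poe_acc = res$criteria$POE_ACC$accuracy %||% NA_real_,
      acc_mi = res$criteria$MI$accuracy %||% NA_real_,
      best_criterion = res$best_criterion,
      best_accuracy = res$best_accuracy,
      flagged = isTRUE(res$best_accuracy >= config$clinical_threshold),
      note = "", stringsAsFactors = FALSE)
  }
  grid <- do.call(rbind, rows)
  rownames(grid) <- NULL
  structure(list(tasks = tasks, grid = grid, classes = classes,
                 class_counts = as.integer(counts), config = config),
            class = "classification_report")
}

#' @export
print.classification_report <- function(x, ...) {
  cat(sprintf("<classification_report> %d classes, %d tasks, mode %s, k = %d\n",
              length(x$classes), nrow(x$grid), x$config$mode, x$config$k))
  g <- x$grid
  for (r in seq_len(nrow(g))) {
    cat(sprintf("  %-28s n=%3s  %s%s\n", g$task[r],
                ifelse(is.na(g$n[r]), "-", g$n[r]),
                ifelse(is.na(g$best_accuracy[r]), "not computable",
                       sprintf("%.1f %% (%s)", g$best_accuracy[r],
                               g$best_criterion[r])),
                ifelse(isTRUE(g$flagged[r]), " *", "")))
  }
  invisible(x)
}

#' Accuracy grid in the layout of a pairwise results table
#'
#' Square matrix (classes plus an "all others" row/column) whose cells hold
#' `"accuracy % (criterion)"` strings, the symmetric presentation used for
#' groupwise classification results.
#'
#' @param report a [run_all_tasks()] result.
#' @return Character matrix.
#' @export
report_grid_matrix <- function(report) {
  cl <- report$classes
  dims <- c(cl, "all others")
  M <- matrix("-", length(dims), length(dims),
              dimnames = list(dims, dims))
  g <- report$grid
  for (r in seq_len(nrow(g))) {
    if (is.na(g$best_accuracy[r])) next
    lab <- sprintf("%.1f %% (%s)", g$best_accuracy[r], g$best_criterion[r])
    if (g$type[r] == "pairwise") {
      M[g$group_a[r], g$group_b[r]] <- lab
      M[g$group_b[r], g$group_a[r]] <- lab
    } else if (g$type[r] == "one_vs_rest") {
      M[g$group_a[r], "all others"] <- lab
      M["all others", g$group_a[r]] <- lab
    }
  }
  M
}
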