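test_that("the discriminant direction recovers the known separating axis", {
  set.seed(10)
  n <- 200
  X <- rbind(matrix(rnorm(n * 4), n, 4),
             matrix(rnorm(n * 4), n, 4) + cbind(rep(3, n), 0, 0, 0))
  colnames(X) <- paste0("f", 1:4)
  y <- rep(c("c0", "c1"), each = n)
  tab <- feature_table(X, labels = y)
  proj <- fit_lda(tab, paste0("f", 1:4))
  angle <- acos(abs(proj$w[1]) / sqrt(sum(proj$w^2))) * 180 / pi
  expect_lt(angle, 5)
  # sign convention: second class has the higher projected mean
  expect_gt(mean(proj$scores[y == "c1"]), mean(proj$scores[y == "c0"]))
})

test_that("singular scatter (duplicated feature) falls back to shrinkage without changing the MDF", {
  set.seed(11)
  n <- 40
  X <- cbind(a = rnorm(n) + rep(c(0, 2), each = n / 2), b = rnorm(n))
  X <- cbind(X, adup = X[, "a"])  # exactly collinear
  y <- rep(c("g0", "g1"), each = n / 2)
  tab <- feature_table(X, labels = y)
  proj_dup <- fit_lda(tab, c("a", "b", "adup"))
  expect_true(all(is.finite(proj_dup$w)))
  proj_ref <- fit_lda(tab, c("a", "b"))
  # projections agree up to scale/sign: perfect rank correlation
  expect_equal(abs(cor(proj_dup$scores, proj_ref$scores)), 1,
               tolerance = 1e-6)
})

test_that("identical classes give a finite projection and chance-level LOOCV", {
  set.seed(12)
  X <- matrix(rnorm(60 * 3), 60, 3)
  colnames(X) <- c("u", "v", "w")
  y <- rep(c("p", "q"), 30)
  tab <- feature_table(X, labels = y)
  proj <- fit_lda(tab, c("u", "v", "w"))
  expect_true(all(is.finite(proj$w)))
  res <- knn_loocv(proj$scores, y, k = 1)
  expect_gt(res$accuracy, 20)
  expect_lt(res$accuracy, 80)
})

test_that("k-NN LOOCV: separated clusters perfect, interleaved points fully wrong", {
  res <- knn_loocv(c(0, 0.1, 0.2, 10, 10.1, 10.2),
                   rep(c("A", "B"), each = 3), k = 1)
  expect_equal(res$misclassified_pct, 0)
  expect_equal(sum(res$confusion), 6)
  # A {0,2}, B {1,3}: every point's nearest neighbor is the other class
  res2 <- knn_loocv(c(0, 2, 1, 3), c("A", "A", "B", "B"), k = 1)
  expect_equal(res2$misclassified_pct, 100)
  expect_error(knn_loocv(c(0, 1, 2), c("A", "B", "A"), k = 3), "smaller")
})

test_that("label permutation yields chance-level accuracy (binomial band)", {
  set.seed(13)
  n <- 100
  coords <- rnorm(n)
  accs <- replicate(20, {
    y <- sample(rep(c("A", "B"), n / 2))
    knn_loocv(coords, y, k = 1)$accuracy
  })
  # mean of 20 permutation replicates within a generous band around 50
  expect_gt(mean(accs), 35)
  expect_lt(mean(accs), 65)
})

test_that("run_task reports all three criteria and the best on a separable cohort", {
  set.seed(14)
  pl <- planted_table(n_per_class = 20, n_features = 30, n_informative = 5,
                      delta = 3)
  res <- run_task(pl$table, "A", "B", pipeline_config())
  expect_named(res$criteria, c("FISHER", "POE_ACC", "MI"))
  expect_equal(res$n, 40)
  expect_gte(res$best_accuracy, 90)
  expect_true(res$best_criterion %in% c("FISHER", "POE_ACC", "MI"))
  accs <- vapply(res$criteria, `[[`, numeric(1), "accuracy")
  expect_equal(res$best_accuracy, max(accs))
})

test_that("nested mode refits per fold and is not more optimistic than paper mode on null data", {
  set.seed(15)
  diffs <- replicate(12, {
    X <- matrix(rnorm(30 * 25), 30, 25)
    colnames(X) <- sprintf("n%02d", 1:25)
    tab <- feature_table(X, labels = rep(c("A", "B"), each = 15))
    p <- run_task(tab, "A", "B", pipeline_config(select_k = 5))$best_accuracy
    n <- run_task(tab, "A", "B",
                  pipeline_config(select_k = 5, mode = "nested"))$best_accuracy
    c(p, n)
  })
  expect_gte(mean(diffs[1, ]), mean(diffs[2, ]))
})

test_that("run_all_tasks enumerates pairs plus one-vs-rest and flags >= 80%", {
  set.seed(16)
  n <- 10
  mk_class <- function(lbl, shift) {
    X <- matrix(rnorm(n * 8), n, 8)
    X[, 1] <- X[, 1] + shift
    colnames(X) <- paste0("f", 1:8)
    feature_table(X, labels = rep(lbl, n), ids = paste0(lbl, 1:n))
  }
  tab <- rbind(mk_class("w", 0), mk_class("x", 8), mk_class("y", 0.2),
               mk_class("z", 0.1))
  class(tab) <- c("feature_table", "data.frame")
  rep4 <- run_all_tasks(tab, classes = c("w", "x", "y", "z"),
                        config = pipeline_config(select_k = 4))
  expect_equal(nrow(rep4$grid), 4 * 3 / 2 + 4)
  expect_true(rep4$grid$flagged[rep4$grid$task == "w vs x"])
  M <- report_grid_matrix(rep4)
  expect_identical(M, t(M))  # symmetric presentation
  expect_identical(M["w", "x"], M["x", "w"])
})

test_that("a class with one lesion yields a not-computable cell, not an error", {
  X <- matrix(rnorm(5 * 3), 5, 3)
  colnames(X) <- c("a", "b", "c")
  tab <- feature_table(X, labels = c("A", "A", "B", "B", "C"))
  rep3 <- suppressWarnings(
    run_all_tasks(tab, classes = c("A", "B", "C"),
                  config = pipeline_config(select_k = 2)))
  g <- rep3$grid
  expect_true(any(is.na(g$best_accuracy)))
  expect_true(all(!is.na(g$note[is.na(g$best_accuracy)])))
})

test_that("reports are bit-identical across reruns (determinism)", {
  set.seed(17)
  pl <- planted_table(n_per_class = 12, n_features = 20)
  r1 <- run_task(pl$table, "A", "B", pipeline_config())
  r2 <- run_task(pl$table, "A", "B", pipeline_config())
  expect_identical(r1, r2)
})
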