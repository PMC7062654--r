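test_that("Fisher coefficient matches hand-computed variance ratios", {
  expect_equal(fisher_coefficient(c(1, 2, 1, 2), c("A", "A", "B", "B")), 0)
  expect_identical(fisher_coefficient(c(0, 0, 1, 1), c("A", "A", "B", "B")),
                   Inf)
  # A {0,1}, B {2,3}: between 1, within 0.25 -> F = 4
  expect_equal(fisher_coefficient(c(0, 1, 2, 3), c("A", "A", "B", "B")), 4)
  expect_error(fisher_coefficient(1:4, rep("A", 4)), "two classes")
  # affine invariance
  set.seed(1)
  v <- rnorm(20); y <- rep(c("A", "B"), 10)
  expect_equal(fisher_coefficient(3 * v - 7, y), fisher_coefficient(v, y))
})

test_that("POE equals the exhaustive single-threshold scan", {
  expect_equal(poe_single(c(0, 1, 10, 11), c("A", "A", "B", "B")), 0)
  expect_equal(poe_single(c(0, 1, 0, 1), c("A", "A", "B", "B")), 0.5)
  expect_equal(poe_single(c(0, 2, 1, 3), c("A", "A", "B", "B")), 0.25)
  # reversed polarity must be found too
  expect_equal(poe_single(c(10, 11, 0, 1), c("A", "A", "B", "B")), 0)
})

test_that("mutual information: aligned indicator gives ln 2, null gives ~0, constant gives 0", {
  y <- rep(c("A", "B"), each = 25)
  expect_equal(mutual_information(rep(c(0, 1), each = 25), y), log(2))
  expect_equal(mutual_information(rep(1, 50), y), 0)
  set.seed(2)
  nulls <- replicate(30, mutual_information(rnorm(200), rep(c("A", "B"), 100)))
  expect_lt(mean(nulls), 0.05)
  # monotone-transform invariance (equal-frequency binning)
  v <- rnorm(50)
  expect_equal(mutual_information(v, y), mutual_information(exp(v), y))
})

test_that("selection excludes missing/zero-variance features and honors ties and k overflow", {
  X <- cbind(good = c(0, 1, 2, 10, 11, 12), flat = rep(1, 6),
             holey = c(1, NA, 3, 4, 5, 6))
  tab <- feature_table(X, labels = rep(c("A", "B"), each = 3))
  sel <- suppressWarnings(select_fisher(tab, k = 10))
  expect_identical(sel$features, "good")
  expect_setequal(names(sel$excluded), c("flat", "holey"))
  expect_warning(select_fisher(tab, k = 10), "candidate")
  # all-identical candidates: k names in canonical (column) order
  X2 <- matrix(rep(c(0, 1, 0, 1, 2, 3), 4), 6, 4)
  colnames(X2) <- c("w", "x", "y", "z")
  tab2 <- feature_table(X2, labels = rep(c("A", "B"), each = 3))
  sel2 <- suppressWarnings(select_features(tab2, "POE_ACC", k = 3))
  expect_identical(sel2$features, c("w", "x", "y"))
})

test_that("POE+ACC's correlation penalty rejects a duplicated best feature", {
  set.seed(3)
  n <- 30
  y <- rep(c("A", "B"), each = n / 2)
  best <- ifelse(y == "A", 0, 4) + rnorm(n, sd = 0.5)
  weaker <- ifelse(y == "A", 0, 2) + rnorm(n, sd = 1)
  X <- cbind(best1 = best, best2 = best + rnorm(n, sd = 1e-3),
             indep = weaker)
  tab <- feature_table(X, labels = y)
  sel <- select_features(tab, "POE_ACC", k = 2)
  expect_identical(sel$features[1], "best1")
  expect_identical(sel$features[2], "indep")
})

test_that("Fisher and MI recover planted features; POE+ACC trades some for decorrelation", {
  set.seed(4)
  recovered <- sapply(c("FISHER", "POE_ACC", "MI"), function(crit) {
    reps <- replicate(8, {
      pl <- planted_table()
      sel <- select_features(pl$table, crit, k = 10)
      c(sum(sel$features %in% pl$informative),
        sel$features[1] %in% pl$informative)
    })
    rowMeans(reps)
  })
  expect_gte(recovered[1, "FISHER"], 9)
  expect_gte(recovered[1, "MI"], 9)
  # planted features share the label-induced correlation (r ~ 0.5 at
  # delta = 2), so the average-correlation penalty deliberately swaps some
  # of them for uncorrelated features: the first pick is always
  # informative, and recovery stays clearly above chance (2/10).
  expect_equal(unname(recovered[2, "POE_ACC"]), 1)
  expect_gte(recovered[1, "POE_ACC"], 4)
})

test_that("vectorized criterion scoring equals the per-feature definitions", {
  set.seed(6)
  X <- matrix(rnorm(40 * 15), 40, 15)
  X[, 3] <- X[, 3] + rep(c(0, 1.5), each = 20)
  X[, 7] <- 0  # constant column
  colnames(X) <- sprintf("g%02d", 1:15)
  y <- rep(c("A", "B"), each = 20)
  expect_equal(adcradiomics:::fisher_scores(X, y),
               apply(X, 2, fisher_coefficient, labels = y),
               ignore_attr = TRUE)
  # exhaustive-scan POE cross-check on coarse integer data (many ties)
  set.seed(7)
  for (rep in 1:20) {
    v <- sample(0:4, 30, replace = TRUE)
    yy <- sample(rep(c("A", "B"), 15))
    u <- sort(unique(v))
    thr <- (u[-1] + u[-length(u)]) / 2
    yb <- as.integer(factor(yy)) - 1L
    brute <- min(1, vapply(thr, function(t) {
      e1 <- (sum(yb[v <= t] == 1) + sum(yb[v > t] == 0)) / 30
      min(e1, 1 - e1)
    }, numeric(1)))
    expect_equal(poe_single(v, yy), brute)
  }
})

test_that("Fisher rank is invariant under affine feature rescaling", {
  set.seed(5)
  pl <- planted_table(n_per_class = 15, n_features = 12, n_informative = 4)
  tab <- pl$table
  sel1 <- select_fisher(tab, k = 5)
  tab$f01 <- tab$f01 * 100 - 3
  tab$f11 <- -2 * tab$f11
  sel2 <- select_fisher(tab, k = 5)
  expect_identical(sel1$features, sel2$features)
})
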