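test_that("forest importance is zero for unsplittable features and finds a planted one", {
  set.seed(12)
  labels <- rep(1:2, each = 25)
  X <- cbind(flat = rep(1, 50),
             signal = labels * 10 + rnorm(50, 0, 0.1),
             matrix(rnorm(50 * 20), 50, dimnames = list(NULL, sprintf("n%02d", 1:20))))
  imp <- forest_importance(X, labels, n_trees = 200, seed = 1)
  expect_equal(imp$gini[imp$feature_id == "flat"], 0)
  expect_identical(imp$feature_id[imp$rank == 1L], "signal")
  expect_error(forest_importance(X, rep(1, 50), seed = 1), "2 clusters")
})

test_that("forest importance is seed-reproducible", {
  set.seed(3)
  labels <- rep(1:2, each = 20)
  X <- matrix(rnorm(40 * 10), 40, dimnames = list(NULL, sprintf("f%d", 1:10)))
  X[, 1] <- X[, 1] + labels
  a <- forest_importance(X, labels, n_trees = 100, seed = 42)
  b <- forest_importance(X, labels, n_trees = 100, seed = 42)
  expect_identical(a, b)
})

test_that("duplicated informative features share importance above the noise", {
  set.seed(14)
  labels <- rep(1:2, each = 30)
  base <- labels * 2 + rnorm(60, 0, 0.5)
  X <- cbind(copy1 = base, copy2 = base,
             matrix(rnorm(60 * 30), 60,
                    dimnames = list(NULL, sprintf("n%02d", 1:30))))
  imp <- forest_importance(X, labels, n_trees = 300, seed = 2)
  noise_med <- stats::median(imp$gini[grepl("^n", imp$feature_id)])
  expect_gt(imp$gini[imp$feature_id == "copy1"], noise_med)
  expect_gt(imp$gini[imp$feature_id == "copy2"], noise_med)
  # both copies contribute: neither takes all the shared signal
  tot <- imp$gini[imp$feature_id == "copy1"] + imp$gini[imp$feature_id == "copy2"]
  expect_gt(imp$gini[imp$feature_id == "copy2"] / tot, 0.1)
})

test_that("a pure-root tree is a single leaf with proportion 1", {
  X <- matrix(rnorm(40), 20, dimnames = list(NULL, c("a", "b")))
  tree <- fit_tree(X, rep("HiClus", 20))
  expect_null(tree$root$children)
  expect_equal(tree$root$proportion, 1)
  expect_equal(tree$root$n, 20L)
})

test_that("the root split lands at the midpoint of the separating gap", {
  set.seed(6)
  x <- c(runif(20, 0, 4.6), runif(20, 5.4, 10))
  X <- matrix(x, ncol = 1, dimnames = list(NULL, "marker"))
  labels <- rep(c("A", "B"), each = 20)
  tree <- fit_tree(X, labels, min_split = 10, min_bucket = 5)
  expect_identical(tree$root$split, "marker")
  mid <- (max(x[1:20]) + min(x[21:40])) / 2
  expect_equal(tree$root$threshold, mid, tolerance = 1e-12)
  kids <- tree$root$children
  expect_equal(kids[[1]]$proportion, 1)
  expect_equal(kids[[2]]$proportion, 1)
  expect_equal(kids[[1]]$n + kids[[2]]$n, tree$root$n)
})

test_that("tree text follows the dominant-cluster block convention", {
  set.seed(6)
  x <- c(rnorm(30, 0), rnorm(30, 10))
  X <- matrix(x, ncol = 1, dimnames = list(NULL, "left EC volume"))
  labels <- rep(c("LoClus", "HiClus"), each = 30)
  txt <- format_tree(fit_tree(X, labels, min_split = 10))
  expect_match(txt[1], "^root -> (Hi|Lo)Clus \\(\\d+/60 = \\d+%\\)")
  expect_match(txt[2], "left EC volume.*->.*Clus \\(\\d+/\\d+ = \\d+%\\)")
})

test_that("tree training accuracy beats the dominant-class baseline", {
  for (s in 1:5) {
    set.seed(s)
    n <- 80
    labels <- sample(c("A", "B"), n, replace = TRUE, prob = c(0.6, 0.4))
    X <- matrix(rnorm(n * 5), n, dimnames = list(NULL, sprintf("f%d", 1:5)))
    X[, 1] <- X[, 1] + 2 * (labels == "A")
    tree <- fit_tree(X, labels)
    acc <- mean(predict(tree, X) == labels)
    expect_gte(acc, max(table(labels)) / n)
  }
})

test_that("marginal ANOVA reproduces the two-group sums-of-squares example", {
  X <- matrix(c(0, 2, 2, 4), ncol = 1, dimnames = list(NULL, "m"))
  out <- marginal_anova(X, c(1, 1, 2, 2))
  expect_equal(out$f, 2)
  expect_equal(out$df1, 1L)
  expect_equal(out$df2, 2L)
  # equal means, equal variances: F near 0
  X2 <- matrix(c(1, 2, 1, 2), ncol = 1, dimnames = list(NULL, "m"))
  expect_equal(marginal_anova(X2, c(1, 1, 2, 2))$f, 0)
})

test_that("marginal ANOVA agrees with aov and flags zero-variance features", {
  for (s in 1:5) {
    set.seed(s)
    n <- 30
    g <- sample(1:3, n, replace = TRUE)
    while (any(tabulate(g, 3) < 2)) g <- sample(1:3, n, replace = TRUE)
    X <- matrix(rnorm(n * 4), n, dimnames = list(NULL, sprintf("f%d", 1:4)))
    out <- marginal_anova(X, g)
    for (j in 1:4) {
      ref <- summary(stats::aov(X[, j] ~ factor(g)))[[1]]
      expect_equal(out$f[j], ref$`F value`[1], tolerance = 1e-9)
      expect_equal(out$p[j], ref$`Pr(>F)`[1], tolerance = 1e-9)
    }
  }
  Xz <- matrix(c(rep(1, 6), rnorm(6)), 6, dimnames = list(NULL, c("z", "ok")))
  out <- marginal_anova(Xz, rep(1:2, 3))
  expect_true(is.na(out$f[1]))
  expect_false(out$significant[1])
})

test_that("summary-statistic ANOVA is an exact identity with the raw-data fit", {
  expect_equal(anova_from_summary(c(1, 3), c(sqrt(2), sqrt(2)), c(2, 2))$f, 2)
  expect_equal(anova_from_summary(c(5, 5, 5), c(1, 2, 1), c(4, 4, 4))$f, 0)
  for (s in 1:20) {
    set.seed(s)
    k <- sample(2:4, 1)
    ns <- sample(3:10, k, replace = TRUE)
    g <- rep(seq_len(k), ns)
    x <- rnorm(sum(ns), mean = g)
    out <- anova_from_summary(tapply(x, g, mean), tapply(x, g, sd), ns)
    ref <- marginal_anova(matrix(x, ncol = 1, dimnames = list(NULL, "x")), g)
    expect_equal(out$f, ref$f, tolerance = 1e-9)
    expect_identical(out$df2, ref$df2[1])
  }
})
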