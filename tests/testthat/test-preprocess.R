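test_that("imputation reproduces hand-computed neighbour means", {
  # 6 subjects, 3 features; one missing cell whose 5 neighbours hold 1..5
  v <- cbind(x = c(0, 1, 2, 3, 4, 5),
             y = c(0, 1, 2, 3, 4, 5),
             z = c(NA, 1, 2, 3, 4, 5))
  ft <- toy_table(v)
  out <- impute_knn(ft, preprocess_config(knn_k = 5))
  expect_equal(unname(out$values[1L, "z"]), 3)
  expect_false(any(out$missing_mask))
  # observed cells untouched
  expect_identical(out$values[-1L, ], ft$values[-1L, ])
})

test_that("imputation with a constant neighbourhood returns the constant", {
  v <- cbind(x = c(0, 1, 2, 3, 4, 10), z = c(NA, rep(7, 5)))
  out <- impute_knn(toy_table(v), preprocess_config(knn_k = 5))
  expect_equal(unname(out$values[1L, "z"]), 7)
})

test_that("imputation is the identity on complete tables and idempotent", {
  set.seed(2)
  v <- matrix(rnorm(40), 8, dimnames = list(sprintf("s%d", 1:8),
                                            sprintf("f%d", 1:5)))
  ft <- feature_table(v)
  expect_identical(impute_knn(ft)$values, v)
  v[2, 3] <- NA
  once <- impute_knn(feature_table(v), preprocess_config(knn_k = 3))
  twice <- impute_knn(once, preprocess_config(knn_k = 3))
  expect_identical(once$values, twice$values)
})

test_that("imputation rejects under-observed features", {
  v <- cbind(x = 1:6, z = c(NA, NA, 7, 8, NA, NA))
  expect_error(impute_knn(toy_table(v), preprocess_config(knn_k = 5)),
               "fewer than knn_k.*z")
})

test_that("sample skewness matches the moment formula", {
  # {0,0,0,1}: m2 = 3/16, m3 = 3/32, g1 = 2/sqrt(3)
  v <- cbind(a = c(0, 0, 0, 1), b = c(-1, 0, 1, 0))
  sym <- symmetrize(toy_table(v),
                    preprocess_config(transform_family = "identity"))
  expect_equal(sym$log$skewness_before[1L], 2 / sqrt(3), tolerance = 1e-12)
  expect_equal(sym$log$skewness_before[1L], 1.1547, tolerance = 1e-4)
})

test_that("an exactly symmetric feature keeps the identity transform", {
  v <- cbind(a = c(-1, 0, 1))
  sym <- symmetrize(toy_table(v))
  expect_identical(sym$log$transform, "identity")
  expect_equal(sym$log$skewness_after, 0)
  expect_identical(sym$table$values, toy_table(v)$values)
})

test_that("strongly lognormal features elect the log transform", {
  picks <- vapply(1:20, function(s) {
    set.seed(s)
    v <- cbind(a = exp(rnorm(500)))
    symmetrize(toy_table(v))$log$transform
  }, character(1L))
  expect_gte(mean(picks == "log_shift"), 0.95)
})

test_that("symmetrizing never increases |skewness| and preserves ranks", {
  for (s in 1:10) {
    set.seed(s)
    v <- cbind(logn = exp(rnorm(80)),
               neg = -exp(rnorm(80)),
               unif = runif(80, -3, 3),
               heavy = rt(80, df = 3))
    sym <- symmetrize(toy_table(v))
    expect_true(all(abs(sym$log$skewness_after) <=
                      abs(sym$log$skewness_before) + 1e-12))
    for (j in colnames(v)) {
      expect_identical(unname(rank(sym$table$values[, j])), rank(v[, j]))
    }
  }
})

test_that("standardization uses the n-1 denominator and flags constants", {
  v <- cbind(a = c(0, 10), b = c(1, 2))
  out <- standardize_features(toy_table(v), "a")
  expect_equal(unname(out$values[, "a"]), c(-1, 1) / sqrt(2), tolerance = 1e-12)
  expect_identical(out$values[, "b"], toy_table(v)$values[, "b"])

  z <- matrix(rnorm(30), 10)
  z <- scale(z)
  dimnames(z) <- list(sprintf("s%d", 1:10), c("a", "b", "c"))
  out2 <- standardize_features(feature_table(unclass(z)[, , drop = FALSE]))
  expect_equal(out2$values, unclass(z)[, ], tolerance = 1e-12, ignore_attr = TRUE)

  const <- cbind(a = rep(1, 5), b = 1:5)
  expect_error(standardize_features(toy_table(const), c("a", "b")),
               "zero-variance.*a")
})

test_that("a fitted transform log can be re-applied to new data", {
  set.seed(4)
  v <- cbind(logn = exp(rnorm(50)), lin = rnorm(50))
  sym <- symmetrize(toy_table(v))
  v2 <- cbind(logn = exp(rnorm(20)), lin = rnorm(20))
  out <- apply_transform_log(toy_table(v2), sym$log)
  tr <- sym$log$transform[sym$log$feature_id == "logn"]
  expect_identical(tr, "log_shift")
  expect_equal(unname(out$values[, "logn"]), log(v2[, "logn"]),
               tolerance = 1e-12, ignore_attr = TRUE)
})
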