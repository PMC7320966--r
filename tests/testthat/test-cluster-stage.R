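test_that("BH adjustment matches the hand-computed step-up example", {
  out <- bh_adjust(c(0.01, 0.04, 0.03, 0.005), q = 0.05)
  expect_equal(out$adjusted, c(0.02, 0.04, 0.04, 0.02))
  expect_true(all(out$reject))
  # m = 1 identity and tie behaviour
  expect_equal(bh_adjust(0.03)$adjusted, 0.03)
  expect_equal(bh_adjust(rep(0.05, 10))$adjusted, rep(0.05, 10))
  expect_error(bh_adjust(c(0.1, 1.2)), "0, 1")
})

test_that("BH adjustment matches a direct step-up oracle on random vectors", {
  set.seed(11)
  for (i in 1:1000) {
    m <- sample(1:40, 1)
    p <- runif(m)^sample(c(1, 2, 4), 1)
    expect_equal(bh_adjust(p)$adjusted, bh_oracle(p), tolerance = 1e-12)
  }
})

test_that("Manhattan distance sums absolute coordinate differences", {
  expect_equal(manhattan_distance(c(0, 0), c(3, 4)), 7)
  expect_equal(manhattan_distance(1:5, 1:5), 0)
  set.seed(1)
  a <- rnorm(10); b <- rnorm(10)
  expect_equal(manhattan_distance(a, b), manhattan_distance(b, a))
  expect_error(manhattan_distance(1:3, 1:4), "length")
})

test_that("PAM solves the separated 1-D example exactly", {
  X <- matrix(c(0, 1, 2, 10, 11, 12), ncol = 1,
              dimnames = list(sprintf("s%d", 1:6), "x"))
  fit <- pam_cluster(X, 2)
  expect_setequal(fit$medoids, c(2L, 5L))
  expect_equal(fit$cost, 4)
  expect_equal(unname(fit$labels), c(1, 1, 1, 2, 2, 2))
})

test_that("PAM handles the degenerate k = n case", {
  X <- matrix(rnorm(8), 4, dimnames = list(sprintf("s%d", 1:4), c("a", "b")))
  fit <- pam_cluster(X, 4)
  expect_equal(fit$cost, 0)
  expect_setequal(fit$medoids, 1:4)
  expect_error(pam_cluster(rbind(X, X), 5), "distinct")
})

test_that("PAM attains the exhaustive minimum on separated instances", {
  set.seed(21)
  for (i in 1:60) {
    k <- sample(2:3, 1)
    n <- sample((2 * k):8, 1)
    inst <- separated_blobs(n, k)
    fit <- pam_cluster(inst$X, k)
    expect_equal(fit$cost, brute_pam_cost(inst$X, k), tolerance = 1e-9)
  }
})

test_that("cluster labels are invariant to subject order", {
  set.seed(5)
  inst <- separated_blobs(12, 2)
  X <- inst$X
  rownames(X) <- sprintf("s%02d", 1:12)
  perm <- sample(12)
  f1 <- pam_cluster(X, 2)
  f2 <- pam_cluster(X[perm, ], 2)
  expect_equal(match_clusters(f1$labels[perm], f2$labels)$agreement, 1)
})

test_that("silhouette widths match the hand-computed 1-D example", {
  # {0,1,9,10} labelled AABB: s = {8.5/9.5, 7.5/8.5, 7.5/8.5, 8.5/9.5}
  X <- matrix(c(0, 1, 9, 10), ncol = 1,
              dimnames = list(sprintf("s%d", 1:4), "x"))
  s <- silhouette_width(X, c("A", "A", "B", "B"))
  expect_equal(unname(s$widths),
               c(8.5 / 9.5, 7.5 / 8.5, 7.5 / 8.5, 8.5 / 9.5))
  expect_equal(s$mean, 0.8885, tolerance = 1e-4)
})

test_that("silhouette conventions: coincident pairs and singletons", {
  X <- matrix(c(0, 0, 10, 10), ncol = 1,
              dimnames = list(sprintf("s%d", 1:4), "x"))
  expect_equal(silhouette_width(X, c(1, 1, 2, 2))$mean, 1)
  X2 <- matrix(c(0, 1, 9), ncol = 1,
               dimnames = list(sprintf("s%d", 1:3), "x"))
  s <- silhouette_width(X2, c(1, 1, 2))
  expect_equal(unname(s$widths[3L]), 0)  # singleton convention
  expect_error(silhouette_width(X2, rep(1, 3)), ">= 2")
})

test_that("within dispersion is non-increasing in k and gap selects 2 blobs", {
  set.seed(31)
  inst <- separated_blobs(40, 2, spread = 1, spacing = 50)
  g <- gap_curve(inst$X, k_max = 5, B = 20, seed = 1)
  expect_true(all(diff(g$curve$log_w) <= 1e-9))
  expect_identical(g$k_hat, 2L)
  expect_error(gap_curve(matrix(1, 10, 2), seed = 1), "degenerate")
})

test_that("near-uniform data yields a flat gap curve", {
  set.seed(33)
  X <- matrix(runif(200), 100, 2)
  g <- gap_curve(X, k_max = 4, B = 30, seed = 2)
  expect_lt(max(abs(g$curve$gap)), 0.25)
})

test_that("screening selects perfectly associated features and flags constants", {
  set.seed(3)
  sev <- rnorm(40, 50, 20)
  v <- cbind(CAPS = sev, PCL = sev, junk = rnorm(40), flat = rep(1, 40))
  ft <- toy_table(v)
  fc <- feature_categories(colnames(v),
                           c("assigned_diagnosis", rep("clinical", 3)))
  scr <- screen_clinical(ft, fc)
  expect_true(scr$selected[scr$feature_id == "PCL"])
  expect_lt(scr$p_adj[scr$feature_id == "PCL"], 1e-10)
  expect_true(is.na(scr$p[scr$feature_id == "flat"]))
  expect_false(scr$selected[scr$feature_id == "flat"])
})

test_that("a single null clinical feature is selected at about the screen level", {
  set.seed(17)
  hits <- vapply(1:2000, function(i) {
    v <- cbind(CAPS = rnorm(101), PCL = rnorm(101))
    rownames(v) <- sprintf("s%03d", 1:101)
    scr <- screen_clinical(feature_table(v),
                           feature_categories(colnames(v),
                                              c("assigned_diagnosis",
                                                "clinical")))
    scr$selected[1L]
  }, logical(1L))
  expect_lt(abs(mean(hits) - 0.2), 0.02)
})

test_that("k-selection policies combine gap and silhouette as documented", {
  g <- structure(list(curve = data.frame(k = 1:4, log_w = 4:1,
                                         gap = c(0, 1, 1.2, 1.1),
                                         s = rep(0.05, 4)),
                      k_hat = 3L, B = 50L), class = "gap_curve")
  sil <- c(`2` = 0.7, `3` = 0.5, `4` = 0.3)
  expect_identical(choose_k(g, sil)$k, 3L)
  expect_false(choose_k(g, sil)$agree)
  expect_identical(choose_k(g, sil, policy = "consensus")$k, 2L)
  expect_identical(choose_k(g, sil, policy = "silhouette")$k, 2L)
  fixed <- choose_k(g, sil, policy = "fixed", fixed_k = 2)
  expect_identical(fixed$k, 2L)
  expect_match(fixed$rationale, "fixed")
  sil2 <- c(`2` = 0.2, `3` = 0.6, `4` = 0.3)
  expect_true(choose_k(g, sil2)$agree)
  expect_identical(choose_k(g, sil2, policy = "consensus")$k, 3L)
})
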