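# Independent oracles and fixture builders used across the suite.

# exhaustive k-medoids: minimum total Manhattan cost over all medoid subsets
brute_pam_cost <- function(X, k) {
  D <- as.matrix(stats::dist(X, method = "manhattan"))
  sets <- utils::combn(nrow(X), k)
  min(apply(sets, 2L, function(m) {
    sum(apply(D[, m, drop = FALSE], 1L, min))
  }))
}

# direct Benjamini-Hochberg step-up adjustment
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  adj_sorted <- rev(cummin(rev(p[o] * m / seq_len(m))))
  pmin(1, adj_sorted)[order(o)]
}

# random instance of k well-separated Gaussian blobs (centers >= 5x the
# within-blob spread apart)
separated_blobs <- function(n, k, d = 2L, spread = 1, spacing = 100) {
  centers <- matrix(stats::runif(k * d, 0, spacing * (k - 1)), k, d)
  # push centers apart deterministically on the first axis
  centers[, 1L] <- centers[, 1L] + spacing * seq_len(k)
  assign <- sort(rep_len(seq_len(k), n))
  X <- centers[assign, , drop = FALSE] +
    matrix(stats::rnorm(n * d, 0, spread), n, d)
  list(X = X, assign = assign)
}

# tiny complete feature table with one assigned-diagnosis + clinical features
toy_table <- function(values) {
  rownames(values) <- sprintf("s%02d", seq_len(nrow(values)))
  feature_table(values)
}

# small synthetic cohort for fast end-to-end tests
small_spec <- function(seed, ...) {
  synthetic_spec(n_subjects = 60L, n_cognitive = 6L, n_structural = 20L,
                 n_functional = 10L, n_planted = 6L,
                 planted_domains = c(cognitive = 2L, structural = 2L,
                                     functional = 2L),
                 seed = seed, ...)
}
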