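#' Benjamini-Hochberg step-up adjustment
#'
#' Thin wrapper around [stats::p.adjust()] (method `"BH"`) returning both the
#' adjusted p-values and the rejection set at level `q`.
#'
#' @param pvalues Numeric vector of p-values in \[0, 1\].
#' @param q FDR level.
#' @return List with `adjusted` (same order as input) and `reject` (logical).
#' @export
bh_adjust <- function(pvalues, q = 0.05) {
  if (any(!is.finite(pvalues) | pvalues < 0 | pvalues > 1)) {
    stop3c("p-values must lie in [0, 1]")
  }
  assert_scalar_number(q, "q", 0, 1)
  adjusted <- stats::p.adjust(pvalues, method = "BH")
  list(adjusted = adjusted, reject = adjusted <= q)
}

#' Supervised screening of clinical features
#'
#' Associates every clinical feature with the assigned-diagnosis score by a
#' correlation test (Pearson by default, Spearman optional), adjusts the
#' p-values by Benjamini-Hochberg across the clinical features, and selects
#' those with adjusted p at or below the permissive screening level
#' (default 0.2).  A zero-variance clinical feature has an undefined
#' p-value; it is flagged and never selected.
#'
#' @param table A complete [feature_table].
#' @param categories A [feature_categories] covering the table.
#' @param q_screen FDR level of the screen (default 0.2).
#' @param method `"pearson"` (default) or `"spearman"`.
#' @return Data frame with columns `feature_id`, `estimate`, `p`, `p_adj`,
#'   `selected`.
#' @export
screen_clinical <- function(table, categories, q_screen = 0.2,
                            method = c("pearson", "spearman")) {
  method <- match.arg(method)
  assert_scalar_number(q_screen, "q_screen", 0, 1)
  if (q_screen <= 0 || q_screen >= 1) stop3c("q_screen must lie in (0, 1)")
  categories <- align_categories(categories, table)
  ad_id <- categories$feature_id[categories$category == "assigned_diagnosis"]
  clin_ids <- categories$feature_id[categories$category == "clinical"]
  if (!length(clin_ids)) stop3c("no clinical features to screen")
  y <- table$values[, ad_id]
  res <- lapply(clin_ids, function(f) {
    x <- table$values[, f]
    if (stats::sd(x) == 0 || stats::sd(y) == 0) {
      return(data.frame(feature_id = f, estimate = NA_real_, p = NA_real_,
                        stringsAsFactors = FALSE))
    }
    ct <- stats::cor.test(x, y, method = method, exact = FALSE)
    data.frame(feature_id = f, estimate = unname(ct$estimate),
               p = ct$p.value, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$p_adj <- NA_real_
  ok <- !is.na(out$p)
  if (any(ok)) out$p_adj[ok] <- bh_adjust(out$p[ok], q_screen)$adjusted
  out$selected <- !is.na(out$p_adj) & out$p_adj <= q_screen
  out
}

#' Manhattan (L1) distance between two vectors
#'
#' @param a,b Numeric vectors of equal length.
#' @return Sum of absolute coordinate differences.
#' @export
manhattan_distance <- function(a, b) {
  if (length(a) != length(b)) stop3c("vectors differ in length")
  sum(abs(a - b))
}

#' k-medoids clustering (PAM) with Manhattan distance
#'
#' Partitioning Around Medoids: greedy BUILD initialization followed by SWAP
#' local search until no single medoid/non-medoid exchange lowers the total
#' Manhattan cost (via [cluster::pam()], which is deterministic).  Each
#' subject is assigned to its nearest medoid.  The degenerate case `k = n`
#' returns every point as its own medoid at cost 0.
#'
#' @param X Numeric matrix (subjects x features), typically standardized.
#' @param k Number of clusters, `1 <= k <=` number of distinct rows.
#' @return Object of class `cluster_model`: `k`, `medoids` (row indices),
#'   `medoid_ids`, `labels` (integer vector in `1..k`), `metric`, `cost`
#'   (total distance of points to their medoids).
#' @export
pam_cluster <- function(X, k) {
  X <- as.matrix(X)
  k <- as.integer(k)
  n <- nrow(X)
  n_distinct <- nrow(unique(X))
  if (k < 1L || k > n_distinct) {
    stop3c("k must lie in 1..", n_distinct, " (number of distinct rows)")
  }
  if (k == n) {
    labels <- seq_len(n)
  } else {
    fit <- cluster::pam(X, k, metric = "manhattan", keep.diss = FALSE,
                        keep.data = FALSE, pamonce = FALSE)
    labels <- unname(fit$clustering)
  }
  # recover medoids and cost explicitly: the medoid of a cluster is its
  # member minimizing total within-cluster L1 distance (lowest index on ties)
  D <- as.matrix(stats::dist(X, method = "manhattan"))
  medoids <- vapply(seq_len(k), function(g) {
    members <- which(labels == g)
    members[which.min(colSums(D[members, members, drop = FALSE]))]
  }, integer(1L))
  # reassign to nearest medoid (lowest medoid index on ties)
  labels <- apply(D[, medoids, drop = FALSE], 1L, which.min)
  cost <- sum(D[cbind(seq_len(n), medoids[labels])])
  structure(list(k = k, medoids = medoids,
                 medoid_ids = rownames(X)[medoids],
                 labels = stats::setNames(as.integer(labels), rownames(X)),
                 metric = "manhattan", cost = cost),
            class = "cluster_model")
}

#' @export
print.cluster_model <- function(x, ...) {
  cat(sprintf("<cluster_model> k = %d (%s), cost = %.4g, sizes: %s\n",
              x$k, x$metric, x$cost,
              paste(tabulate(x$labels, x$k), collapse = "/")))
  invisible(x)
}

#' Silhouette widths under Manhattan distance
#'
#' Per-subject silhouette `s(i) = (b - a) / max(a, b)` where `a` is the mean
#' distance to the subject's own cluster and `b` the smallest mean distance
#' to another cluster; members of singleton clusters contribute `s = 0`.
#'
#' @param X Numeric matrix.
#' @param labels Cluster labels (>= 2 clusters).
#' @return List with `widths` (per subject) and `mean`.
#' @export
silhouette_width <- function(X, labels) {
  X <- as.matrix(X)
  cl <- as.integer(factor(labels))
  if (length(cl) != nrow(X)) stop3c("labels must match rows of X")
  if (length(unique(cl)) < 2L) stop3c("silhouette requires >= 2 clusters")
  sil <- cluster::silhouette(cl, stats::dist(X, method = "manhattan"))
  widths <- stats::setNames(sil[, "sil_width"], rownames(X))
  list(widths = widths, mean = mean(widths))
}

#' Gap statistic over a range of cluster counts
#'
#' For each `k` in `1..k_max`, the within dispersion `W_k` is the total
#' Manhattan cost of [pam_cluster()].  `B` reference datasets are drawn
#' uniformly over the observed range of each feature, by default after
#' rotating the data into its principal-component basis (reference
#' `"pca"`), which respects the correlation structure of the features;
#' `reference = "range"` uses the raw feature ranges instead.
#' `gap(k) = mean_b log W_k(ref_b) - log W_k(data)` with reference spread
#' `s_k = sd_b(log W_k(ref_b)) * sqrt(1 + 1/B)`.  The one-standard-error
#' choice is the smallest `k` with `gap(k) >= gap(k+1) - s_(k+1)`.
#'
#' @param X Numeric matrix.
#' @param k_max Largest cluster count examined (>= 2).
#' @param B Number of reference datasets (>= 10).
#' @param seed Seed for the reference draws.
#' @param reference `"pca"` (default) or `"range"`; see Details.
#' @return Object of class `gap_curve`: data frame `curve` (`k`, `log_w`,
#'   `gap`, `s`) and `k_hat`.
#' @export
gap_curve <- function(X, k_max = 6L, B = 100L, seed = NULL,
                      reference = c("pca", "range")) {
  X <- as.matrix(X)
  reference <- match.arg(reference)
  k_max <- as.integer(k_max)
  B <- as.integer(B)
  if (k_max < 2L) stop3c("k_max must be >= 2")
  if (B < 10L) stop3c("B must be >= 10")
  if (all(apply(X, 2L, function(x) min(x) == max(x)))) {
    stop3c("degenerate (constant) data")
  }
  ctr <- colMeans(X)
  rot <- if (reference == "pca") svd(sweep(X, 2L, ctr), nu = 0L)$v else
    diag(ncol(X))
  rng <- apply(sweep(X, 2L, ctr) %*% rot, 2L, range)
  ks <- seq_len(k_max)
  log_w <- function(M) {
    vapply(ks, function(k) log(max(pam_cluster(M, k)$cost, 1e-12)),
           numeric(1L))
  }
  lw_data <- log_w(X)
  lw_ref <- with_seed(seed, {
    vapply(seq_len(B), function(b) {
      R <- vapply(seq_len(ncol(X)),
                  function(j) stats::runif(nrow(X), rng[1L, j], rng[2L, j]),
                  numeric(nrow(X)))
      log_w(sweep(R %*% t(rot), 2L, ctr, "+"))
    }, numeric(k_max))
  })
  gap <- rowMeans(lw_ref) - lw_data
  s <- apply(lw_ref, 1L, stats::sd) * sqrt(1 + 1 / B)
  ok <- which(gap[-k_max] >= gap[-1L] - s[-1L])
  k_hat <- if (length(ok)) min(ok) else k_max
  structure(list(curve = data.frame(k = ks, log_w = lw_data, gap = gap, s = s),
                 k_hat = as.integer(k_hat), B = B),
            class = "gap_curve")
}

#' Choose the number of clusters from gap and silhouette criteria
#'
#' Default policy takes the gap statistic's one-standard-error choice and
#' records whether the silhouette argmax (over `k >= 2`) agrees.  The
#' `"consensus"` policy requires support from both metrics: it takes the
#' gap choice when the two agree and falls back to the silhouette argmax
#' otherwise (the gap statistic is prone to over-estimating `k` when
#' clusters are elongated, as correlated clinical measures produce).  The
#' policy can instead prioritize the silhouette alone, or force a fixed
#' `k`, in which case both criteria are still reported.
#'
#' @param gap A [gap_curve()] result.
#' @param silhouette_by_k Named numeric vector: mean silhouette width for
#'   each `k` in `2..k_max`.
#' @param policy `"gap"` (default), `"consensus"`, `"silhouette"`, or
#'   `"fixed"`.
#' @param fixed_k Required when `policy = "fixed"`.
#' @return List with `k`, `gap_k`, `silhouette_k`, `agree`, `rationale`.
#' @export
choose_k <- function(gap, silhouette_by_k, policy = c("gap", "consensus",
                                                      "silhouette", "fixed"),
                     fixed_k = NULL) {
  policy <- match.arg(policy)
  stopifnot(inherits(gap, "gap_curve"))
  sil_k <- as.integer(names(silhouette_by_k)[which.max(silhouette_by_k)])
  gap_k <- gap$k_hat
  agree <- identical(gap_k, sil_k)
  k <- switch(policy,
              gap = gap_k,
              consensus = if (agree) gap_k else sil_k,
              silhouette = sil_k,
              fixed = {
                if (is.null(fixed_k)) stop3c("fixed policy requires fixed_k")
                as.integer(fixed_k)
              })
  rationale <- switch(policy,
                      gap = sprintf("gap 1-SE choice k = %d; silhouette argmax k = %d (%s)",
                                    gap_k, sil_k,
                                    if (agree) "agrees" else "disagrees"),
                      consensus = if (agree) {
                        sprintf("gap and silhouette agree on k = %d", gap_k)
                      } else {
                        sprintf("gap 1-SE choice k = %d disagrees with silhouette argmax k = %d; silhouette used",
                                gap_k, sil_k)
                      },
                      silhouette = sprintf("silhouette argmax k = %d; gap 1-SE choice k = %d",
                                           sil_k, gap_k),
                      fixed = sprintf("k = %d fixed by configuration (gap: %d, silhouette: %d)",
                                      k, gap_k, sil_k))
  list(k = k, gap_k = gap_k, silhouette_k = sil_k, agree = agree,
       rationale = rationale)
}
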