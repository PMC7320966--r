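#' Random-forest variable importance for cluster membership
#'
#' Fits a random forest (bootstrap resampling, random feature subsampling at
#' each split; [randomForest::randomForest()]) predicting the cluster labels
#' from the biomarker matrix and reports the mean decrease in Gini impurity
#' attributable to every feature, together with the out-of-bag permutation
#' importance (mean decrease in accuracy).  Gini importance is the primary
#' index; a feature the forest never splits on (e.g. zero variance) scores
#' exactly 0.
#'
#' @param X Numeric biomarker matrix (complete).
#' @param labels Cluster labels (>= 2 clusters).
#' @param n_trees Number of trees (default 500).
#' @param seed Seed controlling the forest's randomness.
#' @param categories Optional [feature_categories] supplying domain tags.
#' @return Data frame with columns `feature_id`, `domain`, `gini`,
#'   `permutation`, `rank` (1 = most important; ties broken by column
#'   order).
#' @export
forest_importance <- function(X, labels, n_trees = 500L, seed = NULL,
                              categories = NULL) {
  X <- as.matrix(X)
  y <- factor(labels)
  if (nlevels(y) < 2L) stop3c("labels must contain >= 2 clusters")
  if (anyNA(X)) stop3c("biomarker matrix must be complete")
  fit <- with_seed(seed, {
    randomForest::randomForest(x = X, y = y, ntree = as.integer(n_trees),
                               importance = TRUE)
  })
  imp <- randomForest::importance(fit)
  gini <- imp[, "MeanDecreaseGini"]
  perm <- imp[, "MeanDecreaseAccuracy"]
  domain <- if (!is.null(categories)) {
    categories$domain[match(colnames(X), categories$feature_id)]
  } else {
    NA_character_
  }
  out <- data.frame(feature_id = colnames(X), domain = domain,
                    gini = unname(gini), permutation = unname(perm),
                    stringsAsFactors = FALSE)
  out$rank <- rank(-out$gini, ties.method = "first")
  out[order(out$rank), , drop = FALSE]
}

# recursively convert an rpart frame into a nested node list; thresholds are
# read from fit$splits (exact midpoints), condition text from labels(fit)
rpart_to_nodes <- function(fit, feature_map) {
  frame <- fit$frame
  node_ids <- as.integer(rownames(frame))
  cond <- labels(fit)  # split label per frame row ("root", "x< 5", ...)
  ylev <- attr(fit, "ylevels")
  # with maxcompete = maxsurrogate = 0, splits rows follow the internal
  # nodes in frame order
  internal <- which(frame$var != "<leaf>")
  split_row <- match(seq_len(nrow(frame)), internal)
  build <- function(id) {
    i <- match(id, node_ids)
    counts <- frame$yval2[i, 1L + seq_along(ylev), drop = TRUE]
    dominant <- ylev[frame$yval[i]]
    node <- list(node = id,
                 n = frame$n[i],
                 dominant = dominant,
                 dominant_n = as.integer(max(counts)),
                 proportion = max(counts) / frame$n[i],
                 split = if (frame$var[i] == "<leaf>") NA_character_ else
                   unname(feature_map[as.character(frame$var[i])]),
                 threshold = if (frame$var[i] == "<leaf>") NA_real_ else
                   unname(fit$splits[split_row[i], "index"]))
    if (!is.na(node$split)) {
      kids <- c(2L * id, 2L * id + 1L)
      node$children <- lapply(kids, function(kid) {
        child <- build(kid)
        child$condition <- cond[match(kid, node_ids)]
        child
      })
    }
    node
  }
  build(1L)
}

#' Fit a CART classification tree on biomarkers
#'
#' Binary recursive partitioning minimizing Gini impurity
#' ([rpart::rpart()], method `"class"`).  Growth stops when a node falls
#' below the minimum split size or when no split improves the fit by the
#' complexity penalty.  Degenerate single-class data yields a single leaf.
#'
#' @param X Numeric biomarker matrix (complete).
#' @param labels Cluster labels.
#' @param min_split Minimum node size eligible for splitting (default 20).
#' @param min_bucket Minimum leaf size (default 7).
#' @param cp Complexity penalty as a fraction of root impurity
#'   (default 0.01).
#' @return Object of class `cluster_tree`: the nested `root` node (counts,
#'   dominant cluster and proportion per node) plus the underlying rpart
#'   fit used for prediction.
#' @export
fit_tree <- function(X, labels, min_split = 20L, min_bucket = 7L, cp = 0.01) {
  X <- as.matrix(X)
  if (anyNA(X)) stop3c("biomarker matrix must be complete")
  y <- factor(labels)
  safe <- make.names(colnames(X), unique = TRUE)
  feature_map <- stats::setNames(colnames(X), safe)
  if (nlevels(y) < 2L) {
    # degenerate single-class data: a pure leaf, no partitioning
    root <- list(node = 1L, n = length(y), dominant = levels(y),
                 dominant_n = length(y), proportion = 1,
                 split = NA_character_, threshold = NA_real_)
    return(structure(list(root = root, fit = NULL,
                          constant = levels(y), feature_map = feature_map),
                     class = "cluster_tree"))
  }
  df <- as.data.frame(X)
  colnames(df) <- safe
  df$.cluster <- y
  fit <- rpart::rpart(.cluster ~ ., data = df, method = "class",
                      control = rpart::rpart.control(
                        minsplit = as.integer(min_split),
                        minbucket = as.integer(min_bucket),
                        cp = cp, xval = 0L,
                        maxcompete = 0L, maxsurrogate = 0L))
  structure(list(root = rpart_to_nodes(fit, feature_map), fit = fit,
                 feature_map = feature_map),
            class = "cluster_tree")
}

#' Predict cluster membership with a fitted tree
#'
#' @param object A [fit_tree()] result.
#' @param newdata Numeric matrix with the training features as columns.
#' @param ... Unused.
#' @return Character vector of predicted cluster labels.
#' @export
predict.cluster_tree <- function(object, newdata, ...) {
  if (is.null(object$fit)) {
    return(rep(object$constant, nrow(as.matrix(newdata))))
  }
  df <- as.data.frame(as.matrix(newdata))
  colnames(df) <- names(object$feature_map)[
    match(colnames(df), object$feature_map)]
  as.character(stats::predict(object$fit, df, type = "class"))
}

#' Render a classification tree as indented text
#'
#' One line per node in the convention
#' `condition -> dominant cluster (count/total = %)`.
#'
#' @param tree A [fit_tree()] result.
#' @return Character vector of lines.
#' @export
format_tree <- function(tree) {
  stopifnot(inherits(tree, "cluster_tree"))
  map <- tree$feature_map
  pretty <- function(cond) {
    if (is.null(cond) || is.na(cond)) return("root")
    for (safe in names(map)) {
      cond <- sub(safe, map[[safe]], cond, fixed = TRUE)
    }
    cond
  }
  lines <- character(0L)
  walk <- function(node, depth, cond) {
    lines[[length(lines) + 1L]] <<- sprintf(
      "%s%s -> %s (%d/%d = %.0f%%)",
      strrep("  ", depth), pretty(cond), node$dominant, node$dominant_n,
      node$n, 100 * node$proportion)
    for (child in node$children %||% list()) {
      walk(child, depth + 1L, child$condition)
    }
  }
  walk(tree$root, 0L, NA_character_)
  lines
}

#' @export
print.cluster_tree <- function(x, ...) {
  cat(format_tree(x), sep = "\n")
  invisible(x)
}

#' Marginal one-way ANOVA of each biomarker across clusters
#'
#' Computes, per feature, the classical one-way ANOVA F statistic with
#' degrees of freedom `(k - 1, n - k)` and adjusts the p-values by
#' Benjamini-Hochberg across all biomarker features jointly.  A
#' zero-variance feature has an undefined F; it is flagged (`NA`) and never
#' significant.
#'
#' @param X Numeric biomarker matrix (complete).
#' @param labels Cluster labels; every cluster needs `n >= 2`.
#' @param q FDR level for the significant set (default 0.05).
#' @return Data frame with columns `feature_id`, `f`, `df1`, `df2`, `p`,
#'   `p_adj`, `significant`.
#' @export
marginal_anova <- function(X, labels, q = 0.05) {
  X <- as.matrix(X)
  if (anyNA(X)) stop3c("biomarker matrix must be complete")
  g <- factor(labels)
  k <- nlevels(g)
  n <- length(g)
  if (k < 2L) stop3c("need >= 2 clusters")
  counts <- tabulate(g)
  if (any(counts < 2L)) stop3c("every cluster needs n >= 2")
  gmeans <- rowsum(X, g) / counts
  grand <- colMeans(X)
  ssb <- colSums(counts * sweep(gmeans, 2L, grand)^2)
  sst <- colSums(sweep(X, 2L, grand)^2)
  ssw <- pmax(sst - ssb, 0)
  df1 <- k - 1L
  df2 <- n - k
  f <- (ssb / df1) / (ssw / df2)
  zero_var <- sst == 0
  f[zero_var] <- NA_real_
  p <- stats::pf(f, df1, df2, lower.tail = FALSE)
  out <- data.frame(feature_id = colnames(X), f = unname(f), df1 = df1,
                    df2 = df2, p = unname(p), stringsAsFactors = FALSE)
  out$p_adj <- NA_real_
  ok <- !is.na(out$p)
  if (any(ok)) out$p_adj[ok] <- bh_adjust(out$p[ok], q)$adjusted
  out$significant <- !is.na(out$p_adj) & out$p_adj <= q
  out
}

#' One-way ANOVA from per-group summary statistics
#'
#' Exact algebraic identity with the raw-data ANOVA:
#' `F = [sum n_i (m_i - m)^2 / (k - 1)] / [sum (n_i - 1) s_i^2 / (N - k)]`.
#' Useful for checking a fitted model against published group means and SDs.
#'
#' @param means,sds,ns Per-group means, standard deviations and sizes
#'   (>= 2 groups, each `n >= 2`).
#' @return List with `f`, `df1`, `df2`, `p`.
#' @export
anova_from_summary <- function(means, sds, ns) {
  k <- length(means)
  if (k < 2L || length(sds) != k || length(ns) != k) {
    stop3c("means, sds, ns must have equal length >= 2")
  }
  if (any(ns < 2L)) stop3c("every group needs n >= 2")
  if (any(sds < 0)) stop3c("sds must be non-negative")
  N <- sum(ns)
  grand <- sum(ns * means) / N
  msb <- sum(ns * (means - grand)^2) / (k - 1L)
  msw <- sum((ns - 1L) * sds^2) / (N - k)
  f <- msb / msw
  list(f = f, df1 = k - 1L, df2 = as.integer(N - k),
       p = stats::pf(f, k - 1L, N - k, lower.tail = FALSE))
}
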