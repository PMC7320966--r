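#' Preprocessing configuration
#'
#' @param knn_k Neighbour count for k-nearest-neighbour imputation
#'   (default 5).
#' @param transform_family Ordered character vector of candidate monotone
#'   transforms for [symmetrize()]; must contain `"identity"`.  Order breaks
#'   ties (earlier wins).
#' @param standardize_clinical Standardize screened clinical features before
#'   clustering (default `TRUE`).
#' @return Object of class `preprocess_config`.
#' @export
preprocess_config <- function(knn_k = 5L,
                              transform_family = c("identity", "log_shift",
                                                   "sqrt", "reciprocal"),
                              standardize_clinical = TRUE) {
  knn_k <- as.integer(knn_k)
  if (knn_k < 1L) stop3c("knn_k must be >= 1")
  known <- c("identity", "log_shift", "sqrt", "reciprocal")
  bad <- setdiff(transform_family, known)
  if (length(bad)) stop3c("unknown transform(s): ", paste(bad, collapse = ", "))
  if (!"identity" %in% transform_family) {
    stop3c("transform_family must contain \"identity\"")
  }
  structure(list(knn_k = knn_k, transform_family = transform_family,
                 standardize_clinical = isTRUE(standardize_clinical)),
            class = "preprocess_config")
}

#' k-nearest-neighbour imputation
#'
#' Replaces each missing cell by the unweighted mean of the feature's values
#' among the `knn_k` nearest subjects.  Subject distance is Euclidean over
#' jointly observed, per-feature standardized columns, rescaled by the
#' number of jointly observed features so that subjects with different
#' missingness patterns remain comparable.  Observed cells are never
#' changed; the returned table has an all-`FALSE` mask, so a second pass is
#' the identity.
#'
#' @param table A [feature_table].
#' @param config A [preprocess_config]; only `knn_k` is used.
#' @return A complete [feature_table].
#' @export
impute_knn <- function(table, config = preprocess_config()) {
  stopifnot(inherits(table, "feature_table"))
  k <- config$knn_k
  v <- table$values
  obs <- !table$missing_mask
  if (k >= nrow(v)) stop3c("knn_k must be smaller than the subject count")
  if (any(rowSums(obs) == 0L)) {
    stop3c("subject(s) with no observed feature: ",
           paste(rownames(v)[rowSums(obs) == 0L], collapse = ", "))
  }
  short <- colSums(obs) < k
  if (any(short)) {
    stop3c("feature(s) observed in fewer than knn_k subjects: ",
           paste(colnames(v)[short], collapse = ", "))
  }
  if (!any(table$missing_mask)) return(table)

  mu <- colMeans(v, na.rm = TRUE)
  sdv <- apply(v, 2L, stats::sd, na.rm = TRUE)
  sdv[sdv == 0 | is.na(sdv)] <- 1
  z <- sweep(sweep(v, 2L, mu), 2L, sdv, "/")

  out <- v
  need <- which(rowSums(!obs) > 0L)
  for (i in need) {
    zi <- z[i, ]
    joint <- obs & matrix(rep(obs[i, ], each = nrow(v)), nrow(v))
    m <- rowSums(joint)
    diff2 <- sweep(z, 2L, zi)^2
    diff2[!joint] <- 0
    d <- sqrt(rowSums(diff2) / pmax(m, 1L))
    d[m == 0L] <- Inf
    d[i] <- Inf
    for (j in which(!obs[i, ])) {
      cand <- which(obs[, j] & is.finite(d))
      if (length(cand) < k) {
        stop3c(sprintf(
          "cannot impute subject \"%s\", feature \"%s\": only %d usable neighbours",
          rownames(v)[i], colnames(v)[j], length(cand)))
      }
      nb <- cand[order(d[cand], cand)][seq_len(k)]
      out[i, j] <- mean(v[nb, j])
    }
  }
  feature_table(out, matrix(FALSE, nrow(out), ncol(out),
                            dimnames = dimnames(out)))
}

# biased sample skewness g1 = m3 / m2^(3/2); 0 for constant input
skewness_g1 <- function(x) {
  m <- mean(x)
  m2 <- mean((x - m)^2)
  if (m2 == 0) return(0)
  mean((x - m)^3) / m2^1.5
}

# shift constant keeping transform arguments positive: c = 1 - min(x) when
# min(x) <= 0, else 0
shift_constant <- function(x) {
  mn <- min(x)
  if (mn <= 0) 1 - mn else 0
}

apply_one_transform <- function(x, transform, shift) {
  switch(transform,
         identity = x,
         log_shift = log(x + shift),
         sqrt = sqrt(x + shift),
         reciprocal = -1 / (x + shift),
         stop3c("unknown transform: ", transform))
}

#' Monotone symmetrizing transforms
#'
#' For every feature, applies the member of the transform family that
#' minimizes the absolute sample skewness `|g1|`, `g1 = m3 / m2^(3/2)` with
#' biased central moments.  A shift `c = 1 - min(x)` (when `min(x) <= 0`) is
#' applied before log, square-root and reciprocal so arguments stay
#' positive; the reciprocal is negated so every family member is strictly
#' monotone increasing.  Ties are broken by family order (identity first),
#' so post-transform `|g1|` never exceeds the pre-transform value.
#'
#' @param table A complete [feature_table].
#' @param config A [preprocess_config]; `transform_family` is used.
#' @return List with `table` (transformed [feature_table]) and `log`, a data
#'   frame recording per feature the chosen transform, shift, and skewness
#'   before/after.
#' @export
symmetrize <- function(table, config = preprocess_config()) {
  stopifnot(inherits(table, "feature_table"))
  if (any(table$missing_mask)) {
    stop3c("symmetrize requires a complete table; run impute_knn first")
  }
  v <- table$values
  family <- config$transform_family
  out <- v
  rec <- vector("list", ncol(v))
  for (j in seq_len(ncol(v))) {
    x <- v[, j]
    shift <- shift_constant(x)
    cand <- lapply(family, function(tr) apply_one_transform(x, tr, shift))
    g1 <- vapply(cand, function(y) {
      if (all(is.finite(y))) skewness_g1(y) else Inf
    }, numeric(1L))
    if (all(!is.finite(g1))) {
      stop3c("non-finite values after every candidate transform for feature ",
             colnames(v)[j])
    }
    pick <- which.min(abs(g1))  # first minimum = family-order tie break
    out[, j] <- cand[[pick]]
    rec[[j]] <- data.frame(feature_id = colnames(v)[j],
                           transform = family[pick],
                           shift = shift,
                           skewness_before = skewness_g1(x),
                           skewness_after = g1[pick],
                           stringsAsFactors = FALSE)
  }
  list(table = feature_table(out), log = do.call(rbind, rec))
}

#' Apply a previously fitted transform log to new data
#'
#' Re-applies the transforms chosen by [symmetrize()] on one table (e.g. a
#' training split) to another table holding the same features.  Arguments of
#' log and reciprocal are clamped just above zero so values outside the
#' fitted range stay finite.
#'
#' @param table A complete [feature_table].
#' @param transform_log The `log` data frame returned by [symmetrize()].
#' @return A transformed [feature_table].
#' @export
apply_transform_log <- function(table, transform_log) {
  stopifnot(inherits(table, "feature_table"))
  v <- table$values
  if (!all(colnames(v) %in% transform_log$feature_id)) {
    stop3c("transform log does not cover all features")
  }
  idx <- match(colnames(v), transform_log$feature_id)
  for (j in seq_len(ncol(v))) {
    tr <- transform_log$transform[idx[j]]
    sh <- transform_log$shift[idx[j]]
    x <- v[, j]
    if (tr %in% c("log_shift", "reciprocal", "sqrt")) {
      x <- pmax(x, 1e-8 - sh)  # guard outside fitted range
    }
    v[, j] <- apply_one_transform(x, tr, sh)
  }
  feature_table(v)
}

#' Standardize a subset of features
#'
#' Centers the given features to mean 0 and scales them to SD 1 (denominator
#' `n - 1`), leaving all other columns untouched.
#'
#' @param table A complete [feature_table].
#' @param features Character vector of feature ids to standardize; defaults
#'   to all.
#' @return A [feature_table].
#' @export
standardize_features <- function(table, features = feature_ids(table)) {
  stopifnot(inherits(table, "feature_table"))
  if (any(table$missing_mask)) stop3c("standardize requires a complete table")
  v <- table$values
  missing <- setdiff(features, colnames(v))
  if (length(missing)) {
    stop3c("unknown feature(s): ", paste(missing, collapse = ", "))
  }
  sub <- v[, features, drop = FALSE]
  sds <- apply(sub, 2L, stats::sd)
  if (any(sds == 0)) {
    stop3c("zero-variance feature(s) in subset: ",
           paste(features[sds == 0], collapse = ", "))
  }
  v[, features] <- scale(sub)
  feature_table(v)
}
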