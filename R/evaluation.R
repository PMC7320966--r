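#' Two-sample test for equality of proportions (pooled Z)
#'
#' `Z = (p1 - p2) / sqrt(pbar (1 - pbar) (1/n1 + 1/n2))` with the pooled
#' proportion `pbar`, two-sided normal p-value, no continuity correction.
#' Row 1 is group 1 (by convention the higher-severity cluster), columns are
#' (positive, negative) diagnosis counts; swapping the rows flips the sign
#' of Z.
#'
#' @param counts 2x2 numeric matrix of cluster x diagnosis counts.
#' @return List with `counts`, `proportions`, `pooled`, `z`, `p`.
#' @export
two_proportion_test <- function(counts) {
  counts <- as.matrix(counts)
  if (!all(dim(counts) == c(2L, 2L)) || any(counts < 0)) {
    stop3c("counts must be a non-negative 2x2 matrix")
  }
  n <- rowSums(counts)
  if (any(n == 0)) stop3c("both row totals must be >= 1")
  p <- counts[, 1L] / n
  pooled <- sum(counts[, 1L]) / sum(n)
  se <- sqrt(pooled * (1 - pooled) * (1 / n[1L] + 1 / n[2L]))
  z <- unname((p[1L] - p[2L]) / se)
  list(counts = counts, proportions = unname(p), pooled = pooled, z = z,
       p = 2 * stats::pnorm(-abs(z)))
}

#' Match one clustering's labels to a reference clustering
#'
#' Finds the permutation of the candidate labels maximizing agreement with
#' the reference (exhaustive over label permutations, tractable for the
#' small cluster counts used here), and reports the agreement fraction
#' after relabeling.  Best-permutation agreement is always at least `1/k`.
#'
#' @param reference,candidate Label vectors over the same subjects.
#' @return List with `mapping` (named: candidate level -> reference level),
#'   `agreement`, and `relabeled` (candidate labels after mapping).
#' @export
match_clusters <- function(reference, candidate) {
  if (length(reference) != length(candidate)) {
    stop3c("labelings cover different subject sets")
  }
  ref <- as.character(reference)
  cand <- as.character(candidate)
  ref_lev <- sort(unique(ref))
  cand_lev <- sort(unique(cand))
  k <- max(length(ref_lev), length(cand_lev))
  if (k > 8L) stop3c("label matching supports at most 8 clusters")
  # pad the smaller side so the permutation is over a square label set
  lev_all_ref <- c(ref_lev, sprintf(".pad_ref_%d", seq_len(k - length(ref_lev))))
  lev_all_cand <- c(cand_lev, sprintf(".pad_cand_%d", seq_len(k - length(cand_lev))))
  perms <- function(v) {
    if (length(v) == 1L) return(list(v))
    out <- list()
    for (i in seq_along(v)) {
      for (rest in perms(v[-i])) out[[length(out) + 1L]] <- c(v[i], rest)
    }
    out
  }
  best <- NULL
  best_agree <- -1
  for (perm in perms(lev_all_ref)) {
    mapped <- perm[match(cand, lev_all_cand)]
    a <- mean(mapped == ref)
    if (a > best_agree) {
      best_agree <- a
      best <- perm
    }
  }
  mapping <- stats::setNames(best, lev_all_cand)[cand_lev]
  list(mapping = mapping, agreement = best_agree,
       relabeled = unname(mapping[cand]))
}

#' Stability configuration for train/validate cross-validation
#'
#' @param fractions Training fractions P (default 20%..90% in steps of 10%).
#' @param iterations Iterations per fraction (default 1000).
#' @param base_seed Base seed; per-iteration seeds are derived
#'   deterministically from (base seed, fraction index, iteration index).
#' @param k Cluster count used in every training run (default fixed 2).
#' @param reestimate_k Additionally re-estimate k on each training sample
#'   (gap + silhouette) and tally how often k = 2 is chosen.
#' @param gap_B Reference-set count for the per-iteration gap statistic when
#'   `reestimate_k` is on (kept small; this is the slow step).
#' @param refit_transforms Re-fit the symmetrizing transforms and the
#'   clinical screen within every training sample (default `TRUE`); when
#'   `FALSE` both are frozen from the full data.
#' @return Object of class `stability_config`.
#' @export
stability_config <- function(fractions = seq(0.2, 0.9, by = 0.1),
                             iterations = 1000L, base_seed = 1L, k = 2L,
                             reestimate_k = FALSE, gap_B = 50L,
                             refit_transforms = TRUE) {
  if (any(fractions <= 0 | fractions >= 1)) {
    stop3c("training fractions must lie in (0, 1)")
  }
  if (iterations < 1L) stop3c("iterations must be >= 1")
  structure(list(fractions = fractions, iterations = as.integer(iterations),
                 base_seed = as.integer(base_seed), k = as.integer(k),
                 reestimate_k = isTRUE(reestimate_k),
                 gap_B = as.integer(gap_B),
                 refit_transforms = isTRUE(refit_transforms)),
            class = "stability_config")
}

# one full training-sample 3C fit: screen -> cluster -> tree
fit_3c_training <- function(values_clin_raw, values_bio, diag_scores, k,
                            q_screen, standardize) {
  # screen clinical features against the assigned diagnosis
  ps <- vapply(seq_len(ncol(values_clin_raw)), function(j) {
    x <- values_clin_raw[, j]
    if (stats::sd(x) == 0 || stats::sd(diag_scores) == 0) return(NA_real_)
    stats::cor.test(x, diag_scores)$p.value
  }, numeric(1L))
  ok <- !is.na(ps)
  sel <- rep(FALSE, length(ps))
  if (any(ok)) sel[ok] <- bh_adjust(ps[ok], q_screen)$reject
  if (!any(sel)) stop3c("no clinical feature survives the screen")
  clin <- values_clin_raw[, sel, drop = FALSE]
  ctr <- colMeans(clin)
  scl <- apply(clin, 2L, stats::sd)
  if (standardize) {
    if (any(scl == 0)) stop3c("zero-variance clinical feature in training set")
    clin <- sweep(sweep(clin, 2L, ctr), 2L, scl, "/")
  }
  model <- pam_cluster(clin, k)
  tree <- fit_tree(values_bio, model$labels)
  list(model = model, tree = tree, selected = sel)
}

#' Train/validate cluster-stability cross-validation
#'
#' For every training fraction P and iteration: draw a simple random
#' training sample, re-run the 3C training pipeline on it (clinical screen,
#' k-medoids clustering, biomarker classification tree), classify the
#' held-out validation subjects with the training tree, and record the
#' fraction that lands in their full-data cluster after optimal label
#' matching on the validation set.  Iterations whose training sample cannot
#' be clustered or screened are skipped and counted.
#'
#' @param table A [feature_table] (may contain missing entries; imputed
#'   once up front).
#' @param categories A [feature_categories] covering the table.
#' @param config A [stability_config].
#' @param preprocess A [preprocess_config].
#' @param q_screen Clinical screening FDR level (default 0.2).
#' @return Object of class `stability_result`: data frame with one row per
#'   fraction (`fraction`, `mean_pct`, `sd_pct`, `frac_k2`, `iterations`,
#'   `skipped`).
#' @export
cross_validate <- function(table, categories, config = stability_config(),
                           preprocess = preprocess_config(), q_screen = 0.2) {
  stopifnot(inherits(config, "stability_config"))
  categories <- align_categories(categories, table)
  complete <- impute_knn(table, preprocess)
  sym_full <- symmetrize(complete, preprocess)
  n <- n_subjects(complete)

  ad_id <- categories$feature_id[categories$category == "assigned_diagnosis"]
  clin_ids <- categories$feature_id[categories$category == "clinical"]
  bio_ids <- categories$feature_id[categories$category == "biomarker"]

  full_vals <- sym_full$table$values
  reference <- fit_3c_training(full_vals[, clin_ids, drop = FALSE],
                               full_vals[, bio_ids, drop = FALSE],
                               full_vals[, ad_id], config$k, q_screen,
                               preprocess$standardize_clinical)$model$labels

  rows <- lapply(seq_along(config$fractions), function(fi) {
    P <- config$fractions[fi]
    matched <- rep(NA_real_, config$iterations)
    k2 <- rep(NA, config$iterations)
    skipped <- 0L
    for (it in seq_len(config$iterations)) {
      seed <- derive_seed(config$base_seed, fi, it)
      res <- try(with_seed(seed, {
        train <- sort(sample.int(n, max(2L, round(P * n))))
        valid <- setdiff(seq_len(n), train)
        if (config$refit_transforms) {
          sym_tr <- symmetrize(
            feature_table(complete$values[train, , drop = FALSE],
                          complete$missing_mask[train, , drop = FALSE]),
            preprocess)
          tr_vals <- sym_tr$table$values
          va_vals <- apply_transform_log(
            feature_table(complete$values[valid, , drop = FALSE],
                          complete$missing_mask[valid, , drop = FALSE]),
            sym_tr$log)$values
        } else {
          tr_vals <- full_vals[train, , drop = FALSE]
          va_vals <- full_vals[valid, , drop = FALSE]
        }
        fitted <- fit_3c_training(tr_vals[, clin_ids, drop = FALSE],
                                  tr_vals[, bio_ids, drop = FALSE],
                                  tr_vals[, ad_id], config$k, q_screen,
                                  preprocess$standardize_clinical)
        pred <- predict(fitted$tree, va_vals[, bio_ids, drop = FALSE])
        agree <- match_clusters(reference[valid], pred)$agreement
        khat <- if (config$reestimate_k) {
          clin_tr <- tr_vals[, clin_ids, drop = FALSE][, fitted$selected,
                                                       drop = FALSE]
          if (preprocess$standardize_clinical) clin_tr <- scale(clin_tr)
          g <- gap_curve(clin_tr, k_max = 6L, B = config$gap_B,
                         seed = derive_seed(seed, 99L))
          sil <- vapply(2:6, function(kk) {
            silhouette_width(clin_tr, pam_cluster(clin_tr, kk)$labels)$mean
          }, numeric(1L))
          names(sil) <- 2:6
          choose_k(g, sil)$k
        } else {
          NA_integer_
        }
        list(agree = agree, khat = khat)
      }), silent = TRUE)
      if (inherits(res, "try-error")) {
        skipped <- skipped + 1L
      } else {
        matched[it] <- 100 * res$agree
        k2[it] <- res$khat
      }
    }
    ok <- !is.na(matched)
    data.frame(fraction = P,
               mean_pct = mean(matched[ok]),
               sd_pct = stats::sd(matched[ok]),
               frac_k2 = if (config$reestimate_k) {
                 mean(k2[ok] == 2L)
               } else {
                 NA_real_
               },
               iterations = sum(ok), skipped = skipped)
  })
  structure(do.call(rbind, rows), class = c("stability_result", "data.frame"))
}

#' Profile configuration for bootstrap cluster profiles
#'
#' @param B Bootstrap resamples (default 400).
#' @param percentiles Lower/upper percentiles of the bootstrap medians
#'   (default 0.025 and 0.975).
#' @return Object of class `profile_config`.
#' @export
profile_config <- function(B = 400L, percentiles = c(0.025, 0.975)) {
  if (B < 2L) stop3c("B must be >= 2")
  if (length(percentiles) != 2L || any(percentiles <= 0 | percentiles >= 1) ||
      diff(percentiles) <= 0) {
    stop3c("percentiles must be two ordered values in (0, 1)")
  }
  structure(list(B = as.integer(B), percentiles = percentiles),
            class = "profile_config")
}

#' Bootstrap cluster profiles of selected features
#'
#' For each cluster and feature, resamples subjects within the cluster with
#' replacement `B` times, takes the median of each resample, and reports
#' the median of the bootstrap medians together with its percentile
#' interval.
#'
#' @param X Numeric matrix (subjects x features).
#' @param labels Cluster labels; every cluster needs `n >= 2`.
#' @param features Feature ids (columns of `X`) to profile, e.g. the
#'   top-importance biomarkers.
#' @param config A [profile_config].
#' @param seed Seed for the resampling.
#' @return Data frame with columns `cluster`, `feature_id`, `median`,
#'   `lower`, `upper`.
#' @export
bootstrap_profile <- function(X, labels, features = colnames(X),
                              config = profile_config(), seed = NULL) {
  X <- as.matrix(X)
  g <- factor(labels)
  if (any(tabulate(g) < 2L)) stop3c("every cluster needs n >= 2")
  missing <- setdiff(features, colnames(X))
  if (length(missing)) stop3c("unknown feature(s): ",
                              paste(missing, collapse = ", "))
  with_seed(seed, {
    rows <- list()
    for (lev in levels(g)) {
      idx <- which(g == lev)
      boots <- matrix(sample(idx, length(idx) * config$B, replace = TRUE),
                      ncol = config$B)
      for (f in features) {
        med <- apply(matrix(X[boots, f], ncol = config$B), 2L,
                     stats::median)
        qs <- stats::quantile(med, config$percentiles, names = FALSE,
                              type = 7)
        rows[[length(rows) + 1L]] <- data.frame(
          cluster = lev, feature_id = f, median = stats::median(med),
          lower = qs[1L], upper = qs[2L], stringsAsFactors = FALSE)
      }
    }
    do.call(rbind, rows)
  })
}
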