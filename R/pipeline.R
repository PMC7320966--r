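#' Pipeline configuration
#'
#' Exactly one of `input` (paths to an on-disk cohort) or `synthetic`
#' (a [synthetic_spec]) must be supplied.
#'
#' @param input List with `table` (CSV path), `category_map` (YAML path) and
#'   optionally `labels` (CSV path with columns subject_id, label), or
#'   `NULL`.
#' @param synthetic A [synthetic_spec], or `NULL`.
#' @param seed Master seed; every stochastic stage derives its own seed from
#'   it.
#' @param q_screen Clinical screening FDR level (default 0.2).
#' @param anova_q Marginal-ANOVA FDR level (default 0.05).
#' @param k_max Largest cluster count examined (default 6).
#' @param gap_B Reference sets for the gap statistic (default 100).
#' @param k_policy `"consensus"` (default: gap's one-standard-error choice
#'   when it agrees with the silhouette argmax, silhouette otherwise),
#'   `"gap"`, `"silhouette"` or `"fixed"`.
#' @param fixed_k Cluster count when `k_policy = "fixed"`.
#' @param n_trees Random-forest size (default 500).
#' @param n_profile Number of top-importance biomarkers profiled
#'   (default 10).
#' @param preprocess A [preprocess_config].
#' @param profile A [profile_config].
#' @param stability A [stability_config], or `NULL` to skip the stability
#'   stage.
#' @param out_dir Output directory for report files, or `NULL` to keep the
#'   report in memory only.
#' @return Object of class `pipeline_config`.
#' @export
pipeline_config <- function(input = NULL, synthetic = NULL, seed = 1L,
                            q_screen = 0.2, anova_q = 0.05, k_max = 6L,
                            gap_B = 100L, k_policy = c("consensus", "gap",
                                                       "silhouette", "fixed"),
                            fixed_k = NULL, n_trees = 500L, n_profile = 10L,
                            preprocess = preprocess_config(),
                            profile = profile_config(),
                            stability = stability_config(),
                            out_dir = NULL) {
  k_policy <- match.arg(k_policy)
  if (is.null(input) == is.null(synthetic)) {
    stop3c("exactly one of `input` and `synthetic` must be supplied")
  }
  assert_scalar_number(seed, "seed")
  assert_scalar_number(q_screen, "q_screen", 0, 1)
  if (q_screen <= 0 || q_screen >= 1) stop3c("q_screen must lie in (0, 1)")
  assert_scalar_number(anova_q, "anova_q", 0, 1)
  if (!is.null(synthetic)) stopifnot(inherits(synthetic, "synthetic_spec"))
  if (!is.null(input) && is.null(input$table)) {
    stop3c("`input$table` (feature-table CSV) is required")
  }
  if (!is.null(input) && is.null(input$category_map)) {
    stop3c("`input$category_map` (category-map YAML) is required")
  }
  structure(list(input = input, synthetic = synthetic,
                 seed = as.integer(seed), q_screen = q_screen,
                 anova_q = anova_q, k_max = as.integer(k_max),
                 gap_B = as.integer(gap_B), k_policy = k_policy,
                 fixed_k = fixed_k, n_trees = as.integer(n_trees),
                 n_profile = as.integer(n_profile), preprocess = preprocess,
                 profile = profile, stability = stability,
                 out_dir = out_dir),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' Top-level keys mirror the arguments of [pipeline_config()]; the
#' `synthetic`, `preprocess`, `profile` and `stability` keys hold nested
#' mappings passed to the respective constructors.
#'
#' @param path Path to a YAML file.
#' @return A [pipeline_config].
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) stop3c("config file not found: ", path)
  y <- yaml::read_yaml(path)
  args <- y[setdiff(names(y), c("synthetic", "preprocess", "profile",
                                "stability"))]
  flatten <- function(lst) {
    lapply(as.list(lst), function(x) if (is.list(x)) unlist(x) else x)
  }
  if (!is.null(y$synthetic)) {
    args$synthetic <- do.call(synthetic_spec, flatten(y$synthetic))
  }
  if (!is.null(y$preprocess)) {
    args$preprocess <- do.call(preprocess_config, flatten(y$preprocess))
  }
  if (!is.null(y$profile)) {
    args$profile <- do.call(profile_config, flatten(y$profile))
  }
  if (!is.null(y$stability)) {
    if (identical(y$stability, FALSE)) {
      args["stability"] <- list(NULL)  # explicit NULL: skip the stage
    } else {
      args$stability <- do.call(stability_config, flatten(y$stability))
    }
  }
  do.call(pipeline_config, args)
}

load_cohort <- function(config) {
  if (!is.null(config$synthetic)) {
    spec <- config$synthetic
    spec$seed <- derive_seed(config$seed, 1L)
    return(generate_dataset(spec))
  }
  table <- read_feature_table(config$input$table)
  categories <- read_category_map(config$input$category_map)
  labels <- NULL
  if (!is.null(config$input$labels)) {
    df <- utils::read.csv(config$input$labels, stringsAsFactors = FALSE)
    labels <- diagnosis_labels(stats::setNames(df[[2L]], df[[1L]]))
    labels <- labels[subject_ids(table)]
  }
  list(table = table, categories = categories, labels = labels,
       truth = NULL)
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop3c(sprintf("stage \"%s\" failed: %s", name, conditionMessage(e)))
  })
}

#' Run the full 3C pipeline
#'
#' Executes categorize (category-map validation), preprocess (5-nn
#' imputation, symmetrizing transforms), cluster (clinical screening,
#' k-medoids with gap/silhouette k-selection), classify (forest importance,
#' classification tree, marginal ANOVA), and evaluate (cluster-diagnosis
#' association when labels are available, bootstrap profiles, optional
#' train/validate stability).  Every stochastic step is seeded from the
#' master seed, so identical configurations produce identical reports.
#'
#' @param config A [pipeline_config].
#' @return A [run_report]; when `config$out_dir` is set the report is also
#'   written there as `report.json` (+ `.txt`).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  cohort <- stage("load", load_cohort(config))
  categories <- stage("categorize",
                      align_categories(cohort$categories, cohort$table))

  complete <- stage("impute", impute_knn(cohort$table, config$preprocess))
  sym <- stage("symmetrize", symmetrize(complete, config$preprocess))
  vals <- sym$table$values

  screening <- stage("screen",
                     screen_clinical(sym$table, categories, config$q_screen))
  selected <- screening$feature_id[screening$selected]
  if (!length(selected)) {
    stop3c("stage \"screen\" failed: no clinical feature survives the screen")
  }

  cluster_out <- stage("cluster", {
    clin <- vals[, selected, drop = FALSE]
    if (config$preprocess$standardize_clinical) clin <- scale(clin)
    gap <- gap_curve(clin, k_max = config$k_max, B = config$gap_B,
                     seed = derive_seed(config$seed, 2L))
    sil <- vapply(2:config$k_max, function(k) {
      silhouette_width(clin, pam_cluster(clin, k)$labels)$mean
    }, numeric(1L))
    names(sil) <- 2:config$k_max
    pick <- choose_k(gap, sil, policy = config$k_policy,
                     fixed_k = config$fixed_k)
    k <- max(pick$k, 2L)  # downstream characterization needs >= 2 clusters
    model <- pam_cluster(clin, k)
    # order clusters by decreasing mean assigned-diagnosis score, so
    # cluster 1 is always the high-severity cluster
    sev_means <- tapply(vals[, categories$feature_id[
      categories$category == "assigned_diagnosis"]], model$labels, mean)
    ord <- order(sev_means, decreasing = TRUE)
    relabel <- match(seq_len(k), ord)
    model$labels[] <- relabel[model$labels]
    model$medoids <- model$medoids[ord]
    model$medoid_ids <- model$medoid_ids[ord]
    list(model = model, gap = gap, silhouette = sil, pick = pick,
         mean_sil = unname(sil[as.character(k)]))
  })
  model <- cluster_out$model
  labels <- model$labels

  ad_id <- categories$feature_id[categories$category == "assigned_diagnosis"]
  association <- NULL
  if (!is.null(cohort$labels) && model$k == 2L) {
    association <- stage("associate", {
      counts <- rbind(
        hi = c(sum(cohort$labels[labels == 1L]), sum(labels == 1L) -
                 sum(cohort$labels[labels == 1L])),
        lo = c(sum(cohort$labels[labels == 2L]), sum(labels == 2L) -
                 sum(cohort$labels[labels == 2L])))
      colnames(counts) <- c("positive", "negative")
      tp <- two_proportion_test(counts)
      av <- marginal_anova(vals[, ad_id, drop = FALSE], labels, q = 0.05)
      list(two_proportion = tp[c("proportions", "pooled", "z", "p")],
           counts = counts,
           anova = list(f = av$f[1L], df1 = av$df1[1L], df2 = av$df2[1L],
                        p = av$p[1L]))
    })
  }

  bio_ids <- categories$feature_id[categories$category == "biomarker"]
  classifier <- stage("classify", {
    bio <- vals[, bio_ids, drop = FALSE]
    importance <- forest_importance(bio, labels, n_trees = config$n_trees,
                                    seed = derive_seed(config$seed, 3L),
                                    categories = categories)
    tree <- fit_tree(bio, labels)
    anova <- marginal_anova(bio, labels, q = config$anova_q)
    list(importance = importance, tree = tree, tree_text = format_tree(tree),
         anova = anova)
  })

  profiles <- stage("profile", {
    top <- utils::head(classifier$importance$feature_id, config$n_profile)
    bootstrap_profile(vals[, bio_ids, drop = FALSE], labels, top,
                      config$profile, seed = derive_seed(config$seed, 4L))
  })

  stability <- NULL
  if (!is.null(config$stability)) {
    stability <- stage("stability", {
      cfg <- config$stability
      cfg$base_seed <- derive_seed(config$seed, 5L)
      cross_validate(cohort$table, categories, cfg, config$preprocess,
                     config$q_screen)
    })
  }

  report <- run_report(
    seed = config$seed,
    config = list(q_screen = config$q_screen, anova_q = config$anova_q,
                  k_max = config$k_max, gap_B = config$gap_B,
                  k_policy = config$k_policy, n_trees = config$n_trees),
    screening = screening,
    cluster = list(k = model$k, medoid_ids = model$medoid_ids,
                   labels = as.list(labels), cost = model$cost,
                   metric = model$metric,
                   sizes = as.list(tabulate(labels, model$k)),
                   mean_silhouette = cluster_out$mean_sil,
                   gap = cluster_out$gap$curve,
                   silhouette_by_k = as.list(cluster_out$silhouette),
                   rationale = cluster_out$pick$rationale),
    association = association,
    classifier = list(importance = classifier$importance,
                      tree_text = classifier$tree_text,
                      anova = classifier$anova),
    stability = if (!is.null(stability)) as.data.frame(stability),
    profiles = profiles)

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    write_report(report, file.path(config$out_dir, "report.json"))
    utils::write.csv(classifier$importance,
                     file.path(config$out_dir, "importance.csv"),
                     row.names = FALSE)
    utils::write.csv(classifier$anova,
                     file.path(config$out_dir, "anova.csv"),
                     row.names = FALSE)
    if (!is.null(stability)) {
      utils::write.csv(as.data.frame(stability),
                       file.path(config$out_dir, "stability.csv"),
                       row.names = FALSE)
    }
  }
  report
}
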