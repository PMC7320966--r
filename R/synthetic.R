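#' Specification of a synthetic multi-domain cohort
#'
#' Describes a simulated cohort with the structure the pipeline assumes: a
#' latent two-component severity mixture on the assigned-diagnosis scale
#' (CAPS-like, truncated to its scale range), clinical totals that load on
#' severity plus a component-linked offset, and three biomarker domains
#' (cognitive z-scores, volume-like positive structural features, bounded
#' correlation-like functional features) in which a small planted subset is
#' shifted between the two severity components and the rest is pure noise.
#'
#' Default block sizes reproduce a 256-feature inventory: 1 assigned
#' diagnosis + 4 clinical + 11 cognitive + 192 structural + 48 functional.
#'
#' @param n_subjects Number of subjects (default 101).
#' @param n_clinical,n_cognitive,n_structural,n_functional Block sizes.
#' @param component_weights Mixing proportions of the high/low severity
#'   components (default 57:44).
#' @param component_means,component_sds Severity moments per component on the
#'   assigned-diagnosis scale.
#' @param severity_range Truncation range of the severity scale.
#' @param clinical_loadings Loading of each clinical total on severity.
#' @param clinical_shift Component-linked offset added to each clinical total
#'   for high-severity subjects, on the severity scale.  This encodes the
#'   clinical signal that distinguishes the subtypes beyond the assigned
#'   diagnosis itself.
#' @param clinical_noise_sds Independent noise SD of each clinical total.
#' @param n_planted Number of informative biomarkers planted across domains.
#' @param planted_effect Standardized (latent-scale) mean shift of planted
#'   biomarkers between the two components.
#' @param planted_domains Named integer split of `n_planted` across
#'   `cognitive`, `structural`, `functional`.
#' @param missing_rate Independent cell-missingness probability in \[0, 0.2\].
#' @param diagnosis_threshold Severity threshold of the binary diagnosis rule.
#' @param label_noise Probability that a diagnosis label is flipped.
#' @param seed Integer seed making the cohort reproducible.
#' @return Object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_subjects = 101L,
                           n_clinical = 4L,
                           n_cognitive = 11L,
                           n_structural = 192L,
                           n_functional = 48L,
                           component_weights = c(hi = 57, lo = 44) / 101,
                           component_means = c(hi = 61.91, lo = 37.45),
                           component_sds = c(hi = 18.16, lo = 23.12),
                           severity_range = c(0, 136),
                           clinical_loadings = rep(1, n_clinical),
                           clinical_shift = rep(70, n_clinical),
                           clinical_noise_sds = c(18, 21, 24, 27)[seq_len(n_clinical)],
                           n_planted = 10L,
                           planted_effect = 4,
                           planted_domains = c(cognitive = 2L, structural = 5L,
                                               functional = 3L),
                           missing_rate = 0.01,
                           diagnosis_threshold = 45,
                           label_noise = 0.15,
                           seed = 1L) {
  spec <- list(n_subjects = as.integer(n_subjects),
               n_clinical = as.integer(n_clinical),
               n_cognitive = as.integer(n_cognitive),
               n_structural = as.integer(n_structural),
               n_functional = as.integer(n_functional),
               component_weights = component_weights / sum(component_weights),
               component_means = component_means,
               component_sds = component_sds,
               severity_range = severity_range,
               clinical_loadings = rep_len(clinical_loadings, n_clinical),
               clinical_shift = rep_len(clinical_shift, n_clinical),
               clinical_noise_sds = rep_len(clinical_noise_sds, n_clinical),
               n_planted = as.integer(n_planted),
               planted_effect = planted_effect,
               planted_domains = planted_domains,
               missing_rate = missing_rate,
               diagnosis_threshold = diagnosis_threshold,
               label_noise = label_noise,
               seed = as.integer(seed))
  counts <- unlist(spec[c("n_subjects", "n_clinical", "n_cognitive",
                          "n_structural", "n_functional")])
  if (any(counts <= 0L)) stop3c("all block counts must be positive")
  if (!all(is.finite(unlist(spec[c("component_means", "component_sds",
                                   "clinical_loadings", "clinical_shift",
                                   "clinical_noise_sds", "planted_effect")])))) {
    stop3c("mixture, loading and effect parameters must be finite")
  }
  if (any(spec$component_sds <= 0)) stop3c("component SDs must be positive")
  if (spec$missing_rate < 0 || spec$missing_rate > 0.2) {
    stop3c("missing_rate must lie in [0, 0.2]")
  }
  if (spec$label_noise < 0 || spec$label_noise > 0.5) {
    stop3c("label_noise must lie in [0, 0.5]")
  }
  if (sum(spec$planted_domains) != spec$n_planted) {
    stop3c("planted_domains must sum to n_planted")
  }
  if (spec$planted_domains[["cognitive"]] > spec$n_cognitive ||
      spec$planted_domains[["structural"]] > spec$n_structural ||
      spec$planted_domains[["functional"]] > spec$n_functional) {
    stop3c("planted counts exceed domain sizes")
  }
  structure(spec, class = "synthetic_spec")
}

# severity draws from the truncated two-component mixture, by rejection
draw_severity <- function(component, spec) {
  mu <- spec$component_means[component]
  sd_ <- spec$component_sds[component]
  sev <- stats::rnorm(length(component), mu, sd_)
  lo <- spec$severity_range[1L]
  hi <- spec$severity_range[2L]
  while (any(bad <- sev < lo | sev > hi)) {
    sev[bad] <- stats::rnorm(sum(bad), mu[bad], sd_[bad])
  }
  sev
}

#' Generate a synthetic cohort
#'
#' Draws a full cohort (feature table, category map, binary diagnosis
#' labels) from a [synthetic_spec], together with the generating ground
#' truth (per-subject severity component and the planted biomarker ids).
#' The same seed yields a bit-identical dataset.
#'
#' Planted biomarkers receive a latent shift of `planted_effect` standard
#' deviations between components before the monotone map onto their domain
#' scale (identity for cognitive z-scores, exponential for volume-like
#' structural features, tanh for bounded functional features).
#'
#' @param spec A [synthetic_spec].
#' @return List with elements `table` ([feature_table]), `categories`
#'   ([feature_categories]), `labels` ([diagnosis_labels]) and `truth`
#'   (list: `component`, `severity`, `planted`).
#' @export
generate_dataset <- function(spec = synthetic_spec()) {
  stopifnot(inherits(spec, "synthetic_spec"))
  with_seed(spec$seed, {
    n <- spec$n_subjects
    subj <- sprintf("subj_%03d", seq_len(n))
    component <- sample(c("hi", "lo"), n, replace = TRUE,
                        prob = spec$component_weights[c("hi", "lo")])
    severity <- draw_severity(component, spec)
    is_hi <- component == "hi"

    clin_ids <- c("PCL", "BDI", "BAI", "CGI",
                  sprintf("clinical_%02d", seq_len(max(0L, spec$n_clinical - 4L))))
    clin_ids <- clin_ids[seq_len(spec$n_clinical)]
    clinical <- vapply(seq_len(spec$n_clinical), function(j) {
      spec$clinical_loadings[j] * severity +
        spec$clinical_shift[j] * is_hi +
        stats::rnorm(n, 0, spec$clinical_noise_sds[j])
    }, numeric(n))
    colnames(clinical) <- clin_ids

    cog_ids <- sprintf("cognitive_%02d", seq_len(spec$n_cognitive))
    str_ids <- sprintf("structural_%03d", seq_len(spec$n_structural))
    fun_ids <- sprintf("functional_%02d", seq_len(spec$n_functional))
    planted <- c(
      sample(cog_ids, spec$planted_domains[["cognitive"]]),
      sample(str_ids, spec$planted_domains[["structural"]]),
      sample(fun_ids, spec$planted_domains[["functional"]])
    )

    latent <- function(id) {
      z <- stats::rnorm(n)
      if (id %in% planted) z <- z + spec$planted_effect * is_hi
      z
    }
    cognitive <- vapply(cog_ids, latent, numeric(n))
    str_meanlog <- stats::runif(spec$n_structural, 5.5, 8.5)
    structural <- vapply(seq_len(spec$n_structural), function(j) {
      exp(str_meanlog[j] + 0.25 * latent(str_ids[j]))
    }, numeric(n))
    colnames(structural) <- str_ids
    functional <- vapply(fun_ids, function(id) tanh(0.6 * latent(id)),
                         numeric(n))

    values <- cbind(CAPS = severity, clinical, cognitive, structural,
                    functional)
    rownames(values) <- subj

    mask <- matrix(stats::runif(length(values)) < spec$missing_rate,
                   nrow = n, dimnames = dimnames(values))
    # keep imputation preconditions satisfiable: every feature observed in at
    # least 6 subjects, every subject observed somewhere
    for (j in which(colSums(!mask) < 6L)) {
      keep <- which(mask[, j])
      mask[keep[seq_len(6L - sum(!mask[, j]))], j] <- FALSE
    }
    for (i in which(rowSums(!mask) == 0L)) mask[i, 1L] <- FALSE
    values[mask] <- NA_real_
    table <- feature_table(values, mask)

    categories <- feature_categories(
      feature_id = colnames(values),
      category = c("assigned_diagnosis", rep("clinical", spec$n_clinical),
                   rep("biomarker", spec$n_cognitive + spec$n_structural +
                         spec$n_functional)),
      domain = c(NA_character_, rep(NA_character_, spec$n_clinical),
                 rep("cognitive", spec$n_cognitive),
                 rep("structural", spec$n_structural),
                 rep("functional", spec$n_functional)))

    pos <- severity > spec$diagnosis_threshold
    flip <- stats::runif(n) < spec$label_noise
    labels <- diagnosis_labels(as.integer(xor(pos, flip)), subj)

    list(table = table, categories = categories, labels = labels,
         truth = list(component = stats::setNames(component, subj),
                      severity = stats::setNames(severity, subj),
                      planted = planted),
         spec = spec)
  })
}

#' Summarize a synthetic cohort against its generating truth
#'
#' Computes component-wise means/SDs per feature and the realized
#' standardized effect (high minus low component mean over pooled SD) of
#' every feature, flagging the planted ones.
#'
#' @param table A complete or incomplete [feature_table].
#' @param truth The `truth` element returned by [generate_dataset()].
#' @return List with `moments` and `effects` data frames.
#' @export
summarize_dataset <- function(table, truth) {
  stopifnot(inherits(table, "feature_table"))
  comp <- truth$component
  if (length(comp) != n_subjects(table) ||
      !identical(names(comp), subject_ids(table))) {
    stop3c("truth$component does not align with the table's subjects")
  }
  v <- table$values
  hi <- comp == "hi"
  m_hi <- colMeans(v[hi, , drop = FALSE], na.rm = TRUE)
  m_lo <- colMeans(v[!hi, , drop = FALSE], na.rm = TRUE)
  s_hi <- apply(v[hi, , drop = FALSE], 2L, stats::sd, na.rm = TRUE)
  s_lo <- apply(v[!hi, , drop = FALSE], 2L, stats::sd, na.rm = TRUE)
  n_hi <- sum(hi); n_lo <- sum(!hi)
  pooled <- sqrt(((n_hi - 1) * s_hi^2 + (n_lo - 1) * s_lo^2) /
                   (n_hi + n_lo - 2))
  effect <- ifelse(pooled > 0, (m_hi - m_lo) / pooled, 0)
  list(
    moments = data.frame(feature_id = colnames(v), mean_hi = m_hi,
                         sd_hi = s_hi, mean_lo = m_lo, sd_lo = s_lo,
                         row.names = NULL, stringsAsFactors = FALSE),
    effects = data.frame(feature_id = colnames(v), effect = effect,
                         planted = colnames(v) %in% truth$planted,
                         row.names = NULL, stringsAsFactors = FALSE)
  )
}
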