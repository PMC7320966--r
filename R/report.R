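#' Assemble a pipeline run report
#'
#' A run report bundles the outputs of every stage together with provenance
#' (seed, configuration hash, timestamp) so that a run can be archived and
#' re-read losslessly.
#'
#' @param seed Master seed of the run.
#' @param config The pipeline configuration used (list).
#' @param screening Screening table (data frame) or `NULL`.
#' @param cluster Cluster-model summary (list) or `NULL`.
#' @param association Cluster-diagnosis association results or `NULL`.
#' @param classifier Classifier report (importance / tree / ANOVA) or `NULL`.
#' @param stability Stability table (data frame) or `NULL`.
#' @param profiles Bootstrap profile table (data frame) or `NULL`.
#' @return Object of class `run_report`.
#' @export
run_report <- function(seed, config = list(), screening = NULL, cluster = NULL,
                       association = NULL, classifier = NULL, stability = NULL,
                       profiles = NULL) {
  assert_scalar_number(seed, "seed")
  cfg_chr <- paste(deparse(config), collapse = "")
  structure(list(
    provenance = list(
      seed = as.integer(seed),
      config_hash = sprintf("%08x", sum(utf8ToInt(cfg_chr) *
                                          (seq_along(utf8ToInt(cfg_chr)) %% 997 + 1)) %%
                              4294967296),
      timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
    ),
    config = config,
    screening = screening,
    cluster = cluster,
    association = association,
    classifier = classifier,
    stability = stability,
    profiles = profiles
  ), class = "run_report")
}

#' Write a run report to disk
#'
#' Emits the machine-readable JSON report at `path` (numeric fields at full
#' double precision, so re-reading reproduces them exactly) and, alongside
#' it, a human-readable plain-text summary at `paste0(path, ".txt")`.
#'
#' @param report A [run_report].
#' @param path Output path for the JSON report.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  stopifnot(inherits(report, "run_report"))
  dir <- dirname(path)
  if (!dir.exists(dir)) stop3c("output directory does not exist: ", dir)
  json <- jsonlite::toJSON(unclass(report), digits = I(17), auto_unbox = TRUE,
                           dataframe = "columns", null = "null", na = "null",
                           pretty = TRUE)
  writeLines(json, path)
  writeLines(format_report(report), paste0(path, ".txt"))
  invisible(path)
}

#' Read back a JSON run report
#'
#' @param path Path written by [write_report()].
#' @return A `run_report` object.
#' @export
read_report <- function(path) {
  if (!file.exists(path)) stop3c("file not found: ", path)
  lst <- jsonlite::fromJSON(path, simplifyVector = TRUE,
                            simplifyDataFrame = TRUE)
  structure(lst, class = "run_report")
}

#' Render the plain-text summary of a run report
#'
#' @param report A [run_report].
#' @return Character vector of lines.
#' @export
format_report <- function(report) {
  out <- c("3C pipeline run report",
           "======================",
           sprintf("seed:        %d", report$provenance$seed),
           sprintf("config hash: %s", report$provenance$config_hash),
           sprintf("timestamp:   %s", report$provenance$timestamp))
  if (!is.null(report$screening)) {
    s <- as.data.frame(report$screening)
    out <- c(out, "", "Clinical screening (vs assigned diagnosis):",
             utils::capture.output(print(s, row.names = FALSE)))
  }
  if (!is.null(report$cluster)) {
    cl <- report$cluster
    out <- c(out, "", sprintf(
      "Clustering: k = %s (%s), mean silhouette = %.3f, sizes: %s",
      cl$k, cl$rationale %||% "", as.numeric(cl$mean_silhouette %||% NA),
      paste(unlist(cl$sizes), collapse = "/")))
  }
  if (!is.null(report$association)) {
    a <- report$association
    out <- c(out, "", sprintf(
      "Cluster vs diagnosis: Z = %.3f (p = %.3g); severity ANOVA F(%d,%d) = %.3f (p = %.3g)",
      as.numeric(a$two_proportion$z), as.numeric(a$two_proportion$p),
      as.integer(a$anova$df1), as.integer(a$anova$df2),
      as.numeric(a$anova$f), as.numeric(a$anova$p)))
  }
  if (!is.null(report$classifier$importance)) {
    imp <- utils::head(as.data.frame(report$classifier$importance), 10L)
    out <- c(out, "", "Top biomarkers by mean decrease Gini:",
             utils::capture.output(print(imp, row.names = FALSE)))
  }
  if (!is.null(report$classifier$tree_text)) {
    out <- c(out, "", "Classification tree:",
             unlist(report$classifier$tree_text))
  }
  if (!is.null(report$stability)) {
    out <- c(out, "", "Stability (train/validate matched %):",
             utils::capture.output(
               print(as.data.frame(report$stability), row.names = FALSE)))
  }
  out
}

#' @export
print.run_report <- function(x, ...) {
  cat(format_report(x), sep = "\n")
  invisible(x)
}
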