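#' Subjects-by-features table with an explicit missingness mask
#'
#' The central data container of the pipeline: a numeric matrix of subjects
#' (rows) by features (columns), together with a logical mask flagging
#' missing entries.  Missing values are carried as `NA` in `values` *and*
#' flagged in `missing_mask`; they are never silently zeroed.
#'
#' @param values Numeric matrix with subject ids as row names and feature ids
#'   as column names.
#' @param missing_mask Optional logical matrix of the same dimension; defaults
#'   to `is.na(values)`.
#'
#' @return An object of class `feature_table` with elements `values` and
#'   `missing_mask`.
#' @export
feature_table <- function(values, missing_mask = NULL) {
  if (!is.matrix(values) || !is.numeric(values)) {
    stop3c("`values` must be a numeric matrix")
  }
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    stop3c("`values` must carry subject row names and feature column names")
  }
  dup_s <- unique(rownames(values)[duplicated(rownames(values))])
  if (length(dup_s)) {
    stop3c("duplicate subject id(s): ", paste(dup_s, collapse = ", "))
  }
  dup_f <- unique(colnames(values)[duplicated(colnames(values))])
  if (length(dup_f)) {
    stop3c("duplicate feature id(s): ", paste(dup_f, collapse = ", "))
  }
  if (is.null(missing_mask)) {
    missing_mask <- is.na(values)
  }
  if (!is.logical(missing_mask) || !identical(dim(missing_mask), dim(values))) {
    stop3c("`missing_mask` must be a logical matrix matching dim(values)")
  }
  if (any(is.na(values) & !missing_mask)) {
    stop3c("NA values present that are not flagged in `missing_mask`")
  }
  dimnames(missing_mask) <- dimnames(values)
  values[missing_mask] <- NA_real_
  structure(list(values = values, missing_mask = missing_mask),
            class = "feature_table")
}

#' @export
print.feature_table <- function(x, ...) {
  cat(sprintf("<feature_table> %d subjects x %d features, %d missing (%.2f%%)\n",
              nrow(x$values), ncol(x$values), sum(x$missing_mask),
              100 * mean(x$missing_mask)))
  invisible(x)
}

#' @rdname feature_table
#' @param table A `feature_table`.
#' @export
subject_ids <- function(table) rownames(table$values)

#' @rdname feature_table
#' @export
feature_ids <- function(table) colnames(table$values)

#' @rdname feature_table
#' @export
n_subjects <- function(table) nrow(table$values)

#' @rdname feature_table
#' @export
n_features <- function(table) ncol(table$values)

#' Read a delimited feature table
#'
#' The file layout is: first row feature ids, first column subject ids.
#' Empty cells and the token `NA` mark missing entries.  Any other
#' non-numeric payload is an error that names the offending cell.
#'
#' @param path Path to a delimited text file.
#' @param delimiter Field separator (default comma).
#' @return A [feature_table].
#' @export
read_feature_table <- function(path, delimiter = ",") {
  if (!file.exists(path)) stop3c("file not found: ", path)
  nf <- utils::count.fields(path, sep = delimiter, quote = "\"",
                            comment.char = "")
  if (length(unique(nf)) != 1L) {
    stop3c("ragged rows in ", path, ": lines ",
           paste(which(nf != nf[1]), collapse = ", "),
           " have a field count different from line 1")
  }
  raw <- utils::read.csv(path, sep = delimiter, header = TRUE,
                         check.names = FALSE, colClasses = "character",
                         na.strings = c("", "NA"))
  if (ncol(raw) < 2L) stop3c("expected a subject-id column plus >=1 feature")
  subj <- raw[[1L]]
  feat <- colnames(raw)[-1L]
  chr <- as.matrix(raw[, -1L, drop = FALSE])
  num <- suppressWarnings(array(as.numeric(chr), dim = dim(chr)))
  bad <- which(is.na(num) & !is.na(chr), arr.ind = TRUE)
  if (nrow(bad)) {
    b <- bad[1L, ]
    stop3c(sprintf("non-numeric value \"%s\" at subject \"%s\", feature \"%s\"",
                   chr[b[1L], b[2L]], subj[b[1L]], feat[b[2L]]))
  }
  rownames(num) <- subj
  colnames(num) <- feat
  feature_table(num)
}

#' Write a feature table to delimited text
#'
#' Missing entries are written as empty cells.  Values are formatted at full
#' double precision so that a read/write round trip is lossless.
#'
#' @param table A [feature_table].
#' @inheritParams read_feature_table
#' @export
write_feature_table <- function(table, path, delimiter = ",") {
  stopifnot(inherits(table, "feature_table"))
  v <- table$values
  chr <- ifelse(is.na(v), "", sprintf("%.17g", v))
  dim(chr) <- dim(v)
  df <- data.frame(subject_id = rownames(v), chr,
                   check.names = FALSE, stringsAsFactors = FALSE)
  colnames(df) <- c("subject_id", colnames(v))
  utils::write.table(df, path, sep = delimiter, row.names = FALSE,
                     quote = TRUE, na = "")
  invisible(path)
}

#' Per-feature category assignments
#'
#' Sorts every feature into one of three categories: the single
#' `assigned_diagnosis` score (the field-standard diagnostic scale used to
#' supervise screening), `clinical` measurements (symptom and sign scales),
#' and objective `biomarker` candidates.  Biomarkers additionally carry a
#' domain tag (`cognitive`, `structural`, `functional`).
#'
#' @param feature_id Character vector of feature ids.
#' @param category Character vector in
#'   `c("assigned_diagnosis", "clinical", "biomarker")`.
#' @param domain Character vector; must be one of `cognitive`, `structural`,
#'   `functional` for biomarkers and `NA` otherwise.
#' @return Object of class `feature_categories` (a data frame).
#' @export
feature_categories <- function(feature_id, category, domain = NA_character_) {
  feature_id <- as.character(feature_id)
  category <- as.character(category)
  domain <- rep_len(as.character(domain), length(feature_id))
  if (length(category) != length(feature_id)) {
    stop3c("`feature_id` and `category` lengths differ")
  }
  dup <- unique(feature_id[duplicated(feature_id)])
  if (length(dup)) stop3c("duplicate feature id(s) in map: ",
                          paste(dup, collapse = ", "))
  ok_cat <- c("assigned_diagnosis", "clinical", "biomarker")
  bad <- setdiff(unique(category), ok_cat)
  if (length(bad)) stop3c("unknown category: ", paste(bad, collapse = ", "))
  n_ad <- sum(category == "assigned_diagnosis")
  if (n_ad != 1L) {
    stop3c("exactly one feature must carry category assigned_diagnosis (found ",
           n_ad, ")")
  }
  ok_dom <- c("cognitive", "structural", "functional")
  is_bm <- category == "biomarker"
  if (any(is_bm & (is.na(domain) | !domain %in% ok_dom))) {
    stop3c("every biomarker needs a domain in {",
           paste(ok_dom, collapse = ", "), "}: ",
           paste(feature_id[is_bm & (is.na(domain) | !domain %in% ok_dom)],
                 collapse = ", "))
  }
  if (any(!is_bm & !is.na(domain))) {
    stop3c("domain must be absent for non-biomarker features: ",
           paste(feature_id[!is_bm & !is.na(domain)], collapse = ", "))
  }
  structure(data.frame(feature_id = feature_id, category = category,
                       domain = domain, stringsAsFactors = FALSE),
            class = c("feature_categories", "data.frame"))
}

#' Read a feature-category map from a YAML config
#'
#' The config is a flat mapping `feature_id: category` where biomarker
#' entries use `biomarker/<domain>` (e.g. `biomarker/structural`).
#'
#' @param path Path to a YAML file.
#' @return A [feature_categories] object.
#' @export
read_category_map <- function(path) {
  if (!file.exists(path)) stop3c("file not found: ", path)
  lst <- yaml::read_yaml(path)
  if (!length(lst) || is.null(names(lst))) {
    stop3c("category map must be a non-empty mapping of feature id to category")
  }
  parts <- strsplit(vapply(lst, as.character, character(1L)), "/", fixed = TRUE)
  category <- vapply(parts, `[`, character(1L), 1L)
  domain <- vapply(parts, function(p) if (length(p) > 1L) p[2L] else NA_character_,
                   character(1L))
  feature_categories(names(lst), category, domain)
}

#' Write a feature-category map as YAML
#'
#' @param categories A [feature_categories] object.
#' @param path Output path.
#' @export
write_category_map <- function(categories, path) {
  stopifnot(inherits(categories, "feature_categories"))
  val <- ifelse(is.na(categories$domain), categories$category,
                paste(categories$category, categories$domain, sep = "/"))
  lst <- as.list(val)
  names(lst) <- categories$feature_id
  yaml::write_yaml(lst, path)
  invisible(path)
}

#' Check that a category map covers a feature table exactly
#'
#' Errors (naming features) if any table feature is absent from the map or
#' any map entry is absent from the table.
#'
#' @param categories A [feature_categories].
#' @param table A [feature_table].
#' @return The categories reordered to the table's feature order, invisibly
#'   usable downstream.
#' @export
align_categories <- function(categories, table) {
  stopifnot(inherits(categories, "feature_categories"),
            inherits(table, "feature_table"))
  miss <- setdiff(feature_ids(table), categories$feature_id)
  if (length(miss)) {
    stop3c("feature(s) present in table but absent from category map: ",
           paste(miss, collapse = ", "))
  }
  extra <- setdiff(categories$feature_id, feature_ids(table))
  if (length(extra)) {
    stop3c("feature(s) present in category map but absent from table: ",
           paste(extra, collapse = ", "))
  }
  out <- categories[match(feature_ids(table), categories$feature_id), ,
                    drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("feature_categories", "data.frame")
  out
}

#' Binary external diagnosis labels
#'
#' Optional per-subject DSM-style binary diagnosis (1 = positive), kept
#' independent of the continuous assigned-diagnosis score.
#'
#' @param labels Vector coercible to 0/1, named by subject id.
#' @param subject_ids Expected subject ids (order enforced).
#' @return Named integer vector of class `diagnosis_labels`.
#' @export
diagnosis_labels <- function(labels, subject_ids = names(labels)) {
  if (is.null(subject_ids)) stop3c("labels must be named by subject id")
  lab <- as.integer(labels)
  if (length(lab) != length(subject_ids)) {
    stop3c("label length does not match subject count")
  }
  if (any(is.na(lab)) || !all(lab %in% c(0L, 1L))) {
    stop3c("labels must be binary 0/1")
  }
  names(lab) <- subject_ids
  structure(lab, class = "diagnosis_labels")
}
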