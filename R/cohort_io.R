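#' Construct a validated feature table
#'
#' A feature table is the canonical container of the pipeline: a dense numeric
#' subjects-by-features matrix, unique subject identifiers, unique ordered
#' feature names, and (optionally) per-subject class labels coded +1 for the
#' positive group and -1 for the control group. Unlabeled tables are allowed
#' and represent external cohorts scored by an already-trained ensemble.
#'
#' @param values numeric matrix, subjects in rows, features in columns.
#' @param subject_ids character vector of unique subject identifiers.
#' @param feature_names character vector of unique feature names; defaults to
#'   the column names of `values`.
#' @param labels optional integer vector in `{+1, -1}`, one per subject.
#' @return An object of class `feature_table` with elements `values`,
#'   `subject_ids`, `feature_names`, `labels` (or `NULL`).
#' @export
feature_table <- function(values, subject_ids, feature_names = colnames(values),
                          labels = NULL) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (nrow(values) == 0L || ncol(values) == 0L) stopf("empty feature table")
  if (anyNA(values) || any(!is.finite(values))) {
    bad <- which(!is.finite(values), arr.ind = TRUE)[1, ]
    stopf("missing/non-finite feature value at subject '%s', feature '%s'",
          subject_ids[bad[1]], (feature_names %||% as.character(bad[2]))[bad[2]])
  }
  subject_ids <- as.character(subject_ids)
  if (length(subject_ids) != nrow(values)) stopf("subject id count != row count")
  dup <- subject_ids[duplicated(subject_ids)]
  if (length(dup)) stopf("duplicated subject id(s): %s", paste(unique(dup), collapse = ", "))
  if (is.null(feature_names)) feature_names <- paste0("feature_", seq_len(ncol(values)))
  feature_names <- as.character(feature_names)
  if (length(feature_names) != ncol(values)) stopf("feature name count != column count")
  if (anyDuplicated(feature_names)) {
    stopf("duplicated feature name(s): %s",
          paste(unique(feature_names[duplicated(feature_names)]), collapse = ", "))
  }
  if (!is.null(labels)) {
    labels <- as.integer(labels)
    if (length(labels) != nrow(values)) stopf("label count != row count")
    if (!all(labels %in% c(-1L, 1L))) stopf("labels must be +1 or -1")
    if (sum(labels == 1L) < 2L || sum(labels == -1L) < 2L) {
      stopf("need at least 2 subjects per class (got %d positive, %d negative)",
            sum(labels == 1L), sum(labels == -1L))
    }
  }
  dimnames(values) <- list(subject_ids, feature_names)
  structure(list(values = values, subject_ids = subject_ids,
                 feature_names = feature_names, labels = labels),
            class = "feature_table")
}

#' @export
print.feature_table <- function(x, ...) {
  cat(sprintf("feature_table: %d subjects x %d features\n",
              nrow(x$values), ncol(x$values)))
  if (is.null(x$labels)) {
    cat("  unlabeled (external cohort)\n")
  } else {
    cat(sprintf("  labels: %d positive (+1), %d negative (-1)\n",
                sum(x$labels == 1L), sum(x$labels == -1L)))
  }
  invisible(x)
}

# Fixed label dictionary; mapping is idempotent (already-mapped values map to
# themselves).
.label_map <- c("PO" = 1L, "1" = 1L, "+1" = 1L, "HC" = -1L, "-1" = -1L, "0" = -1L)

map_labels <- function(tokens) {
  tokens <- trimws(as.character(tokens))
  out <- .label_map[tokens]
  if (anyNA(out)) {
    stopf("unknown label token(s): %s",
          paste(unique(tokens[is.na(out)]), collapse = ", "))
  }
  unname(out)
}

detect_delimiter <- function(path) {
  first <- readLines(path, n = 1L, warn = FALSE)
  if (length(first) == 0L) stopf("empty file: %s", path)
  if (lengths(regmatches(first, gregexpr("\t", first))) >=
      lengths(regmatches(first, gregexpr(",", first)))) "\t" else ","
}

resolve_delimiter <- function(delimiter, path) {
  switch(match.arg(delimiter, c("auto", "comma", "tab")),
         auto = detect_delimiter(path), comma = ",", tab = "\t")
}

#' Read a feature table from delimited text
#'
#' Expects a header row, one row per subject, a subject-id column, numeric
#' feature columns, and optionally a label column whose tokens are mapped by
#' the fixed dictionary `PO/1/+1 -> +1`, `HC/-1/0 -> -1`.
#'
#' @param path path to a CSV/TSV file.
#' @param label_column name of the label column, or `NULL` for an unlabeled
#'   external cohort.
#' @param id_column name of the subject-id column (default `"subject_id"`;
#'   if absent, row numbers are used with a warning).
#' @param delimiter `"auto"` (default), `"comma"` or `"tab"`.
#' @return A [feature_table()].
#' @export
read_feature_table <- function(path, label_column = NULL,
                               id_column = "subject_id",
                               delimiter = c("auto", "comma", "tab")) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  sep <- resolve_delimiter(delimiter, path)
  df <- utils::read.table(path, header = TRUE, sep = sep, stringsAsFactors = FALSE,
                          check.names = FALSE, colClasses = NA, comment.char = "",
                          quote = "\"")
  if (nrow(df) == 0L) stopf("empty table: %s", path)
  if (id_column %in% names(df)) {
    ids <- as.character(df[[id_column]])
    df[[id_column]] <- NULL
  } else {
    warnf("id column '%s' not found; using row numbers", id_column)
    ids <- as.character(seq_len(nrow(df)))
  }
  labels <- NULL
  if (!is.null(label_column)) {
    if (!label_column %in% names(df)) stopf("label column '%s' not found", label_column)
    labels <- map_labels(df[[label_column]])
    df[[label_column]] <- NULL
  }
  non_num <- names(df)[!vapply(df, is.numeric, logical(1))]
  if (length(non_num)) {
    stopf("non-numeric feature column(s): %s", paste(non_num, collapse = ", "))
  }
  ft <- feature_table(as.matrix(df), ids, names(df), labels)
  unknown <- setdiff(ft$feature_names, canonical_feature_names())
  if (length(unknown) && length(unknown) < length(ft$feature_names)) {
    warnf("%d feature name(s) outside the canonical 72-name vocabulary", length(unknown))
  }
  ft
}

#' Write a feature table to delimited text
#'
#' Values are written at full precision (`%.17g`) so write-then-read
#' round-trips bit-identically.
#'
#' @param ft a [feature_table()].
#' @param path output path.
#' @param delimiter `"comma"` (default) or `"tab"`.
#' @export
write_feature_table <- function(ft, path, delimiter = c("comma", "tab")) {
  sep <- switch(match.arg(delimiter), comma = ",", tab = "\t")
  df <- data.frame(subject_id = ft$subject_ids, check.names = FALSE,
                   stringsAsFactors = FALSE)
  if (!is.null(ft$labels)) df$group <- ifelse(ft$labels == 1L, "PO", "HC")
  vals <- apply(ft$values, 2, function(col) sprintf("%.17g", col))
  if (is.null(dim(vals))) vals <- matrix(vals, nrow = nrow(ft$values))
  colnames(vals) <- ft$feature_names
  df <- cbind(df, as.data.frame(vals, stringsAsFactors = FALSE))
  utils::write.table(df, path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Construct a covariate table
#'
#' Named numeric covariate columns (age, education, forensic instrument
#' scores, ...) keyed by subject id. Missing values are tolerated and counted
#' per column; covariates feed only the post-hoc regression stage, never the
#' classifier.
#'
#' @param data data.frame of numeric columns.
#' @param subject_ids character vector, one id per row.
#' @return An object of class `covariate_table` with elements `data`,
#'   `subject_ids`, `n_missing` (named per-column missing counts).
#' @export
covariate_table <- function(data, subject_ids) {
  data <- as.data.frame(data)
  subject_ids <- as.character(subject_ids)
  if (length(subject_ids) != nrow(data)) stopf("subject id count != row count")
  if (anyDuplicated(subject_ids)) stopf("duplicated subject ids in covariates")
  non_num <- names(data)[!vapply(data, is.numeric, logical(1))]
  if (length(non_num)) stopf("non-numeric covariate column(s): %s",
                             paste(non_num, collapse = ", "))
  rownames(data) <- subject_ids
  structure(list(data = data, subject_ids = subject_ids,
                 n_missing = vapply(data, function(x) sum(is.na(x)), integer(1))),
            class = "covariate_table")
}

#' Read a covariate table from delimited text
#'
#' @inheritParams read_feature_table
#' @return A [covariate_table()].
#' @export
read_covariate_table <- function(path, id_column = "subject_id",
                                 delimiter = c("auto", "comma", "tab")) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  sep <- resolve_delimiter(delimiter, path)
  df <- utils::read.table(path, header = TRUE, sep = sep, stringsAsFactors = FALSE,
                          check.names = FALSE, comment.char = "", quote = "\"")
  if (!id_column %in% names(df)) stopf("id column '%s' not found", id_column)
  ids <- as.character(df[[id_column]])
  df[[id_column]] <- NULL
  covariate_table(df, ids)
}

#' Row-align a covariate table to a feature table
#'
#' Subjects present in the feature table but absent from the covariate table
#' are excluded from the joined view (they remain in the feature table for
#' classification); the count of exclusions is reported. Covariate-only ids
#' are dropped with a warning.
#'
#' @param ft a [feature_table()].
#' @param cov a [covariate_table()].
#' @return A list with `subject_ids` (the intersection, in feature-table
#'   order), `covariates` (row-aligned data.frame), `labels` (aligned labels
#'   or `NULL`) and `n_dropped` (feature-table subjects without covariates).
#' @export
align_covariates <- function(ft, cov) {
  stopifnot(inherits(ft, "feature_table"), inherits(cov, "covariate_table"))
  keep <- ft$subject_ids[ft$subject_ids %in% cov$subject_ids]
  if (length(keep) == 0L) stopf("no overlapping subject ids between features and covariates")
  extra <- setdiff(cov$subject_ids, ft$subject_ids)
  if (length(extra)) {
    warnf("%d covariate id(s) not present in the feature table; dropped", length(extra))
  }
  list(subject_ids = keep,
       covariates = cov$data[keep, , drop = FALSE],
       labels = if (!is.null(ft$labels)) ft$labels[match(keep, ft$subject_ids)],
       n_dropped = length(ft$subject_ids) - length(keep))
}

#' Canonical 72-feature white-matter vocabulary
#'
#' The study-standard feature set: 17 regions of interest (5 anterior
#' cingulate subregions per hemisphere, left/right amygdala, 5 corpus-callosum
#' segments) times the 4 DTI scalars FA/MD/RD/AD, plus 4 structural
#' connectivity features (amygdala-prefrontal fiber counts, both directions
#' and hemispheres). Non-canonical names are accepted by the pipeline with a
#' warning so it stays generic. The same vocabulary ships as a manifest in
#' `system.file("extdata", "feature_manifest.csv", package = "dtipattern")`.
#'
#' @return Character vector of length 72.
#' @export
canonical_feature_names <- function() {
  acc <- c("cACC", "dACC", "rACC", "sgACC", "pgACC")
  rois <- c(paste0(rep(acc, each = 2), "_", c("left", "right")),
            "amygdala_left", "amygdala_right",
            paste0("CC", 1:5))
  c(paste0(rep(c("FA", "MD", "RD", "AD"), each = length(rois)), "_", rois),
    "SC_amygdala_to_PFC_left", "SC_PFC_to_amygdala_left",
    "SC_amygdala_to_PFC_right", "SC_PFC_to_amygdala_right")
}
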