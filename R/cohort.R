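#' Construct a cohort
#'
#' A cohort pairs a normalized log-scale expression matrix (samples x
#' transcripts) with per-sample clinical outcome: the metastasis class,
#' disease-free survival (DFS) in months, and the event/censor flag.
#'
#' @param expression numeric matrix, samples in rows, transcripts in
#'   columns. Row and column names, when present, must agree with
#'   `sample_ids` / `transcript_ids`.
#' @param class_labels per-sample class, coerced to a factor with levels
#'   `c("non_distant", "distant")`.
#' @param dfs_months per-sample disease-free survival time in months
#'   (non-negative real).
#' @param event_flags per-sample event indicator: 1 (or `"event"`) if death
#'   or distant metastasis was observed, 0 (or `"censored"`) otherwise.
#' @param sample_ids unique sample identifiers; defaults to the expression
#'   row names.
#' @param transcript_ids unique transcript identifiers; defaults to the
#'   expression column names.
#' @return An object of class `"cohort"`.
#' @export
cohort <- function(expression, class_labels, dfs_months, event_flags,
                   sample_ids = rownames(expression),
                   transcript_ids = colnames(expression)) {
  expression <- as.matrix(expression)
  if (is.null(sample_ids)) sample_ids <- paste0("S", seq_len(nrow(expression)))
  if (is.null(transcript_ids)) {
    transcript_ids <- paste0("TX", seq_len(ncol(expression)))
  }
  if (is.numeric(class_labels)) {
    class_labels <- ifelse(class_labels == 1, "distant", "non_distant")
  }
  class_labels <- factor(as.character(class_labels),
                         levels = c("non_distant", "distant"))
  if (is.character(event_flags)) {
    event_flags <- ifelse(event_flags == "event", 1L, 0L)
  }
  event_flags <- as.integer(event_flags)
  rownames(expression) <- sample_ids
  colnames(expression) <- transcript_ids
  obj <- structure(list(
    sample_ids = as.character(sample_ids),
    expression = expression,
    transcript_ids = as.character(transcript_ids),
    class_labels = class_labels,
    dfs_months = as.numeric(dfs_months),
    event_flags = event_flags
  ), class = "cohort")
  validate_cohort(obj)
  obj
}

#' Validate a cohort object
#'
#' Checks every structural invariant: matching dimensions, unique ids,
#' finite expression values, complete clinical fields, non-negative DFS
#' times, and binary event flags.
#'
#' @param x a `"cohort"` object.
#' @param require_both_classes if `TRUE`, additionally require both classes
#'   to be nonempty (needed by any training operation).
#' @return `x`, invisibly. Errors describe the first violated invariant.
#' @export
validate_cohort <- function(x, require_both_classes = FALSE) {
  stopifnot(inherits(x, "cohort"))
  n <- length(x$sample_ids)
  p <- length(x$transcript_ids)
  if (anyDuplicated(x$sample_ids)) {
    stop("duplicate sample id: ",
         x$sample_ids[duplicated(x$sample_ids)][1])
  }
  if (anyDuplicated(x$transcript_ids)) {
    stop("duplicate transcript id: ",
         x$transcript_ids[duplicated(x$transcript_ids)][1])
  }
  if (nrow(x$expression) != n) {
    stop("expression has ", nrow(x$expression), " rows for ", n, " samples")
  }
  if (ncol(x$expression) != p) {
    stop("expression has ", ncol(x$expression), " columns for ", p,
         " transcripts")
  }
  if (!all(is.finite(x$expression))) stop("non-finite expression value")
  if (length(x$class_labels) != n || anyNA(x$class_labels)) {
    stop("every sample needs a class label in {non_distant, distant}")
  }
  if (length(x$dfs_months) != n || anyNA(x$dfs_months)) {
    stop("every sample needs a dfs_months value")
  }
  if (any(x$dfs_months < 0)) stop("negative dfs_months")
  if (length(x$event_flags) != n || anyNA(x$event_flags) ||
      !all(x$event_flags %in% c(0L, 1L))) {
    stop("every sample needs an event flag in {0, 1}")
  }
  if (require_both_classes && any(table(x$class_labels) == 0)) {
    stop("both classes must be nonempty for training")
  }
  invisible(x)
}

#' @export
print.cohort <- function(x, ...) {
  tab <- table(x$class_labels)
  cat("cohort:", length(x$sample_ids), "samples x",
      length(x$transcript_ids), "transcripts\n")
  cat("  classes: non_distant =", tab[["non_distant"]],
      ", distant =", tab[["distant"]], "\n")
  cat("  events:", sum(x$event_flags), "observed,",
      sum(x$event_flags == 0), "censored; median DFS",
      round(stats::median(x$dfs_months), 1), "months\n")
  invisible(x)
}

#' Read a cohort from an expression/clinical TSV pair
#'
#' The expression file has one row per sample: a `sample_id` column followed
#' by one numeric column per transcript. The clinical file has columns
#' `sample_id`, `metastasis` (1 = distant, 0 = non_distant), `dfs_months`,
#' and `event` (1 = event, 0 = censored). Sample order follows the
#' expression file.
#'
#' @param expression_path,clinical_path paths to the two TSV files.
#' @return A validated `"cohort"`.
#' @export
read_cohort <- function(expression_path, clinical_path) {
  for (p in c(expression_path, clinical_path)) {
    if (!file.exists(p)) stop("file not found: ", p)
  }
  expr <- utils::read.delim(expression_path, check.names = FALSE,
                            stringsAsFactors = FALSE)
  clin <- utils::read.delim(clinical_path, check.names = FALSE,
                            stringsAsFactors = FALSE)
  if (names(expr)[1] != "sample_id") {
    stop("expression file must start with a sample_id column")
  }
  need <- c("sample_id", "metastasis", "dfs_months", "event")
  if (!all(need %in% names(clin))) {
    stop("clinical file must have columns: ", paste(need, collapse = ", "))
  }
  if (anyDuplicated(expr$sample_id)) {
    stop("duplicate sample id in expression file: ",
         expr$sample_id[duplicated(expr$sample_id)][1])
  }
  if (anyDuplicated(clin$sample_id)) {
    stop("duplicate sample id in clinical file: ",
         clin$sample_id[duplicated(clin$sample_id)][1])
  }
  miss_clin <- setdiff(expr$sample_id, clin$sample_id)
  if (length(miss_clin)) {
    stop("sample missing from clinical file: ", miss_clin[1])
  }
  miss_expr <- setdiff(clin$sample_id, expr$sample_id)
  if (length(miss_expr)) {
    stop("sample missing from expression file: ", miss_expr[1])
  }
  mat <- as.matrix(expr[, -1, drop = FALSE])
  if (!is.numeric(mat)) {
    bad <- which(!sapply(expr[, -1, drop = FALSE], is.numeric))[1]
    badrow <- which(is.na(suppressWarnings(as.numeric(expr[[bad + 1]]))))[1]
    stop("non-numeric expression value at row ", badrow, ", column '",
         names(expr)[bad + 1], "'")
  }
  clin <- clin[match(expr$sample_id, clin$sample_id), ]
  cohort(mat,
         class_labels = clin$metastasis,
         dfs_months = clin$dfs_months,
         event_flags = clin$event,
         sample_ids = expr$sample_id,
         transcript_ids = colnames(mat))
}

#' Write a cohort as an expression/clinical TSV pair
#'
#' @param x a `"cohort"`.
#' @param expression_path,clinical_path output TSV paths (see
#'   [read_cohort()] for the layout).
#' @return The two paths, invisibly.
#' @export
write_cohort <- function(x, expression_path, clinical_path) {
  validate_cohort(x)
  expr <- data.frame(sample_id = x$sample_ids, x$expression,
                     check.names = FALSE)
  utils::write.table(expr, expression_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  clin <- data.frame(sample_id = x$sample_ids,
                     metastasis = as.integer(x$class_labels == "distant"),
                     dfs_months = x$dfs_months,
                     event = x$event_flags)
  utils::write.table(clin, clinical_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(c(expression_path, clinical_path))
}

#' Regulator categories used by the pre-filter
#'
#' The five epithelial-mesenchymal-transition (EMT) regulator categories,
#' plus `"other"` for everything else.
#' @export
EMT_CATEGORIES <- c("growth factor", "ligand-dependent nuclear receptor",
                    "transcription regulator", "cytokine", "kinase")

#' Read a transcript annotation table
#'
#' TSV with columns `transcript_id`, `gene_symbol`, `regulator_type`; the
#' regulator type must come from the closed vocabulary of the five EMT
#' categories plus `"other"`.
#'
#' @param path TSV path.
#' @return A data frame with the three columns.
#' @export
read_annotation <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  ann <- utils::read.delim(path, check.names = FALSE,
                           stringsAsFactors = FALSE)
  need <- c("transcript_id", "gene_symbol", "regulator_type")
  if (!all(need %in% names(ann))) {
    stop("annotation file must have columns: ", paste(need, collapse = ", "))
  }
  if (anyDuplicated(ann$transcript_id)) {
    stop("duplicate transcript_id in annotation: ",
         ann$transcript_id[duplicated(ann$transcript_id)][1])
  }
  vocab <- c(EMT_CATEGORIES, "other")
  bad <- setdiff(unique(ann$regulator_type), vocab)
  if (length(bad)) stop("unknown regulator_type: ", bad[1])
  ann[, need]
}

#' Write a transcript annotation table
#' @param ann data frame with `transcript_id`, `gene_symbol`,
#'   `regulator_type`.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_annotation <- function(ann, path) {
  utils::write.table(ann, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# internal: subset helpers keeping all clinical fields aligned
cohort_subset_samples <- function(x, idx) {
  cohort(x$expression[idx, , drop = FALSE],
         class_labels = x$class_labels[idx],
         dfs_months = x$dfs_months[idx],
         event_flags = x$event_flags[idx],
         sample_ids = x$sample_ids[idx],
         transcript_ids = x$transcript_ids)
}

cohort_subset_transcripts <- function(x, ids) {
  miss <- setdiff(ids, x$transcript_ids)
  if (length(miss)) stop("transcript not in cohort: ", miss[1])
  cohort(x$expression[, ids, drop = FALSE],
         class_labels = x$class_labels,
         dfs_months = x$dfs_months,
         event_flags = x$event_flags,
         sample_ids = x$sample_ids,
         transcript_ids = ids)
}
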