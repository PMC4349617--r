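# vectorized pooled two-sample t-test p-values, one per expression column
expr_t_pvalues <- function(x, transcripts = x$transcript_ids) {
  g1 <- x$class_labels == "non_distant"
  g2 <- x$class_labels == "distant"
  n1 <- sum(g1); n2 <- sum(g2)
  if (n1 < 2 || n2 < 2) stop("both classes need at least 2 samples")
  E <- x$expression[, transcripts, drop = FALSE]
  m1 <- colMeans(E[g1, , drop = FALSE])
  m2 <- colMeans(E[g2, , drop = FALSE])
  v1 <- apply(E[g1, , drop = FALSE], 2, stats::var)
  v2 <- apply(E[g2, , drop = FALSE], 2, stats::var)
  sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
  tstat <- (m1 - m2) / sqrt(sp2 * (1 / n1 + 1 / n2))
  p <- 2 * stats::pt(-abs(tstat), df = n1 + n2 - 2)
  p[!is.finite(tstat)] <- 1 # constant transcripts carry no evidence
  stats::setNames(p, transcripts)
}

#' Appearance-frequency shortlist
#'
#' The top-k transcripts by appearance count across the run bests of a
#' [multi_run()] ensemble. Count ties are broken by the higher mean fitness
#' of the run-best solutions containing the transcript, then by transcript
#' id.
#'
#' @param run_ensemble a `"run_ensemble"`.
#' @param k shortlist size (default 30, the published choice). If fewer
#'   transcripts were ever selected, all of them are returned with a
#'   warning.
#' @return Ordered character vector of transcript ids.
#' @export
appearance_shortlist <- function(run_ensemble, k = 30) {
  stopifnot(inherits(run_ensemble, "run_ensemble"))
  counts <- run_ensemble$counts
  if (length(counts) == 0) stop("empty run ensemble")
  mean_f <- vapply(names(counts), function(tx) {
    fs <- vapply(run_ensemble$run_bests, function(s) {
      if (tx %in% s$transcript_ids) s$fitness$f else NA_real_
    }, numeric(1))
    mean(fs, na.rm = TRUE)
  }, numeric(1))
  ord <- order(-counts, -mean_f, names(counts))
  if (k > length(counts)) {
    warning("only ", length(counts), " transcripts were ever selected; ",
            "returning all of them")
    k <- length(counts)
  }
  names(counts)[ord][seq_len(k)]
}

#' Sequential backward selection
#'
#' Starting from `start_set`, repeatedly evaluates `f(G - x)` by grid search
#' for every member x and removes the one whose removal yields the largest
#' fitness (the smallest decrease; a removal may increase f). Ties are
#' broken by removing the transcript with the larger univariate t-test
#' p-value (least individually informative), then by id. Records the whole
#' trajectory down to a single transcript and reports both the
#' highest-fitness and the highest-survival-area sets encountered.
#'
#' @param start_set nonempty character vector of transcript ids.
#' @param x training `"cohort"`.
#' @param w fitness weight.
#' @param t_max survival-area horizon (months).
#' @param verbose print one line per removal.
#' @return A list with `trajectory` (data frame: size, removed, acc, asurv,
#'   f, gamma_code, c_code, and a `transcripts` list-column), `best_by_f`,
#'   and `best_by_asurv` (each a [selection_result()]).
#' @export
sbs <- function(start_set, x, w = 0.8, t_max = max(x$dfs_months),
                verbose = FALSE) {
  if (length(start_set) < 1) stop("empty start set")
  validate_cohort(x, require_both_classes = TRUE)
  pvals <- expr_t_pvalues(x, start_set)
  eval_set <- function(G) {
    gs <- grid_search_best(x, G, w = w, t_max = t_max)
    list(acc = gs$fitness$acc, asurv = gs$fitness$asurv, f = gs$fitness$f,
         gamma_code = gs$params$gamma_code, c_code = gs$params$c_code)
  }
  G <- start_set
  full <- eval_set(G)
  rows <- list(c(list(size = length(G), removed = NA_character_), full,
                 list(transcripts = list(G))))
  while (length(G) > 1) {
    cand <- lapply(G, function(tx) eval_set(setdiff(G, tx)))
    fs <- vapply(cand, function(z) z$f, numeric(1))
    pick <- order(-fs, -pvals[G], G)[1]
    removed <- G[pick]
    G <- setdiff(G, removed)
    if (verbose) {
      message(sprintf("sbs: size %d, removed %s, f = %.4f",
                      length(G), removed, fs[pick]))
    }
    rows[[length(rows) + 1]] <- c(
      list(size = length(G), removed = removed), cand[[pick]],
      list(transcripts = list(G)))
  }
  trajectory <- do.call(rbind, lapply(rows, function(r) {
    data.frame(size = r$size, removed = r$removed, acc = r$acc,
               asurv = r$asurv, f = r$f, gamma_code = r$gamma_code,
               c_code = r$c_code, stringsAsFactors = FALSE)
  }))
  trajectory$transcripts <- lapply(rows, function(r) r$transcripts[[1]])
  as_result <- function(i, tag) {
    r <- rows[[i]]
    selection_result(r$transcripts[[1]],
                     list(acc = r$acc, asurv = r$asurv, w = w, f = r$f),
                     r$gamma_code, r$c_code, provenance = tag)
  }
  list(trajectory = trajectory,
       best_by_f = as_result(which.max(trajectory$f), "sbs best by f"),
       best_by_asurv = as_result(which.max(trajectory$asurv),
                                 "sbs best by asurv"))
}

#' Write an SBS trajectory as TSV
#' @param traj the `trajectory` data frame from [sbs()].
#' @param path output path (columns size, removed_id, acc, asurv, f).
#' @return `path`, invisibly.
#' @export
write_sbs_trajectory <- function(traj, path) {
  utils::write.table(
    data.frame(size = traj$size, removed_id = traj$removed, acc = traj$acc,
               asurv = traj$asurv, f = traj$f),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Univariate metrics and ranks per transcript
#'
#' For each transcript: the pooled two-sample t-test p-value of its
#' expression between classes, the single-transcript LOOCV SVM accuracy
#' under an accuracy-only (w = 1) grid search, and the survival area of
#' that classifier's LOOCV-predicted groups. Three rank columns follow
#' (1 = best: highest accuracy, largest area, smallest p; ties resolved by
#' transcript id so each rank column is a permutation).
#'
#' @param x training `"cohort"`.
#' @param transcripts transcript ids to score.
#' @param t_max survival-area horizon (months).
#' @return A data frame with columns `transcript_id`, `t_p_value`,
#'   `single_gene_acc`, `single_gene_asurv`, `rank_acc`, `rank_asurv`,
#'   `rank_p`.
#' @export
univariate_rank <- function(x, transcripts, t_max = max(x$dfs_months)) {
  validate_cohort(x, require_both_classes = TRUE)
  p <- expr_t_pvalues(x, transcripts)
  acc <- numeric(length(transcripts))
  asurv <- numeric(length(transcripts))
  for (i in seq_along(transcripts)) {
    gs <- grid_search_best(x, transcripts[i], w = 1, t_max = t_max)
    acc[i] <- gs$fitness$acc
    lo <- loocv_predict(x, transcripts[i], gs$params)
    asurv[i] <- asurv_from_labels(
      x, ifelse(lo$predicted == "non_distant", "non_met", "met"),
      t_max)$signed_area_fraction
  }
  k <- length(transcripts)
  rk <- function(keys) {
    out <- integer(k)
    out[order(keys, transcripts)] <- seq_len(k)
    out
  }
  data.frame(transcript_id = transcripts, t_p_value = unname(p),
             single_gene_acc = acc, single_gene_asurv = asurv,
             rank_acc = rk(-acc), rank_asurv = rk(-asurv), rank_p = rk(p),
             stringsAsFactors = FALSE)
}

#' Pearson correlation of two rank vectors
#'
#' @param ranks_a,ranks_b equal-length integer rank vectors with nonzero
#'   variance.
#' @return The Pearson correlation coefficient.
#' @export
rank_correlation <- function(ranks_a, ranks_b) {
  if (length(ranks_a) != length(ranks_b)) stop("rank vectors differ in length")
  if (stats::sd(ranks_a) == 0 || stats::sd(ranks_b) == 0) {
    stop("zero variance in a rank vector")
  }
  stats::cor(ranks_a, ranks_b)
}

#' Category-and-significance pre-filter
#'
#' Keeps the transcripts annotated with one of the requested regulator
#' categories (transcripts absent from the annotation count as `"other"`),
#' ranks them by the pooled two-sample t-test p-value of expression between
#' classes, and truncates to the `k` smallest p-values. With
#' `categories = NULL` every category passes, leaving a pure top-k-by-p
#' filter.
#'
#' @param x a `"cohort"`.
#' @param annotation data frame as from [read_annotation()], or `NULL`
#'   (all transcripts are `"other"` and `categories` must then be `NULL`).
#' @param categories regulator categories to keep; default the five EMT
#'   categories.
#' @param k maximum number of surviving transcripts (default 474, the
#'   published candidate-set size).
#' @return A reduced `"cohort"` whose transcripts are ordered by ascending
#'   p-value; sample order is preserved.
#' @export
emt_filter <- function(x, annotation = NULL, categories = EMT_CATEGORIES,
                       k = 474) {
  validate_cohort(x, require_both_classes = TRUE)
  cat_of <- stats::setNames(rep("other", length(x$transcript_ids)),
                            x$transcript_ids)
  if (!is.null(annotation)) {
    hit <- intersect(annotation$transcript_id, names(cat_of))
    cat_of[hit] <- annotation$regulator_type[
      match(hit, annotation$transcript_id)]
  }
  keep <- if (is.null(categories)) x$transcript_ids
          else x$transcript_ids[cat_of[x$transcript_ids] %in% categories]
  if (length(keep) == 0) stop("no transcript survives the category filter")
  p <- expr_t_pvalues(x, keep)
  keep <- keep[order(p, keep)][seq_len(min(k, length(keep)))]
  cohort_subset_transcripts(x, keep)
}
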