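#' Cross-validated weight sweep
#'
#' Estimates held-out accuracy for several fitness weights. Samples are
#' split into `folds` stratified groups (class proportions preserved); each
#' group serves as the test set once while the selection pipeline
#' ([multi_run()] followed by taking the highest-fitness solution) runs on
#' the remaining groups, and the selected panel's grid-best SVM predicts
#' the held-out group. If a split leaves a training part without both
#' classes it is redrawn a bounded number of times.
#'
#' @param x a `"cohort"`.
#' @param weights fitness weights to compare (default `c(1, 0.8, 0.5,
#'   0.2)`).
#' @param folds number of groups (default 5).
#' @param config a [ga_config()] giving the selection budget; its `w` and
#'   `seed` fields are overridden per weight/fold.
#' @param seed integer seed for the fold assignment and the per-fold runs.
#' @param max_retries redraws allowed for degenerate splits.
#' @return A data frame with one row per weight: `w`, `mean_test_acc`, and
#'   `fold_acc` (list-column of per-fold accuracies).
#' @export
weight_sweep <- function(x, weights = c(1, 0.8, 0.5, 0.2), folds = 5,
                         config = ga_config(), seed = 1, max_retries = 20) {
  validate_cohort(x, require_both_classes = TRUE)
  set.seed(seed)
  n <- length(x$sample_ids)
  assign_folds <- function() {
    fold <- integer(n)
    for (cl in levels(x$class_labels)) {
      idx <- which(x$class_labels == cl)
      fold[idx] <- sample(rep_len(seq_len(folds), length(idx)))
    }
    fold
  }
  ok <- function(fold) {
    all(vapply(seq_len(folds), function(k) {
      length(unique(x$class_labels[fold != k])) == 2 && sum(fold == k) > 0
    }, logical(1)))
  }
  fold <- assign_folds()
  tries <- 0
  while (!ok(fold)) {
    tries <- tries + 1
    if (tries > max_retries) stop("could not form folds with both classes")
    fold <- assign_folds()
  }
  rows <- lapply(weights, function(w) {
    accs <- vapply(seq_len(folds), function(k) {
      train <- cohort_subset_samples(x, which(fold != k))
      test <- cohort_subset_samples(x, which(fold == k))
      cfg <- config
      cfg$w <- w
      cfg$seed <- seed + 1000 * k
      ens <- multi_run(train, cfg)
      svm_test_predict(train, test, ens$S_a$transcript_ids, w = w,
                       t_max = if (is.null(cfg$t_max)) max(train$dfs_months)
                               else cfg$t_max)$acc
    }, numeric(1))
    list(w = w, mean_test_acc = mean(accs), fold_acc = accs)
  })
  out <- data.frame(w = vapply(rows, `[[`, numeric(1), "w"),
                    mean_test_acc = vapply(rows, `[[`, numeric(1),
                                           "mean_test_acc"))
  out$fold_acc <- lapply(rows, `[[`, "fold_acc")
  out
}

#' Write a run manifest
#'
#' Records what produced a set of outputs: command name, resolved
#' configuration, master seed, package version, input file digests, and
#' timing. Every CLI command writes one next to its outputs.
#'
#' @param path output JSON path.
#' @param command command name.
#' @param config named list of resolved settings.
#' @param seed master seed.
#' @param inputs character vector of input file paths (digested with MD5).
#' @param started POSIXct start time (defaults to now).
#' @return `path`, invisibly.
#' @export
write_manifest <- function(path, command, config, seed, inputs = character(),
                           started = Sys.time()) {
  digests <- if (length(inputs)) {
    as.list(stats::setNames(unname(tools::md5sum(inputs)), inputs))
  } else list()
  manifest <- list(
    command = command,
    config = config,
    seed = seed,
    tool_version = as.character(utils::packageVersion("survsel")),
    input_digests = digests,
    started = format(started, "%Y-%m-%dT%H:%M:%S%z"),
    elapsed_sec = as.numeric(difftime(Sys.time(), started, units = "secs")))
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
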