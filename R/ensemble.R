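#' Random-subspace SVM ensemble over a transcript panel
#'
#' Trains `n_members` RBF-SVM classifiers, each on `member_size` transcripts
#' drawn uniformly without replacement from the panel (independently across
#' members). Each member's gamma/C pair is chosen by its own grid search on
#' the training cohort; the ensemble predicts by majority vote, with exact
#' ties broken toward `distant` (favoring sensitivity to metastasis).
#'
#' @param train training `"cohort"` (both classes present).
#' @param test test `"cohort"`; its transcripts must cover the panel.
#' @param transcripts the parent transcript panel `G`.
#' @param n_members number of ensemble members (default 30).
#' @param member_size transcripts per member (default 5); must not exceed
#'   `|G|`.
#' @param w fitness weight used by each member's grid search.
#' @param t_max survival-area horizon for the grid search (months).
#' @param seed integer seed controlling the member subsets.
#' @return A list with `predicted` (factor over test samples), `acc` (test
#'   accuracy), `votes` (members x samples 0/1 matrix), and `members`
#'   (each member's transcripts and codes).
#' @export
ensemble_train_predict <- function(train, test, transcripts, n_members = 30,
                                   member_size = 5, w = 1,
                                   t_max = max(train$dfs_months),
                                   seed = 1) {
  if (member_size > length(transcripts)) {
    stop("member_size exceeds the panel size")
  }
  validate_cohort(train, require_both_classes = TRUE)
  validate_cohort(test)
  miss <- setdiff(transcripts, test$transcript_ids)
  if (length(miss)) stop("test cohort lacks transcript: ", miss[1])
  set.seed(seed)
  ytr <- as.integer(train$class_labels == "distant")
  votes <- matrix(0L, n_members, length(test$sample_ids))
  members <- vector("list", n_members)
  for (m in seq_len(n_members)) {
    sub <- sample(transcripts, member_size)
    gs <- grid_search_best(train, sub, w = w, t_max = t_max)
    votes[m, ] <- .svc_train_predict_cpp(
      train$expression[, sub, drop = FALSE], ytr,
      gs$params$gamma, gs$params$C,
      test$expression[, sub, drop = FALSE])
    members[[m]] <- list(transcripts = sub,
                         gamma_code = gs$params$gamma_code,
                         c_code = gs$params$c_code)
  }
  pos <- colSums(votes)
  pred01 <- as.integer(pos >= n_members / 2) # tie -> distant
  predicted <- factor(ifelse(pred01 == 1, "distant", "non_distant"),
                      levels = c("non_distant", "distant"))
  yte <- as.integer(test$class_labels == "distant")
  list(predicted = predicted, acc = mean(pred01 == yte), votes = votes,
       members = members)
}

#' Single-SVM train/test evaluation of a transcript panel
#'
#' Grid-searches gamma/C on the training cohort, trains one RBF-SVM on all
#' training samples, and predicts the test cohort.
#'
#' @inheritParams ensemble_train_predict
#' @return A list with `predicted`, `acc`, and `params`.
#' @export
svm_test_predict <- function(train, test, transcripts, w = 1,
                             t_max = max(train$dfs_months)) {
  validate_cohort(train, require_both_classes = TRUE)
  gs <- grid_search_best(train, transcripts, w = w, t_max = t_max)
  pred01 <- .svc_train_predict_cpp(
    train$expression[, transcripts, drop = FALSE],
    as.integer(train$class_labels == "distant"),
    gs$params$gamma, gs$params$C,
    test$expression[, transcripts, drop = FALSE])
  predicted <- factor(ifelse(pred01 == 1, "distant", "non_distant"),
                      levels = c("non_distant", "distant"))
  list(predicted = predicted,
       acc = mean(pred01 == as.integer(test$class_labels == "distant")),
       params = gs$params)
}
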