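#' Decode a 4-bit hyperparameter code
#'
#' Both the RBF kernel width gamma and the soft-margin cost C are searched
#' over the 16-point log2 grid `2^-7, 2^-6, ..., 2^8`, encoded as integers
#' 0-15.
#'
#' @param code integer in 0..15.
#' @return `2^(code - 7)`.
#' @export
decode_log2_param <- function(code) {
  if (any(code < 0 | code > 15 | code != round(code))) {
    stop("code must be an integer in 0..15")
  }
  2^(code - 7)
}

#' SVM hyperparameter pair
#' @param gamma_code,c_code integer codes 0-15.
#' @return A list with the codes and the decoded `gamma` and `C`.
#' @export
svm_params <- function(gamma_code, c_code) {
  list(gamma_code = as.integer(gamma_code), c_code = as.integer(c_code),
       gamma = decode_log2_param(gamma_code), C = decode_log2_param(c_code))
}

# internal: 0/1 response (distant = 1) restricted to a transcript set
cohort_xy <- function(x, transcripts) {
  miss <- setdiff(transcripts, x$transcript_ids)
  if (length(miss)) stop("transcript not in cohort: ", miss[1])
  list(X = x$expression[, transcripts, drop = FALSE],
       y = as.integer(x$class_labels == "distant"))
}

#' Leave-one-out cross-validated RBF-SVM predictions
#'
#' For each sample, an RBF-kernel C-SVM (`exp(-gamma ||x_i - x_j||^2)`) is
#' trained on the remaining samples restricted to the transcript set and
#' predicts the held-out sample. A training fold reduced to one class
#' predicts that fold's majority class (with a warning); this keeps tiny
#' cohorts usable inside the optimizer.
#'
#' @param x a `"cohort"` with both classes present.
#' @param transcripts nonempty character vector of transcript ids.
#' @param params an [svm_params()] pair.
#' @return A list with `predicted` (factor with the cohort's class levels)
#'   and `acc` (fraction of correctly predicted samples).
#' @export
loocv_predict <- function(x, transcripts, params) {
  validate_cohort(x, require_both_classes = TRUE)
  if (length(transcripts) < 1) stop("need at least one transcript")
  d <- cohort_xy(x, transcripts)
  if (min(table(x$class_labels)) == 1) {
    warning("a class has a single sample: its fold is one-class and ",
            "predicts the training majority")
  }
  pred01 <- .svc_loocv_cpp(d$X, d$y, params$gamma, params$C)
  predicted <- factor(ifelse(pred01 == 1, "distant", "non_distant"),
                      levels = c("non_distant", "distant"))
  list(predicted = predicted, acc = mean(pred01 == d$y))
}

#' Weighted classification/survival fitness of a transcript set
#'
#' The selection objective `f(G) = w * Acc + (1 - w) * Asurv`, where `Acc`
#' is the LOOCV accuracy of the RBF-SVM on the transcript set and `Asurv`
#' is the normalized Kaplan-Meier area between the survival curves of the
#' LOOCV-PREDICTED groups (predicted non-distant on top). A negative signed
#' area (classifier inverts the groups) contributes 0 to `f`; the raw
#' signed value is kept in the breakdown.
#'
#' @param x a `"cohort"`.
#' @param transcripts transcript set `G`.
#' @param params an [svm_params()] pair.
#' @param w accuracy weight in `[0, 1]`; `w = 1` degenerates to
#'   accuracy-only selection.
#' @param t_max survival-area horizon in months.
#' @return A fitness breakdown: list with `acc`, `asurv` (signed), `w`,
#'   `f`, and the per-sample `predicted` factor.
#' @export
fitness_eval <- function(x, transcripts, params, w,
                         t_max = max(x$dfs_months)) {
  if (w < 0 || w > 1) stop("w must be in [0, 1]")
  lo <- loocv_predict(x, transcripts, params)
  groups01 <- ifelse(lo$predicted == "non_distant", 1L, 2L)
  asurv <- asurv_fast(x$dfs_months, x$event_flags, groups01, t_max)
  if (any(table(lo$predicted) == 0)) asurv <- 0 # empty-group convention
  list(acc = lo$acc, asurv = asurv, w = w,
       f = w * lo$acc + (1 - w) * max(asurv, 0),
       predicted = lo$predicted)
}

#' Exhaustive gamma/C grid search for one transcript set
#'
#' Evaluates the fitness on all 256 code pairs of the log2 grid and returns
#' the maximizer. Equal-fitness ties are broken toward the smallest
#' `c_code`, then the smallest `gamma_code` (prefers smoother models,
#' deterministic).
#'
#' @inheritParams fitness_eval
#' @return A list with `params` (the winning [svm_params()]), `fitness`
#'   (breakdown as in [fitness_eval()], without predictions), and `grid`
#'   (the full 256 x 5 evaluation matrix).
#' @export
grid_search_best <- function(x, transcripts, w = 1,
                             t_max = max(x$dfs_months)) {
  validate_cohort(x, require_both_classes = TRUE)
  if (length(transcripts) < 1) stop("need at least one transcript")
  if (w < 0 || w > 1) stop("w must be in [0, 1]")
  d <- cohort_xy(x, transcripts)
  grid <- .svc_grid_cpp(d$X, d$y, x$dfs_months, as.integer(x$event_flags),
                        w, t_max)
  best <- order(-grid[, "f"], grid[, "c_code"], grid[, "gamma_code"])[1]
  list(params = svm_params(grid[[best, "gamma_code"]],
                           grid[[best, "c_code"]]),
       fitness = list(acc = grid[[best, "acc"]],
                      asurv = grid[[best, "asurv"]],
                      w = w, f = grid[[best, "f"]]),
       grid = grid)
}
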