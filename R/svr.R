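#' Support-vector regression of disease-free survival time
#'
#' Epsilon-insensitive SVR with RBF kernel (via [e1071::svm()]) regressing
#' DFS months on the expression of a transcript panel. gamma and C are
#' chosen by exhaustive search over the same 16 x 16 log2 code grid used for
#' classification, minimizing training mean absolute error (ties toward the
#' smallest `c_code`, then `gamma_code`); epsilon is fixed at 0.1 months to
#' keep the search two-dimensional. The model is fitted on the training
#' cohort and evaluated on it, matching the usual presentation of such
#' survival-time fits.
#'
#' @param train a `"cohort"`.
#' @param transcripts nonempty transcript panel.
#' @param epsilon epsilon-tube half-width in months (default 0.1).
#' @return A list with `predicted` (months, per training sample), `mae`
#'   (mean absolute error in months), `pearson_r` (correlation of predicted
#'   vs observed months), and `params`.
#' @export
svr_fit_predict <- function(train, transcripts, epsilon = 0.1) {
  validate_cohort(train)
  if (length(transcripts) < 1) stop("need at least one transcript")
  y <- train$dfs_months
  if (stats::sd(y) == 0) stop("degenerate (constant) survival targets")
  X <- train$expression[, transcripts, drop = FALSE]
  best <- NULL
  for (ccode in 0:15) {
    for (gcode in 0:15) {
      fit <- e1071::svm(X, y, type = "eps-regression", kernel = "radial",
                        gamma = decode_log2_param(gcode),
                        cost = decode_log2_param(ccode),
                        epsilon = epsilon, scale = FALSE)
      mae <- mean(abs(stats::fitted(fit) - y))
      if (is.null(best) || mae < best$mae) {
        best <- list(fit = fit, mae = mae,
                     params = svm_params(gcode, ccode))
      }
    }
  }
  pred <- as.numeric(stats::fitted(best$fit))
  list(predicted = pred, mae = best$mae,
       pearson_r = stats::cor(pred, y), params = best$params)
}
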