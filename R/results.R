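#' Construct a selection result
#'
#' Records one selected transcript panel together with its fitness breakdown
#' and the SVM hyperparameter codes that produced it.
#'
#' @param transcript_ids nonempty character vector of selected transcripts.
#' @param fitness a fitness breakdown as returned by [fitness_eval()] (a
#'   list with `acc`, `asurv`, `w`, `f`).
#' @param gamma_code,c_code integer codes 0-15 (see [decode_log2_param()]).
#' @param provenance free-text provenance (run seed, stage r, method tag).
#' @return An object of class `"selection_result"`.
#' @export
selection_result <- function(transcript_ids, fitness, gamma_code, c_code,
                             provenance = "") {
  if (length(transcript_ids) == 0) {
    stop("selection result needs a nonempty transcript list")
  }
  if (gamma_code < 0 || gamma_code > 15 || c_code < 0 || c_code > 15) {
    stop("hyperparameter codes must be integers in 0..15")
  }
  structure(list(
    transcript_ids = as.character(transcript_ids),
    fitness = fitness[c("acc", "asurv", "w", "f")],
    gamma_code = as.integer(gamma_code),
    c_code = as.integer(c_code),
    provenance = as.character(provenance)
  ), class = "selection_result")
}

#' @export
print.selection_result <- function(x, ...) {
  cat("selection_result:", length(x$transcript_ids), "transcripts",
      sprintf("(f = %.4f, acc = %.4f, asurv = %.4f, w = %.2f)",
              x$fitness$f, x$fitness$acc, x$fitness$asurv, x$fitness$w),
      "\n")
  invisible(x)
}

#' Write / read a selection result as JSON
#'
#' Lossless round trip of all fields.
#'
#' @param result a `"selection_result"`.
#' @param path JSON path.
#' @return `write_result` returns `path` invisibly; `read_result` returns
#'   the reconstructed `"selection_result"`.
#' @export
write_result <- function(result, path) {
  stopifnot(inherits(result, "selection_result"))
  jsonlite::write_json(unclass(result), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_result
#' @export
read_result <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  x <- tryCatch(jsonlite::read_json(path, simplifyVector = TRUE),
                error = function(e) stop("malformed result file: ",
                                         conditionMessage(e)))
  need <- c("transcript_ids", "fitness", "gamma_code", "c_code")
  if (!all(need %in% names(x))) stop("malformed result file: missing fields")
  selection_result(x$transcript_ids, as.list(x$fitness), x$gamma_code,
                   x$c_code, if (is.null(x$provenance)) "" else x$provenance)
}
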