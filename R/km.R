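#' Kaplan-Meier product-limit estimate
#'
#' Right-continuous step estimate of the survival function under right
#' censoring, with the standard tie convention (events processed before
#' censorings at equal times; censor-only times create no drop). Backed by
#' [survival::survfit()].
#'
#' @param times per-subject follow-up times in months (non-negative).
#' @param events per-subject event indicator (1 = event, 0 = censored), or
#'   a character vector with values `"event"` / `"censored"`.
#' @return An object of class `"km_curve"` with `breakpoints` (strictly
#'   increasing times at which the curve drops) and `probabilities` (the
#'   survival probability after each breakpoint); `S(0) = 1` is implicit.
#' @export
km_estimate <- function(times, events) {
  if (length(times) == 0) stop("empty input")
  if (any(times < 0)) stop("negative time")
  if (is.character(events)) events <- as.integer(events == "event")
  events <- as.integer(events)
  stopifnot(length(events) == length(times), all(events %in% 0:1))
  fit <- survival::survfit(survival::Surv(times, events) ~ 1)
  drop <- fit$n.event > 0
  structure(list(breakpoints = fit$time[drop],
                 probabilities = fit$surv[drop]),
            class = "km_curve")
}

#' Evaluate a Kaplan-Meier curve
#'
#' Step evaluation: constant between breakpoints, right-continuous, constant
#' extrapolation beyond the last breakpoint.
#'
#' @param curve a `"km_curve"`.
#' @param t numeric vector of times.
#' @return Survival probabilities at `t`.
#' @export
km_survival <- function(curve, t) {
  stopifnot(inherits(curve, "km_curve"))
  vapply(t, function(ti) {
    i <- findInterval(ti, curve$breakpoints)
    if (i == 0) 1 else curve$probabilities[i]
  }, numeric(1))
}

#' @export
print.km_curve <- function(x, ...) {
  cat("km_curve with", length(x$breakpoints), "drops; final S =",
      if (length(x$probabilities)) round(min(x$probabilities), 4) else 1,
      "\n")
  invisible(x)
}

#' Export a Kaplan-Meier curve as a two-column TSV
#' @param curve a `"km_curve"`.
#' @param path output path; columns `time`, `survival` (the point `(0, 1)`
#'   is included).
#' @return `path`, invisibly.
#' @export
write_km_curve <- function(curve, path) {
  stopifnot(inherits(curve, "km_curve"))
  utils::write.table(
    data.frame(time = c(0, curve$breakpoints),
               survival = c(1, curve$probabilities)),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Normalized signed area between two survival curves
#'
#' Exact step-function integration of `S_a(t) - S_b(t)` over `[0, t_max]`,
#' divided by `t_max`, so the result lies in `[-1, 1]`. This is the
#' disease-free survival area statistic: the fraction of the maximum
#' possible area separating the two groups' Kaplan-Meier curves.
#'
#' @param curve_a,curve_b `"km_curve"` objects (group a is conventionally
#'   the non-metastasis group, so a positive value means group a survives
#'   longer).
#' @param t_max upper integration limit in months (positive); typically the
#'   maximum observed disease-free survival time.
#' @return A list with `signed_area_fraction` and `t_max`.
#' @export
area_between_curves <- function(curve_a, curve_b, t_max) {
  stopifnot(inherits(curve_a, "km_curve"), inherits(curve_b, "km_curve"))
  if (t_max <= 0) stop("t_max must be positive")
  brk <- sort(unique(c(0, curve_a$breakpoints[curve_a$breakpoints < t_max],
                       curve_b$breakpoints[curve_b$breakpoints < t_max],
                       t_max)))
  widths <- diff(brk)
  lefts <- brk[-length(brk)]
  vals <- km_survival(curve_a, lefts) - km_survival(curve_b, lefts)
  list(signed_area_fraction = sum(widths * vals) / t_max, t_max = t_max)
}

#' Disease-free survival area of a two-group split of a cohort
#'
#' Builds one Kaplan-Meier curve per group (the non-metastasis group as
#' curve a) and returns the normalized signed area between them. The signed
#' convention keeps the diagnostic information when a candidate classifier
#' inverts the groups; the fitness function clamps negatives to zero.
#'
#' @param x a `"cohort"`.
#' @param groups per-sample group membership: values `"non_met"` / `"met"`
#'   (factor or character).
#' @param t_max integration horizon in months; defaults to the maximum
#'   observed DFS time in the cohort.
#' @return A list with `signed_area_fraction`, `t_max`, and `group_sizes`
#'   (named pair; if either group is empty the area is 0 by convention and
#'   the zero size flags it).
#' @export
asurv_from_labels <- function(x, groups, t_max = max(x$dfs_months)) {
  validate_cohort(x)
  groups <- as.character(groups)
  stopifnot(length(groups) == length(x$sample_ids),
            all(groups %in% c("non_met", "met")))
  if (t_max <= 0) stop("t_max must be positive")
  sizes <- c(non_met = sum(groups == "non_met"), met = sum(groups == "met"))
  if (any(sizes == 0)) {
    return(list(signed_area_fraction = 0, t_max = t_max,
                group_sizes = sizes))
  }
  a <- km_estimate(x$dfs_months[groups == "non_met"],
                   x$event_flags[groups == "non_met"])
  b <- km_estimate(x$dfs_months[groups == "met"],
                   x$event_flags[groups == "met"])
  res <- area_between_curves(a, b, t_max)
  list(signed_area_fraction = res$signed_area_fraction, t_max = t_max,
       group_sizes = sizes)
}

# internal: compiled fast path used inside the GA fitness (identical result,
# cross-checked against asurv_from_labels in the tests)
asurv_fast <- function(dfs, events, groups01, t_max) {
  .asurv_cpp(dfs, as.integer(events), as.integer(groups01), t_max)
}

#' Two-sample t-test on disease-free survival between classes
#'
#' Compares DFS months between the non-distant and distant classes.
#'
#' @param x a `"cohort"` with at least two samples per class.
#' @param var_equal pooled-variance Student test when `TRUE` (default);
#'   Welch when `FALSE`. Both are exposed because published summaries often
#'   leave the variant unstated.
#' @return A list with `statistic`, `p_value`, and `means` (named by class,
#'   months).
#' @export
dfs_t_test <- function(x, var_equal = TRUE) {
  validate_cohort(x, require_both_classes = TRUE)
  g1 <- x$dfs_months[x$class_labels == "non_distant"]
  g2 <- x$dfs_months[x$class_labels == "distant"]
  if (length(g1) < 2 || length(g2) < 2) {
    stop("both classes need at least 2 samples")
  }
  tt <- stats::t.test(g1, g2, var.equal = var_equal)
  list(statistic = unname(tt$statistic), p_value = tt$p.value,
       means = c(non_distant = mean(g1), distant = mean(g2)))
}
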