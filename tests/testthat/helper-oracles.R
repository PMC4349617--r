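# Shared fixtures and independent oracles.

# small two-class cohort with a controllable number of informative features
toy_cohort <- function(n_per_class = 10, p = 4, n_informative = 2,
                       effect = 2, seed = 1, mu_nm = 80, mu_m = 15) {
  set.seed(seed)
  n <- 2 * n_per_class
  cls <- rep(c("non_distant", "distant"), each = n_per_class)
  E <- matrix(rnorm(n * p), n, p)
  if (n_informative > 0) {
    E[cls == "distant", seq_len(n_informative)] <-
      E[cls == "distant", seq_len(n_informative)] + effect
  }
  dfs <- ifelse(cls == "distant", pmin(rexp(n, 1 / mu_m), 120),
                pmin(rexp(n, 1 / mu_nm), runif(n, 60, 120)))
  ev <- ifelse(cls == "distant", 1L, rbinom(n, 1, 0.3))
  cohort(E, class_labels = cls, dfs_months = dfs, event_flags = ev,
         sample_ids = sprintf("S%03d", 1:n),
         transcript_ids = sprintf("TX%04d", 1:p))
}

# hand product-limit estimator: events before censorings at tied times
km_oracle <- function(times, events) {
  ord <- order(times)
  times <- times[ord]; events <- events[ord]
  ut <- unique(times)
  surv <- 1
  bp <- numeric(0); pr <- numeric(0)
  at_risk <- length(times)
  for (t in ut) {
    d <- sum(times == t & events == 1)
    m <- sum(times == t)
    if (d > 0) {
      surv <- surv * (1 - d / at_risk)
      bp <- c(bp, t); pr <- c(pr, surv)
    }
    at_risk <- at_risk - m
  }
  list(breakpoints = bp, probabilities = pr)
}

# independent step evaluator (right-continuous, S(0) = 1)
step_eval <- function(bp, pr, t) {
  vapply(t, function(ti) {
    i <- sum(bp <= ti)
    if (i == 0) 1 else pr[i]
  }, numeric(1))
}

# left-endpoint Riemann sum on a grid containing every breakpoint: exact
# for right-continuous step functions
riemann_area <- function(curve_a, curve_b, t_max, fill = 1000) {
  grid <- sort(unique(c(seq(0, t_max, length.out = fill + 1),
                        curve_a$breakpoints[curve_a$breakpoints < t_max],
                        curve_b$breakpoints[curve_b$breakpoints < t_max])))
  w <- diff(grid)
  va <- step_eval(curve_a$breakpoints, curve_a$probabilities, grid[-length(grid)])
  vb <- step_eval(curve_b$breakpoints, curve_b$probabilities, grid[-length(grid)])
  sum(w * (va - vb)) / t_max
}

# random valid km_curve
random_km_curve <- function(max_t = 120) {
  k <- sample(1:8, 1)
  structure(list(breakpoints = sort(runif(k, 0, max_t)),
                 probabilities = sort(runif(k), decreasing = TRUE)),
            class = "km_curve")
}

# e1071-based LOOCV oracle (independent of the compiled path)
e1071_loocv <- function(X, y01, gamma, C) {
  n <- nrow(X)
  out <- integer(n)
  for (i in seq_len(n)) {
    m <- e1071::svm(X[-i, , drop = FALSE],
                    factor(y01[-i], levels = c(0, 1)),
                    kernel = "radial", gamma = gamma, cost = C,
                    scale = FALSE)
    out[i] <- as.integer(as.character(predict(m, X[i, , drop = FALSE])))
  }
  out
}

# synthetic run_ensemble built from explicit solutions (for shortlist tests)
fake_run_ensemble <- function(solutions_f) {
  # solutions_f: list of list(transcripts=..., f=...)
  run_bests <- lapply(seq_along(solutions_f), function(i) {
    s <- solutions_f[[i]]
    selection_result(s$transcripts,
                     list(acc = s$f, asurv = 0, w = 1, f = s$f), 7, 7,
                     provenance = paste("fake run", i))
  })
  all_tx <- unlist(lapply(run_bests, function(s) s$transcript_ids))
  counts <- sort(table(all_tx), decreasing = TRUE)
  structure(list(run_bests = run_bests,
                 counts = stats::setNames(as.integer(counts), names(counts)),
                 S_a = run_bests[[1]], S_b = run_bests[[1]],
                 scores = rep(1, length(run_bests)),
                 config = ga_config(r_start = 1, r_end = 1, runs = length(run_bests))),
            class = "run_ensemble")
}
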