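test_that("km_estimate matches the hand product-limit", {
  # uncensored: empirical survival function
  c1 <- km_estimate(c(5, 10), c(1, 1))
  expect_equal(km_survival(c1, c(0, 4.99, 5, 9.99, 10, 50)),
               c(1, 1, 0.5, 0.5, 0, 0))

  # all censored: flat at 1
  c2 <- km_estimate(c(3, 8, 20), c(0, 0, 0))
  expect_length(c2$breakpoints, 0)
  expect_equal(km_survival(c2, c(0, 10, 100)), c(1, 1, 1))

  # tied event and censoring at t = 4: the event factor counts the
  # censored subject as still at risk (events before censorings), so
  # S = 3/4 on [2,4) and (3/4)*(2/3) = 1/2 on [4,6)
  c3 <- km_estimate(c(2, 4, 4, 6), c(1, 0, 1, 0))
  expect_equal(km_survival(c3, c(1, 2, 3.9, 4, 5.9, 6, 10)),
               c(1, 0.75, 0.75, 0.5, 0.5, 0.5, 0.5))

  # random cohorts against the independent oracle
  set.seed(21)
  for (i in 1:25) {
    n <- sample(3:40, 1)
    tm <- round(rexp(n, 1 / 30), 1) # rounding forces ties
    ev <- rbinom(n, 1, 0.6)
    fit <- km_estimate(tm, ev)
    orc <- km_oracle(tm, ev)
    expect_equal(fit$breakpoints, orc$breakpoints)
    expect_equal(fit$probabilities, orc$probabilities)
  }

  expect_error(km_estimate(numeric(0), integer(0)), "empty")
  expect_error(km_estimate(c(-1, 2), c(1, 1)), "negative")
})

test_that("km_estimate with no censoring equals the empirical survival", {
  set.seed(4)
  tm <- rexp(30, 1 / 20)
  fit <- km_estimate(tm, rep(1, 30))
  at <- sort(tm)
  expect_equal(km_survival(fit, at), 1 - seq_along(at) / 30)
})

test_that("area_between_curves does exact step integration", {
  flat1 <- structure(list(breakpoints = numeric(0),
                          probabilities = numeric(0)), class = "km_curve")
  flat0 <- structure(list(breakpoints = 0.0001, probabilities = 0),
                     class = "km_curve")
  drop50 <- structure(list(breakpoints = 50, probabilities = 0.5),
                      class = "km_curve")

  expect_equal(area_between_curves(drop50, drop50, 100)$signed_area_fraction,
               0)
  expect_equal(area_between_curves(flat1, flat0, 80)$signed_area_fraction,
               1, tolerance = 1e-5)
  # (50 * 1 + 50 * 0.5) / 100
  expect_equal(area_between_curves(drop50, flat0, 100)$signed_area_fraction,
               0.75, tolerance = 1e-5)
  expect_error(area_between_curves(flat1, flat0, 0), "positive")
})

test_that("area matches the breakpoint-aware Riemann oracle on random curves", {
  set.seed(33)
  for (i in 1:100) {
    a <- random_km_curve(); b <- random_km_curve()
    t_max <- runif(1, 50, 150)
    got <- area_between_curves(a, b, t_max)$signed_area_fraction
    expect_equal(got, riemann_area(a, b, t_max), tolerance = 1e-9)
    expect_lte(abs(got), 1)
  }
})

test_that("asurv is antisymmetric, flags empty groups, and the compiled and survfit paths agree", {
  x <- toy_cohort(n_per_class = 15, seed = 9)
  g <- ifelse(x$class_labels == "non_distant", "non_met", "met")
  t_max <- max(x$dfs_months)
  a1 <- asurv_from_labels(x, g, t_max)
  a2 <- asurv_from_labels(x, ifelse(g == "met", "non_met", "met"), t_max)
  expect_equal(a1$signed_area_fraction, -a2$signed_area_fraction)
  expect_gt(a1$signed_area_fraction, 0) # non-distant curve on top

  all_one <- asurv_from_labels(x, rep("met", 30), t_max)
  expect_equal(all_one$signed_area_fraction, 0)
  expect_equal(unname(all_one$group_sizes["non_met"]), 0L)

  set.seed(14)
  for (i in 1:20) {
    gg <- sample(c("non_met", "met"), 30, replace = TRUE)
    if (length(unique(gg)) < 2) next
    r_path <- asurv_from_labels(x, gg, t_max)$signed_area_fraction
    c_path <- survsel:::asurv_fast(x$dfs_months, x$event_flags,
                                   ifelse(gg == "non_met", 1L, 2L), t_max)
    expect_equal(r_path, c_path, tolerance = 1e-12)
  }
})

test_that("asurv below t_max ignores the exact disposition of later samples", {
  x <- toy_cohort(n_per_class = 12, seed = 17)
  t_max <- 60
  g <- ifelse(x$class_labels == "non_distant", "non_met", "met")
  base <- asurv_from_labels(x, g, t_max)$signed_area_fraction
  # administratively censor everything beyond the horizon
  y <- x
  late <- y$dfs_months > t_max
  y$dfs_months[late] <- t_max
  y$event_flags[late] <- 0L
  expect_equal(asurv_from_labels(y, g, t_max)$signed_area_fraction, base)
})

test_that("dfs_t_test separates the synthetic survival distributions", {
  x <- toy_cohort(n_per_class = 4, seed = 2)
  x$dfs_months <- rep(c(3, 7, 12, 20), 2) # identical distributions
  res <- dfs_t_test(x)
  expect_equal(res$statistic, 0)
  expect_equal(res$p_value, 1)
  expect_equal(unname(res$means[1]), unname(res$means[2]))

  y <- toy_cohort(n_per_class = 3, seed = 2)
  y$dfs_months <- c(10, 10.01, 9.99, 0.01, 0, 0.02)
  res2 <- dfs_t_test(y)
  expect_lt(res2$p_value, 1e-3)
  expect_gt(res2$means["non_distant"], res2$means["distant"])
  # Welch variant exposed
  expect_false(identical(dfs_t_test(y, var_equal = FALSE)$p_value,
                         res2$p_value))
})

test_that("km curves export as two-column TSV", {
  fit <- km_estimate(c(2, 4, 4, 6), c(1, 0, 1, 0))
  p <- tempfile(fileext = ".tsv")
  write_km_curve(fit, p)
  tab <- read.delim(p)
  expect_equal(names(tab), c("time", "survival"))
  expect_equal(tab$time, c(0, 2, 4))
  expect_equal(tab$survival, c(1, 0.75, 0.5))
})
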