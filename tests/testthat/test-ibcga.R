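# cheap deterministic fitness for operator-level tests: weighted mask sum
# plus small code terms (no SVM involved)
toy_fitness <- function(weights, gw = 0.001, cw = 0.0001) {
  function(ch) {
    f <- sum(weights[ch$mask]) + gw * ch$gamma_code + cw * ch$c_code
    list(acc = f, asurv = 0, w = 1, f = f)
  }
}

eval_pop <- function(pop, fn) lapply(pop, function(ch) {
  ch$fitness <- fn(ch); ch
})

test_that("initial populations are uniform r-subsets", {
  set.seed(1)
  pop <- init_population(20, 5, 60)
  expect_length(pop, 60)
  expect_true(all(vapply(pop, function(ch) sum(ch$mask), numeric(1)) == 5))
  expect_true(all(vapply(pop, function(ch) ch$gamma_code, integer(1)) %in% 0:15))

  full <- init_population(7, 7, 10)
  expect_true(all(vapply(full, function(ch) all(ch$mask), logical(1))))
  expect_error(init_population(5, 6, 10), "exceed")

  # marginal inclusion frequency r/n within 3 binomial sigmas
  counts <- rowSums(vapply(init_population(20, 5, 10000),
                           function(ch) ch$mask, logical(20)))
  expected <- 10000 * 5 / 20
  sigma <- sqrt(10000 * 0.25 * 0.75)
  expect_true(all(abs(counts - expected) <= 3 * sigma))
})

test_that("tournament selection matches its closed-form selection pressure", {
  set.seed(2)
  n <- 20
  pop <- eval_pop(init_population(30, 4, n), toy_fitness(runif(30)))
  best_key <- which.max(vapply(pop, function(ch) ch$fitness$f, numeric(1)))
  hit <- replicate(400, {
    pool <- tournament_select(pop)
    any(vapply(pool, function(ch) identical(ch, pop[[best_key]]), logical(1)))
  })
  p_closed <- 1 - ((n - 1) / n)^(2 * n)
  expect_lt(abs(mean(hit) - p_closed), 0.06)

  # two individuals, f = (1, 0): the better wins 3 of the 4 draw patterns
  two <- init_population(4, 2, 2)
  two[[1]]$fitness <- list(f = 1); two[[2]]$fitness <- list(f = 0)
  frac <- mean(replicate(2000, {
    pool <- tournament_select(two)
    mean(vapply(pool, function(ch) ch$fitness$f, numeric(1)) == 1)
  }))
  expect_lt(abs(frac - 0.75), 0.04)

  # equal fitness: near-uniform pool composition
  eq <- init_population(10, 3, 10)
  for (i in seq_along(eq)) {
    eq[[i]]$gamma_code <- i - 1L # unique tag
    eq[[i]]$fitness <- list(f = 0)
  }
  picks <- table(factor(unlist(replicate(500, {
    vapply(tournament_select(eq), function(ch) ch$gamma_code, integer(1))
  }, simplify = FALSE)), levels = 0:9))
  expect_lt(max(picks) / min(picks), 1.6)

  un <- init_population(5, 2, 3)
  expect_error(tournament_select(un), "unevaluated")
})

test_that("the orthogonal array is balanced and pairwise orthogonal", {
  for (k in c(1, 3, 5, 7)) {
    oa <- oa_array(k)
    M <- 2^ceiling(log2(k + 1))
    expect_equal(nrow(oa), M)
    oa <- as.matrix(oa)
    for (j in seq_len(ncol(oa))) {
      expect_equal(sum(oa[, j] == 1), M / 2)
    }
    if (k >= 2) {
      for (j1 in 1:(k - 1)) for (j2 in (j1 + 1):k) {
        combos <- table(oa[, j1], oa[, j2])
        expect_true(all(combos == M / 4))
      }
    }
  }
})

test_that("main-effect composite finds the additive optimum", {
  set.seed(3)
  for (rep in 1:25) {
    g <- matrix(runif(6), 3, 2) # per-factor level payoffs
    lv <- oa_array(3)
    fit <- apply(lv, 1, function(row) sum(g[cbind(1:3, row)]))
    comp <- oa_composite(lv, fit)
    brute <- as.matrix(expand.grid(1:2, 1:2, 1:2))
    brute_f <- apply(brute, 1, function(row) sum(g[cbind(1:3, row)]))
    expect_equal(sum(g[cbind(1:3, comp)]), max(brute_f))
  }
})

test_that("OA crossover respects the subset-size invariant and short-circuits", {
  set.seed(5)
  w <- runif(30)
  fn <- toy_fitness(w)

  p <- eval_pop(init_population(30, 8, 2), fn)
  same <- oa_crossover(p[[1]], p[[1]], fn)
  expect_identical(same$children[[1]]$mask, p[[1]]$mask)
  expect_equal(same$n_evals, 0L)

  for (rep in 1:50) {
    pr <- eval_pop(init_population(30, 8, 2), fn)
    cr <- oa_crossover(pr[[1]], pr[[2]], fn)
    for (ch in cr$children) {
      expect_equal(sum(ch$mask), 8)
      expect_true(ch$gamma_code %in% c(pr[[1]]$gamma_code, pr[[2]]$gamma_code))
      expect_true(ch$c_code %in% c(pr[[1]]$c_code, pr[[2]]$c_code))
      # positions where the parents agree are inherited untouched
      agree <- pr[[1]]$mask == pr[[2]]$mask
      expect_identical(ch$mask[agree], pr[[1]]$mask[agree])
      expect_false(is.null(ch$fitness))
    }
    expect_lte(cr$n_evals, 9L) # L8 rows + composite
  }
})

test_that("swap mutation moves exactly one selected gene", {
  set.seed(6)
  ch <- init_population(15, 6, 1)[[1]]
  for (i in 1:1000) {
    mut <- mutate_chromosome(ch)
    expect_equal(sum(mut$mask), 6)
    expect_true(sum(mut$mask != ch$mask) %in% c(0, 2))
    expect_null(mut$fitness)
  }
  full <- init_population(6, 6, 1)[[1]]
  expect_identical(mutate_chromosome(full)$mask, full$mask)
})

test_that("a GA run respects stage structure, elitism, and its budget", {
  x <- toy_cohort(n_per_class = 8, p = 15, n_informative = 3, effect = 2,
                  seed = 19)
  cfg <- ga_config(r_start = 3, r_end = 5, pop_size = 10, gmax = 5,
                   runs = 2, w = 0.8, seed = 4)
  set.seed(cfg$seed)
  run <- ibcga_run(x, cfg)

  expect_named(run$stage_solutions, c("3", "4", "5"))
  for (r in 3:5) {
    expect_length(run$stage_solutions[[as.character(r)]]$transcript_ids, r)
    expect_true(all(diff(run$trajectory[[as.character(r)]]) >= 0))
  }
  expect_equal(run$best$fitness$f,
               max(vapply(run$stage_solutions, function(s) s$fitness$f,
                          numeric(1))))
  M <- 8
  bound <- (5 - 3 + 1) * cfg$gmax *
    (cfg$pop_size + cfg$p_c * cfg$pop_size * (M + 1) / 2)
  expect_lte(run$n_evals, bound)

  expect_error(ibcga_run(x, ga_config(r_start = 3, r_end = 99)), "exceeds")
})

test_that("multi_run is bit-identical under a fixed seed and counts appearances", {
  x <- toy_cohort(n_per_class = 8, p = 12, n_informative = 3, effect = 2,
                  seed = 23)
  cfg <- ga_config(r_start = 3, r_end = 4, pop_size = 8, gmax = 4, runs = 3,
                   w = 0.8, seed = 7)
  e1 <- multi_run(x, cfg)
  e2 <- multi_run(x, cfg)
  expect_identical(e1, e2)

  expect_true(all(e1$counts <= cfg$runs))
  fs <- vapply(e1$run_bests, function(s) s$fitness$f, numeric(1))
  expect_equal(e1$S_a$fitness$f, max(fs))

  one <- multi_run(x, ga_config(r_start = 3, r_end = 3, pop_size = 8,
                                gmax = 3, runs = 1, w = 1, seed = 2))
  expect_identical(one$S_a, one$S_b)
})

test_that("with w = 1 the search ignores survival entirely", {
  x <- toy_cohort(n_per_class = 8, p = 12, n_informative = 3, effect = 2,
                  seed = 29)
  cfg <- ga_config(r_start = 3, r_end = 4, pop_size = 8, gmax = 4, runs = 2,
                   w = 1, seed = 31)
  base <- multi_run(x, cfg)
  scrambled <- x
  set.seed(1)
  scrambled$dfs_months <- sample(x$dfs_months)
  scrambled$event_flags <- sample(x$event_flags)
  alt <- multi_run(scrambled, cfg)
  expect_identical(base$S_a$transcript_ids, alt$S_a$transcript_ids)
  expect_equal(base$S_a$fitness$f, alt$S_a$fitness$f)
})
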