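test_that("appearance shortlist orders by count, mean fitness, then id", {
  one <- fake_run_ensemble(list(
    list(transcripts = paste0("T", 1:10), f = 0.9)))
  expect_warning(got <- appearance_shortlist(one, k = 30), "returning all")
  expect_setequal(got, paste0("T", 1:10))

  counts <- fake_run_ensemble(list(
    list(transcripts = c("A", "B"), f = 0.5),
    list(transcripts = c("A", "B"), f = 0.5),
    list(transcripts = c("A", "B", "C"), f = 0.5),
    list(transcripts = c("A", "B", "C"), f = 0.5),
    list(transcripts = c("A", "B", "C"), f = 0.5)))
  expect_setequal(appearance_shortlist(counts, k = 2), c("A", "B"))

  # brute-force sort oracle on random tables
  set.seed(61)
  for (rep in 1:20) {
    sols <- lapply(1:6, function(i) {
      list(transcripts = sample(paste0("T", 1:8), sample(2:5, 1)),
           f = sample(c(0.4, 0.6, 0.8), 1))
    })
    ens <- fake_run_ensemble(sols)
    k <- 4
    got <- suppressWarnings(appearance_shortlist(ens, k))
    # independent ordering
    txs <- sort(unique(unlist(lapply(sols, `[[`, "transcripts"))))
    cnt <- vapply(txs, function(tx) {
      sum(vapply(sols, function(s) tx %in% s$transcripts, logical(1)))
    }, numeric(1))
    mf <- vapply(txs, function(tx) {
      fs <- vapply(sols, function(s) {
        if (tx %in% s$transcripts) s$f else NA_real_
      }, numeric(1))
      mean(fs, na.rm = TRUE)
    }, numeric(1))
    oracle <- txs[order(-cnt, -mf, txs)][seq_len(min(k, length(txs)))]
    expect_identical(got, oracle)
  }
})

test_that("SBS removes the least informative transcript first", {
  x <- toy_cohort(n_per_class = 10, p = 3, n_informative = 2, effect = 3,
                  seed = 67)
  # TX0003 is pure noise
  tr <- sbs(x$transcript_ids, x, w = 1)
  expect_equal(tr$trajectory$size, c(3, 2, 1))
  expect_true(is.na(tr$trajectory$removed[1]))

  # exhaustive one-step oracle
  w <- 1; t_max <- max(x$dfs_months)
  step_f <- vapply(x$transcript_ids, function(tx) {
    grid_search_best(x, setdiff(x$transcript_ids, tx), w = w,
                     t_max = t_max)$fitness$f
  }, numeric(1))
  expect_equal(tr$trajectory$removed[2],
               names(step_f)[which.max(step_f)])
  expect_equal(tr$trajectory$removed[2], "TX0003")

  single <- sbs("TX0001", x, w = 1)
  expect_equal(nrow(single$trajectory), 1)
  expect_error(sbs(character(0), x), "empty")
})

test_that("SBS records are reproducible by independent re-evaluation", {
  x <- toy_cohort(n_per_class = 8, p = 4, n_informative = 2, effect = 2,
                  seed = 71)
  w <- 0.8; t_max <- max(x$dfs_months)
  tr <- sbs(x$transcript_ids, x, w = w, t_max = t_max)
  for (i in seq_len(nrow(tr$trajectory))) {
    gs <- grid_search_best(x, tr$trajectory$transcripts[[i]], w = w,
                           t_max = t_max)
    expect_equal(gs$fitness$f, tr$trajectory$f[i])
    expect_equal(gs$fitness$acc, tr$trajectory$acc[i])
  }
  # both reported optima sit on the trajectory
  expect_equal(tr$best_by_f$fitness$f, max(tr$trajectory$f))
  expect_equal(tr$best_by_asurv$fitness$asurv, max(tr$trajectory$asurv))

  p <- tempfile(fileext = ".tsv")
  write_sbs_trajectory(tr$trajectory, p)
  expect_equal(read.delim(p)$size, tr$trajectory$size)
})

test_that("greedy SBS beats random removal orders on average", {
  x <- toy_cohort(n_per_class = 8, p = 5, n_informative = 2, effect = 2,
                  seed = 73)
  w <- 1; t_max <- max(x$dfs_months)
  tr <- sbs(x$transcript_ids, x, w = w, t_max = t_max)
  set.seed(3)
  n_orders <- 20
  rand_f <- matrix(NA_real_, n_orders, 5)
  for (o in seq_len(n_orders)) {
    order_ids <- sample(x$transcript_ids)
    G <- x$transcript_ids
    rand_f[o, 5] <- grid_search_best(x, G, w = w, t_max = t_max)$fitness$f
    for (s in 4:1) {
      G <- setdiff(G, order_ids[5 - s])
      rand_f[o, s] <- grid_search_best(x, G, w = w, t_max = t_max)$fitness$f
    }
  }
  for (s in 1:5) {
    expect_gte(tr$trajectory$f[tr$trajectory$size == s],
               mean(rand_f[, s]))
  }
})

test_that("univariate ranks are permutations and find planted signals", {
  x <- toy_cohort(n_per_class = 10, p = 5, n_informative = 1, effect = 4,
                  seed = 79)
  ur <- univariate_rank(x, x$transcript_ids)
  for (col in c("rank_acc", "rank_asurv", "rank_p")) {
    expect_setequal(ur[[col]], 1:5)
  }
  expect_equal(ur$transcript_id[ur$rank_p == 1], "TX0001")

  # duplicated transcript columns get identical metrics, adjacent ranks
  y <- x
  y$expression <- cbind(y$expression, y$expression[, 1])
  y <- cohort(y$expression, y$class_labels, y$dfs_months, y$event_flags,
              sample_ids = y$sample_ids,
              transcript_ids = c(x$transcript_ids, "TX0001b"))
  ur2 <- univariate_rank(y, c("TX0001", "TX0001b"))
  expect_equal(ur2$single_gene_acc[1], ur2$single_gene_acc[2])
  expect_equal(ur2$t_p_value[1], ur2$t_p_value[2])
  expect_setequal(ur2$rank_acc, 1:2)
})

test_that("rank correlation behaves at the extremes and rejects bad input", {
  expect_equal(rank_correlation(1:10, 1:10), 1)
  expect_equal(rank_correlation(1:10, 10:1), -1)
  expect_error(rank_correlation(1:4, 1:5), "length")
  expect_error(rank_correlation(rep(1, 4), 1:4), "variance")
})

test_that("the category filter keeps the smallest p-values within category", {
  x <- toy_cohort(n_per_class = 12, p = 20, n_informative = 6, effect = 2,
                  seed = 83)
  ann <- data.frame(
    transcript_id = x$transcript_ids[1:16], # 4 left uncovered -> other
    gene_symbol = paste0("G", 1:16),
    regulator_type = rep(c("kinase", "cytokine", "other", "growth factor"),
                         4))
  filt <- emt_filter(x, ann, k = 5)
  expect_length(filt$transcript_ids, 5)
  expect_identical(filt$sample_ids, x$sample_ids)

  # independent oracle: eligible transcripts sorted by pooled-t p
  eligible <- ann$transcript_id[ann$regulator_type != "other"]
  p <- survsel:::expr_t_pvalues(x, eligible)
  expect_identical(filt$transcript_ids,
                   eligible[order(p, eligible)][1:5])

  # k larger than the eligible set keeps all survivors
  all_kept <- emt_filter(x, ann, k = 100)
  expect_setequal(all_kept$transcript_ids, eligible)

  # NULL categories: pure top-k by p over everything
  topk <- emt_filter(x, ann, categories = NULL, k = 3)
  pall <- survsel:::expr_t_pvalues(x)
  expect_identical(topk$transcript_ids,
                   x$transcript_ids[order(pall, x$transcript_ids)][1:3])

  lonely <- data.frame(transcript_id = x$transcript_ids,
                       gene_symbol = x$transcript_ids,
                       regulator_type = "other")
  expect_error(emt_filter(x, lonely, k = 5), "survives")
})
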