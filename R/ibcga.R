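#' GA configuration
#'
#' Settings of the inheritable bi-objective combinatorial GA. The defaults
#' are the published study settings: stages r = 10..30, population 60,
#' crossover probability 0.8, mutation probability 0.05, 60 generations per
#' stage, 30 independent runs, and fitness weight w = 0.8.
#'
#' @param r_start,r_end smallest and largest subset size searched; each
#'   stage r contributes one solution `S_r`.
#' @param pop_size population size (>= 2).
#' @param p_c crossover probability (fraction of the mating pool paired for
#'   orthogonal-array crossover each generation).
#' @param p_m mutation probability (fraction of individuals mutated each
#'   generation; the stage-best individual is never mutated).
#' @param gmax generations per stage.
#' @param runs number of independent GA runs aggregated by [multi_run()].
#' @param w fitness weight on accuracy (`1 - w` on the survival area).
#' @param seed master seed; run i uses `seed + i`.
#' @param t_max survival-area horizon in months; `NULL` means the maximum
#'   observed DFS time of the training cohort.
#' @param p_code per-code-gene re-randomization probability inside the
#'   mutation operator.
#' @return A validated list of class `"ga_config"`.
#' @export
ga_config <- function(r_start = 10, r_end = 30, pop_size = 60, p_c = 0.8,
                      p_m = 0.05, gmax = 60, runs = 30, w = 0.8, seed = 1,
                      t_max = NULL, p_code = 0.1) {
  cfg <- structure(as.list(environment()), class = "ga_config")
  if (r_start < 1 || r_start > r_end) stop("need 1 <= r_start <= r_end")
  if (pop_size < 2) stop("pop_size must be >= 2")
  for (p in c("p_c", "p_m", "w", "p_code")) {
    if (cfg[[p]] < 0 || cfg[[p]] > 1) stop(p, " must be in [0, 1]")
  }
  if (gmax < 1 || runs < 1) stop("gmax and runs must be positive")
  cfg
}

#' Chromosome constructor
#'
#' A chromosome is a binary transcript mask with exactly `r` ones plus two
#' 4-bit hyperparameter genes; the cached fitness breakdown is attached
#' after evaluation.
#'
#' @param mask logical vector over the candidate transcripts.
#' @param gamma_code,c_code integer codes 0-15.
#' @param fitness optional cached breakdown.
#' @return A list of class `"chromosome"`.
#' @export
chromosome <- function(mask, gamma_code, c_code, fitness = NULL) {
  if (gamma_code < 0 || gamma_code > 15 || c_code < 0 || c_code > 15) {
    stop("hyperparameter codes must be in 0..15")
  }
  structure(list(mask = as.logical(mask), gamma_code = as.integer(gamma_code),
                 c_code = as.integer(c_code), fitness = fitness),
            class = "chromosome")
}

# sample() treats a length-1 numeric x as 1:x; this never does
resample <- function(x, k) x[sample.int(length(x), k)]

#' Random initial population
#'
#' Each mask is a uniform random r-subset of the n candidates; codes are
#' uniform over 0..15.
#'
#' @param n number of candidate transcripts.
#' @param r ones per mask (`r <= n`).
#' @param pop_size number of chromosomes.
#' @return A list of unevaluated chromosomes.
#' @export
init_population <- function(n, r, pop_size) {
  if (r > n) stop("r must not exceed n")
  lapply(seq_len(pop_size), function(i) {
    mask <- rep(FALSE, n)
    mask[resample(seq_len(n), r)] <- TRUE
    chromosome(mask, sample(0:15, 1), sample(0:15, 1))
  })
}

#' Binary tournament selection
#'
#' Builds a mating pool of `length(population)` winners of independent
#' size-2 tournaments (two individuals drawn with replacement; the higher
#' fitness wins, ties are broken at random).
#'
#' @param population list of evaluated chromosomes.
#' @return The mating pool (list of chromosomes).
#' @export
tournament_select <- function(population) {
  n <- length(population)
  fs <- vapply(population, function(ch) {
    if (is.null(ch$fitness)) stop("unevaluated individual in tournament")
    ch$fitness$f
  }, numeric(1))
  lapply(seq_len(n), function(i) {
    ab <- sample.int(n, 2, replace = TRUE)
    if (fs[ab[1]] > fs[ab[2]]) population[[ab[1]]]
    else if (fs[ab[2]] > fs[ab[1]]) population[[ab[2]]]
    else population[[resample(ab, 1)]]
  })
}

#' Two-level orthogonal array
#'
#' Walsh-Hadamard construction of the two-level orthogonal array
#' `L_M(2^k)` with `M = 2^ceiling(log2(k + 1))` rows: entry (i, j) is the
#' parity of the bitwise AND of row index i (0-based) and column index j.
#'
#' @param k number of factors (1..M-1).
#' @return An M x k matrix of levels 1/2.
#' @export
oa_array <- function(k) {
  stopifnot(k >= 1)
  M <- 2^ceiling(log2(k + 1))
  sapply(seq_len(k), function(j) {
    vapply(0:(M - 1), function(i) {
      bits <- bitwAnd(i, j)
      as.integer(sum(as.integer(intToBits(bits))) %% 2) + 1L
    }, integer(1))
  })
}

#' Main-effect composite of an orthogonal experiment
#'
#' Given the level matrix of an orthogonal array and the fitness of each
#' row, picks for every factor the level with the higher mean fitness
#' (orthogonality makes these per-factor means unbiased main effects; for
#' an additive fitness the composite is the exact optimum over all level
#' combinations). Ties go to level 1.
#'
#' @param levels M x k matrix of levels 1/2.
#' @param fitness length-M numeric row fitnesses.
#' @return Integer vector of k chosen levels.
#' @export
oa_composite <- function(levels, fitness) {
  stopifnot(nrow(levels) == length(fitness))
  apply(levels, 2, function(col) {
    if (mean(fitness[col == 1]) >= mean(fitness[col == 2])) 1L else 2L
  })
}

# restore sum(mask) == r by random flips among the positions where the
# parents differ (keeps offspring inside the parents' combinatorial span)
repair_mask <- function(mask, r, diff_pos) {
  s <- sum(mask)
  if (s > r) {
    ones <- diff_pos[mask[diff_pos]]
    mask[resample(ones, s - r)] <- FALSE
  } else if (s < r) {
    zeros <- diff_pos[!mask[diff_pos]]
    mask[resample(zeros, r - s)] <- TRUE
  }
  mask
}

#' Orthogonal-array crossover
#'
#' Positions where the two parents differ (mask positions and the two code
#' genes) are grouped into at most 7 factors: each differing code gene is
#' its own factor and the differing mask positions are chunked into
#' contiguous blocks. A two-level orthogonal array over the k factors
#' defines M candidate offspring (level 1 takes the block from `parent1`,
#' level 2 from `parent2`); every candidate is repaired to exactly r ones
#' and evaluated, a composite offspring is assembled from the better level
#' of each factor by main-effect analysis and evaluated too, and the two
#' highest-fitness distinct candidates become the children. Identical
#' parents short-circuit to copies with zero evaluations.
#'
#' @param parent1,parent2 evaluated chromosomes with equal mask length and
#'   equal r.
#' @param fitness_fn function(chromosome) -> fitness breakdown (a list with
#'   at least `f`).
#' @return A list with `children` (two chromosomes, fitness attached) and
#'   `n_evals` (fitness calls spent, for budget accounting).
#' @export
oa_crossover <- function(parent1, parent2, fitness_fn) {
  stopifnot(length(parent1$mask) == length(parent2$mask),
            sum(parent1$mask) == sum(parent2$mask))
  r <- sum(parent1$mask)
  dm <- which(parent1$mask != parent2$mask)
  dg <- parent1$gamma_code != parent2$gamma_code
  dc <- parent1$c_code != parent2$c_code
  if (length(dm) == 0 && !dg && !dc) {
    return(list(children = list(parent1, parent2), n_evals = 0L))
  }
  n_code <- sum(dg, dc)
  blocks <- list()
  if (length(dm) > 0) {
    k_mask <- min(length(dm), 7L - n_code)
    grp <- cut(seq_along(dm), k_mask, labels = FALSE)
    blocks <- split(dm, grp)
  }
  k <- length(blocks) + n_code
  lv <- oa_array(k)
  build <- function(levvec) {
    mask <- parent1$mask
    j <- 0
    for (b in blocks) {
      j <- j + 1
      if (levvec[j] == 2) mask[b] <- parent2$mask[b]
    }
    gc_ <- parent1$gamma_code
    cc_ <- parent1$c_code
    if (dg) { j <- j + 1; if (levvec[j] == 2) gc_ <- parent2$gamma_code }
    if (dc) { j <- j + 1; if (levvec[j] == 2) cc_ <- parent2$c_code }
    if (length(dm) > 0) mask <- repair_mask(mask, r, dm)
    chromosome(mask, gc_, cc_)
  }
  cands <- lapply(seq_len(nrow(lv)), function(i) {
    ch <- build(lv[i, ])
    ch$fitness <- fitness_fn(ch)
    ch
  })
  n_evals <- nrow(lv)
  comp_lev <- oa_composite(lv, vapply(cands, function(ch) ch$fitness$f,
                                      numeric(1)))
  comp <- build(comp_lev)
  comp$fitness <- fitness_fn(comp)
  n_evals <- n_evals + 1L
  cands <- c(cands, list(comp))
  key <- vapply(cands, function(ch) {
    paste(c(as.integer(ch$mask), ch$gamma_code, ch$c_code), collapse = "")
  }, character(1))
  ord <- order(-vapply(cands, function(ch) ch$fitness$f, numeric(1)))
  picked <- ord[!duplicated(key[ord])][1:2]
  if (is.na(picked[2])) picked[2] <- picked[1]
  list(children = cands[picked], n_evals = n_evals)
}

#' Swap mutation
#'
#' Exchanges one randomly chosen selected transcript with one unselected
#' transcript (preserving the subset size r); each hyperparameter code gene
#' is independently re-randomized with probability `p_code`. The cached
#' fitness is invalidated. With no unselected genes (r = n) the mask is
#' unchanged.
#'
#' @param chrom a chromosome.
#' @param p_code per-code re-randomization probability.
#' @return The mutated, unevaluated chromosome.
#' @export
mutate_chromosome <- function(chrom, p_code = 0.1) {
  sel <- which(chrom$mask)
  unsel <- which(!chrom$mask)
  if (length(sel) > 0 && length(unsel) > 0) {
    chrom$mask[resample(sel, 1)] <- FALSE
    chrom$mask[resample(unsel, 1)] <- TRUE
  }
  if (stats::runif(1) < p_code) chrom$gamma_code <- sample(0:15, 1)
  if (stats::runif(1) < p_code) chrom$c_code <- sample(0:15, 1)
  chrom$fitness <- NULL
  chrom
}

# internal: fast fitness closure over a cohort (compiled LOOCV + Asurv),
# with an evaluation counter for budget accounting
make_fitness_fn <- function(x, w, t_max, counter) {
  X <- x$expression
  y <- as.integer(x$class_labels == "distant")
  dfs <- x$dfs_months
  ev <- as.integer(x$event_flags)
  function(chrom) {
    counter$n <- counter$n + 1L
    pred <- .svc_loocv_cpp(X[, chrom$mask, drop = FALSE], y,
                           decode_log2_param(chrom$gamma_code),
                           decode_log2_param(chrom$c_code))
    acc <- mean(pred == y)
    asurv <- .asurv_cpp(dfs, ev, ifelse(pred == 0L, 1L, 2L), t_max)
    list(acc = acc, asurv = asurv, w = w,
         f = w * acc + (1 - w) * max(asurv, 0))
  }
}

#' One inheritable bi-objective combinatorial GA run
#'
#' Evolves subsets of size `r_start`, records the stage best `S_r`, then
#' inherits: every individual flips one random 0 to 1 (the elite included,
#' changed only by that mandated flip), the stage size grows by one, and
#' evolution continues up to `r_end`. Within a stage each generation applies
#' binary tournament selection, orthogonal-array crossover on `p_c *
#' pop_size` parents, swap mutation on `p_m * pop_size` randomly chosen
#' non-elite individuals, and elitism (the stage best always survives, so
#' the best-fitness trajectory is non-decreasing within a stage).
#'
#' Uses the current RNG state; seed it (or use [multi_run()]) for
#' reproducibility.
#'
#' @param x training `"cohort"` (both classes nonempty, at least `r_end`
#'   transcripts).
#' @param config a [ga_config()].
#' @return A list with `stage_solutions` (one [selection_result()] per
#'   stage r), `best` (the highest-f stage solution), `trajectory` (per
#'   stage, the best fitness after each generation), and `n_evals`.
#' @export
ibcga_run <- function(x, config) {
  stopifnot(inherits(config, "ga_config"))
  validate_cohort(x, require_both_classes = TRUE)
  n <- length(x$transcript_ids)
  if (n < config$r_end) stop("r_end exceeds the number of transcripts")
  t_max <- if (is.null(config$t_max)) max(x$dfs_months) else config$t_max
  counter <- new.env()
  counter$n <- 0L
  fitness_fn <- make_fitness_fn(x, config$w, t_max, counter)
  evaluate <- function(pop) {
    for (i in seq_along(pop)) {
      if (is.null(pop[[i]]$fitness)) pop[[i]]$fitness <- fitness_fn(pop[[i]])
    }
    pop
  }
  fvec <- function(pop) vapply(pop, function(ch) ch$fitness$f, numeric(1))

  N <- config$pop_size
  pop <- evaluate(init_population(n, config$r_start, N))
  stage_solutions <- list()
  trajectory <- list()
  for (r in config$r_start:config$r_end) {
    elite <- pop[[which.max(fvec(pop))]]
    traj <- numeric(config$gmax)
    for (gen in seq_len(config$gmax)) {
      pool <- tournament_select(pop)
      n_par <- 2L * floor(config$p_c * N / 2)
      if (n_par >= 2) {
        idx <- sample.int(N, n_par)
        for (p in seq(1, n_par, by = 2)) {
          cr <- oa_crossover(pool[[idx[p]]], pool[[idx[p + 1]]], fitness_fn)
          pool[[idx[p]]] <- cr$children[[1]]
          pool[[idx[p + 1]]] <- cr$children[[2]]
        }
      }
      n_mut <- round(config$p_m * N)
      if (n_mut > 0) {
        best_i <- which.max(fvec(pool))
        mut_i <- resample(setdiff(seq_len(N), best_i),
                          min(n_mut, N - 1L))
        for (i in mut_i) {
          pool[[i]] <- mutate_chromosome(pool[[i]], config$p_code)
        }
      }
      pool <- evaluate(pool)
      fs <- fvec(pool)
      if (elite$fitness$f > max(fs)) pool[[which.min(fs)]] <- elite
      pop <- pool
      elite <- pop[[which.max(fvec(pop))]]
      traj[gen] <- elite$fitness$f
    }
    stage_solutions[[as.character(r)]] <- selection_result(
      x$transcript_ids[elite$mask], elite$fitness,
      elite$gamma_code, elite$c_code,
      provenance = sprintf("ibcga stage r=%d", r))
    trajectory[[as.character(r)]] <- traj
    if (r < config$r_end) {
      pop <- lapply(pop, function(ch) {
        zeros <- which(!ch$mask)
        ch$mask[resample(zeros, 1)] <- TRUE
        ch$fitness <- NULL
        ch
      })
      pop <- evaluate(pop)
    }
  }
  fbest <- vapply(stage_solutions, function(s) s$fitness$f, numeric(1))
  list(stage_solutions = stage_solutions,
       best = stage_solutions[[which.max(fbest)]],
       trajectory = trajectory, n_evals = counter$n)
}

#' Aggregate R independent GA runs
#'
#' Runs [ibcga_run()] `config$runs` times with derived seeds
#' (`config$seed + run index`), records every run's best solution, counts
#' how often each transcript appears across the run bests, and reports both
#' the most accurate solution `S_a` (highest fitness) and the most robust
#' one `S_b` (highest appearance score). The appearance score of a solution
#' S is `0.5 * f(S) / max_f + 0.5 * mean(count(g) / R)` over its
#' transcripts, blending fitness with how often its members recur.
#'
#' @param x training `"cohort"`.
#' @param config a [ga_config()].
#' @return An object of class `"run_ensemble"`: list with `run_bests`,
#'   `counts` (named appearance counts, decreasing), `S_a`, `S_b`,
#'   `scores`, and `config`.
#' @export
multi_run <- function(x, config) {
  stopifnot(inherits(config, "ga_config"))
  run_bests <- vector("list", config$runs)
  for (i in seq_len(config$runs)) {
    set.seed(config$seed + i)
    res <- ibcga_run(x, config)
    res$best$provenance <- sprintf("run %d seed %d; %s", i, config$seed + i,
                                   res$best$provenance)
    run_bests[[i]] <- res$best
  }
  all_tx <- unlist(lapply(run_bests, function(s) s$transcript_ids))
  counts <- sort(table(all_tx), decreasing = TRUE)
  counts <- stats::setNames(as.integer(counts), names(counts))
  fs <- vapply(run_bests, function(s) s$fitness$f, numeric(1))
  scores <- vapply(run_bests, function(s) {
    0.5 * s$fitness$f / max(fs) +
      0.5 * mean(counts[s$transcript_ids] / config$runs)
  }, numeric(1))
  structure(list(run_bests = run_bests, counts = counts,
                 S_a = run_bests[[which.max(fs)]],
                 S_b = run_bests[[which.max(scores)]],
                 scores = scores, config = config),
            class = "run_ensemble")
}

#' @export
print.run_ensemble <- function(x, ...) {
  cat("run_ensemble:", length(x$run_bests), "runs,",
      length(x$counts), "distinct transcripts in run bests\n")
  cat("  S_a: f =", round(x$S_a$fitness$f, 4),
      "|", length(x$S_a$transcript_ids), "transcripts\n")
  cat("  S_b: f =", round(x$S_b$fitness$f, 4),
      "|", length(x$S_b$transcript_ids), "transcripts\n")
  invisible(x)
}
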