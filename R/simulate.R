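#' Synthetic-cohort configuration
#'
#' Parameters of the generator, defaulting to the structure of the lung
#' cancer training cohort the method targets: 78 samples split 37
#' non-distant : 41 distant, a few hundred candidate transcripts with a
#' small planted informative subset, strongly separated disease-free
#' survival (distant events early, non-distant mostly censored late) over a
#' 120-month follow-up.
#'
#' @param n_samples total samples (default 78).
#' @param n_transcripts candidate transcripts (default 474).
#' @param n_informative planted class-informative transcripts (default 10).
#' @param n_non_distant samples in the non-distant class (default 37; the
#'   rest are distant).
#' @param effect_size mean expression shift of informative transcripts in
#'   the distant class, in noise-SD units (default 1.5).
#' @param noise_sd expression noise SD (default 1).
#' @param mu_non_distant,mu_distant latent exponential mean survival of the
#'   two classes, months (defaults 90 and 14).
#' @param horizon follow-up horizon, months (default 120).
#' @param censor_window uniform censoring window for the non-distant class,
#'   months (default `c(60, 120)`).
#' @param seed integer seed.
#' @return A validated list of class `"sim_config"`.
#' @export
sim_config <- function(n_samples = 78, n_transcripts = 474,
                       n_informative = 10, n_non_distant = 37,
                       effect_size = 1.5, noise_sd = 1,
                       mu_non_distant = 90, mu_distant = 14, horizon = 120,
                       censor_window = c(60, 120), seed = 1) {
  cfg <- structure(as.list(environment()), class = "sim_config")
  if (n_informative > n_transcripts) {
    stop("n_informative must not exceed n_transcripts")
  }
  if (n_non_distant < 0 || n_non_distant > n_samples) {
    stop("n_non_distant must be between 0 and n_samples")
  }
  if (horizon <= 0) stop("horizon must be positive")
  if (mu_non_distant <= mu_distant) {
    stop("mu_non_distant must exceed mu_distant")
  }
  cfg
}

# internal: draw one cohort given fixed planted columns
sim_draw <- function(cfg, informative, sample_prefix) {
  n <- cfg$n_samples
  p <- cfg$n_transcripts
  cls <- rep(c("non_distant", "distant"),
             c(cfg$n_non_distant, n - cfg$n_non_distant))
  E <- matrix(stats::rnorm(n * p, 0, cfg$noise_sd), n, p)
  shift <- cfg$effect_size * cfg$noise_sd
  E[cls == "distant", informative] <- E[cls == "distant", informative] + shift
  dfs <- numeric(n)
  event <- integer(n)
  dist <- cls == "distant"
  nd <- sum(dist)
  dfs[dist] <- pmin(stats::rexp(nd, 1 / cfg$mu_distant), cfg$horizon)
  event[dist] <- 1L
  nn <- n - nd
  latent <- stats::rexp(nn, 1 / cfg$mu_non_distant)
  cens <- pmin(stats::runif(nn, cfg$censor_window[1], cfg$censor_window[2]),
               cfg$horizon)
  dfs[!dist] <- pmin(latent, cens)
  event[!dist] <- as.integer(latent <= cens)
  cohort(E, class_labels = cls, dfs_months = dfs, event_flags = event,
         sample_ids = sprintf("%s%03d", sample_prefix, seq_len(n)),
         transcript_ids = sprintf("TX%04d", seq_len(p)))
}

# internal: synthetic annotation; planted transcripts cycle through the EMT
# categories, the rest draw uniformly from the full vocabulary
sim_annotation <- function(transcript_ids, informative) {
  vocab <- c(EMT_CATEGORIES, "other")
  reg <- sample(vocab, length(transcript_ids), replace = TRUE)
  names(reg) <- transcript_ids
  reg[informative] <- rep_len(EMT_CATEGORIES, length(informative))
  data.frame(transcript_id = transcript_ids,
             gene_symbol = sub("^TX", "GENE", transcript_ids),
             regulator_type = unname(reg), stringsAsFactors = FALSE)
}

#' Simulate a cohort with planted informative transcripts
#'
#' Class labels are fixed by the configured balance. Informative transcripts
#' are normal with a mean shift of `effect_size` SD in the distant class;
#' the rest are pure noise. Distant samples experience the event at an
#' exponential time (mean `mu_distant`) capped at the horizon; non-distant
#' samples have a long latent exponential time (mean `mu_non_distant`)
#' right-censored by a uniform censoring window, so most are censored.
#' Class drives expression and survival independently - exactly the
#' dependence structure the weighted fitness exploits. Deterministic under
#' `config$seed`.
#'
#' @param config a [sim_config()].
#' @return A list with `cohort`, `informative` (planted transcript ids,
#'   possibly empty), and `annotation`.
#' @export
simulate_cohort <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  informative <- sort(resample(seq_len(config$n_transcripts),
                               config$n_informative))
  x <- sim_draw(config, informative, "S")
  ann <- sim_annotation(x$transcript_ids, x$transcript_ids[informative])
  list(cohort = x, informative = x$transcript_ids[informative],
       annotation = ann)
}

#' Simulate a train/test cohort pair
#'
#' Two cohorts from the same generative process (same planted transcripts
#' and effect sizes) with disjoint sample ids, mirroring a 78-sample
#' training cohort and an independent 26-sample test cohort with a 6 : 20
#' class balance.
#'
#' @param config a [sim_config()] describing the training cohort.
#' @param n_test test samples (default 26).
#' @param n_test_non_distant non-distant test samples (default 6).
#' @return A list with `train`, `test`, `informative`, and `annotation`.
#' @export
make_paperlike_pair <- function(config = sim_config(), n_test = 26,
                                n_test_non_distant = 6) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  informative <- sort(resample(seq_len(config$n_transcripts),
                               config$n_informative))
  train <- sim_draw(config, informative, "S")
  test_cfg <- config
  test_cfg$n_samples <- n_test
  test_cfg$n_non_distant <- n_test_non_distant
  test <- sim_draw(test_cfg, informative, "T")
  ann <- sim_annotation(train$transcript_ids,
                        train$transcript_ids[informative])
  list(train = train, test = test,
       informative = train$transcript_ids[informative], annotation = ann)
}

#' Write a simulated data set to disk
#'
#' Emits the standard cohort TSV pair, the annotation TSV, and a
#' ground-truth JSON (planted transcript ids plus the configuration echo).
#'
#' @param sim result of [simulate_cohort()].
#' @param dir output directory (created if needed).
#' @param prefix file-name prefix.
#' @return Named vector of the written paths, invisibly.
#' @export
write_simulation <- function(sim, dir, prefix = "synthetic") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    expression = file.path(dir, paste0(prefix, "_expression.tsv")),
    clinical = file.path(dir, paste0(prefix, "_clinical.tsv")),
    annotation = file.path(dir, paste0(prefix, "_annotation.tsv")),
    truth = file.path(dir, paste0(prefix, "_truth.json")))
  write_cohort(sim$cohort, paths["expression"], paths["clinical"])
  write_annotation(sim$annotation, paths["annotation"])
  jsonlite::write_json(list(informative = sim$informative),
                       paths["truth"], auto_unbox = TRUE)
  invisible(paths)
}
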