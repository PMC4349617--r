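# survsel — survival-informed gene selection for metastasis prognosis

`survsel` discovers small prognostic transcript panels from paired
expression and disease-free-survival (DFS) data, for the setting where a
transcriptomics cohort is far wider than it is deep (hundreds of candidate
transcripts, tens of patients) and purely accuracy-driven wrapper selection
overfits. Its users are computational biologists building metastasis
classifiers from bulk expression cohorts with clinical follow-up.

## The method

Candidate transcript subsets *G* are scored by a weighted bi-objective
fitness

    f(G) = w · Acc + (1 − w) · Asurv,    w ∈ [0, 1]

where `Acc` is the leave-one-out cross-validation accuracy of an RBF-kernel
C-SVM (`exp(−γ‖xᵢ − xⱼ‖²)`, γ and C on the grid `2⁻⁷ … 2⁸`) restricted to
*G*, and `Asurv` is the **disease-free survival area**: the normalized area
between the Kaplan-Meier DFS curves of the two *predicted* groups,

    Asurv = (1 / t_max) ∫₀^{t_max} [ S_pred-non-met(t) − S_pred-met(t) ] dt.

A panel that truly carries prognostic signal must both classify metastasis
and stratify survival; the second term penalizes sets that only memorize
training labels. The search is an inheritable bi-objective combinatorial
genetic algorithm (IBCGA): subsets of exactly *r* transcripts are evolved
with tournament selection, orthogonal-array crossover and swap mutation,
the stage solution `S_r` is recorded, and the population inherits into
stage *r* + 1 (r = 10 … 30 by default). Independent runs are aggregated by
per-transcript appearance counts, a shortlist is refined by sequential
backward selection (SBS), and the resulting panel is evaluated by a
random-subspace SVM ensemble and by support-vector regression of survival
time. A synthetic-cohort generator with planted informative transcripts
makes the whole pipeline testable end to end.

## Worked example

```r
library(survsel)

# synthetic 78-sample training / 26-sample test pair, 474 transcripts,
# 10 planted informative ones
pair <- make_paperlike_pair(sim_config(seed = 7))

# univariate pre-filter, then a reduced-budget multi-run GA
filt <- emt_filter(pair$train, pair$annotation, categories = NULL, k = 60)
cfg  <- ga_config(r_start = 10, r_end = 12, pop_size = 20, gmax = 15,
                  runs = 5, w = 0.8, seed = 11)
ens  <- multi_run(filt, cfg)
ens
#> run_ensemble: 5 runs, 31 distinct transcripts in run bests
#>   S_a: f = 0.9029 | 10 transcripts
#>   S_b: f = 0.9029 | 10 transcripts

# appearance shortlist, then sequential backward selection
short <- appearance_shortlist(ens, k = 20)
sum(pair$informative %in% short)     # planted transcripts recovered
#> [1] 9
tr <- sbs(short[1:10], filt, w = 0.8)
tr$best_by_f
#> selection_result: 10 transcripts (f = 0.9029, acc = 1.0000, asurv = 0.5143, w = 0.80)

# independent-test evaluation of the selected panel
svm_test_predict(pair$train, pair$test, tr$best_by_f$transcript_ids,
                 w = 0.8)$acc
#> [1] 0.9615385
ensemble_train_predict(pair$train, pair$test, tr$best_by_f$transcript_ids,
                       n_members = 30, member_size = 5, w = 0.8,
                       seed = 3)$acc
#> [1] 0.9230769
```

The selection reaches LOOCV accuracy 1.0 with a predicted-group survival
area of 0.51 (the planted signal is strong at this effect size), recovers
9 of the 10 planted transcripts in the top-20 shortlist, and the panel
carries over to the held-out cohort (96% single-SVM, 92% ensemble test
accuracy). On real cohorts the same calls apply to objects from
`read_cohort()`.

A thin command-line front end wraps the same functions:

```sh
Rscript inst/cli/survsel.R simulate --seed 1 --out-dir data/
Rscript inst/cli/survsel.R select --expression data/train_expression.tsv \
    --clinical data/train_clinical.tsv --runs 5 --gmax 15 --pop 20 \
    --rstart 10 --rend 12 --out-dir run1/
```

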