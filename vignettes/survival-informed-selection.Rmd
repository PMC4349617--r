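---
title: "Survival-informed gene selection: model, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Survival-informed gene selection: model, parameters, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(survsel)
```

## The problem

Microarray cohorts for metastasis prognosis typically pair a few hundred
candidate transcripts with fewer than a hundred patients. Many transcript
subsets separate the training classes perfectly, so purely
accuracy-driven wrapper selection overfits: training accuracy saturates
while independent-test accuracy stays poor. `survsel` implements a
selection objective that spends part of its weight on a second, clinically
anchored signal — how well the *predicted* groups separate in disease-free
survival (DFS) — on the hypothesis that a genuinely prognostic transcript
set must also stratify survival.

## The objective

For a transcript subset $G$ with RBF-SVM hyperparameters $(\gamma, C)$,

$$ f(G) = w \cdot Acc + (1 - w) \cdot A_{surv}, \qquad w \in [0, 1], $$

where

* $Acc$ is the leave-one-out cross-validation (LOOCV) accuracy of the
  RBF-kernel C-SVM ($k(x_i, x_j) = \exp(-\gamma\|x_i - x_j\|^2)$)
  restricted to $G$;
* $A_{surv}$ is the *disease-free survival area*: the Kaplan-Meier curves
  of the two LOOCV-*predicted* groups are integrated from 0 to $t_{max}$
  and the signed area between them (predicted non-metastasis curve on top)
  is divided by $t_{max}$, giving a value in $[-1, 1]$.

Using predicted rather than true groups is essential: the objective must
score candidate classifiers, and a classifier that merely reproduces noisy
training labels gains nothing on the survival term. With $w = 1$ the
objective degenerates to conventional accuracy-only selection.

Two conventions matter and are tested:

* **Sign and clamping.** $A_{surv}$ is kept signed in all reported
  breakdowns (a negative value flags a classifier that inverts the
  groups), but contributes $\max(A_{surv}, 0)$ to $f$, keeping
  $f \in [0, 1]$.
* **Kaplan-Meier ties.** At tied times, events are processed before
  censorings; censoring-only times produce no drop. The estimator is
  delegated to `survival::survfit()`; the area uses exact step-function
  integration (no quadrature error), and a compiled re-implementation of
  both is used inside the optimizer's hot loop, cross-checked against the
  `survfit`-backed path in the test suite.

$t_{max}$ defaults to the largest observed DFS time in the training
cohort (117 months in the study this package targets) and is configurable
everywhere it appears.

## The search

Feature selection for a fixed subset size $r$ is the combinatorial problem
$C(n, r)$. The optimizer is an inheritable bi-objective combinatorial GA:

1. **Chromosome**: $n$ binary mask genes with exactly $r$ ones, plus two
   4-bit genes encoding $\gamma, C \in \{2^{-7}, \dots, 2^{8}\}$.
2. **Stages**: evolve at size $r$, record the stage best $S_r$, then
   *inherit* — every individual flips one random 0 to 1 — and continue at
   $r + 1$, from `r_start` (10) to `r_end` (30).
3. **Generations** (60 per stage by default): binary tournament selection
   (pairs drawn with replacement), orthogonal-array crossover on
   $p_c N_{pop}$ parents, swap mutation on $p_m N_{pop}$ non-elite
   individuals, elitism.
4. **Crossover**: positions where the parents differ are grouped into at
   most 7 factors (each differing code gene is its own factor; differing
   mask positions form contiguous blocks). A two-level orthogonal array
   $L_M(2^k)$, $M = 2^{\lceil \log_2(k+1) \rceil}$, defines $M$ candidate
   offspring; each is repaired to $\sum f_i = r$ by random flips restricted
   to the differing positions, and a composite offspring takes the better
   level of each factor by main-effect analysis. The two fittest distinct
   candidates survive. For an additive objective the composite is provably
   the optimum over all $2^k$ block exchanges; the test suite checks this
   against exhaustive enumeration. (Note that two equal-size masks always
   differ in an even number of positions, so a three-factor experiment
   necessarily involves the code genes or grouped blocks.)
5. **Aggregation**: $R$ independent runs (30 by default, seeds
   `seed + run`) yield run-best solutions; per-transcript appearance
   counts across run bests are tabulated. $S_a$ is the highest-fitness
   solution; $S_b$ maximizes the appearance score
   $\tfrac12 f(S)/f_{max} + \tfrac12\,\mathrm{mean}_{g \in S}(count(g)/R)$,
   a deliberate realization of "fitness plus how often its members recur"
   — the literature formula it abbreviates is not fully specified, so this
   package fixes one auditable form.

Defaults (`ga_config()`): `r_start = 10`, `r_end = 30`, `pop_size = 60`,
`p_c = 0.8`, `p_m = 0.05`, `gmax = 60`, `runs = 30`, `w = 0.8`. `gmax` is
interpreted per stage (each $S_r$ gets its own termination test); the
mutation operator swaps one selected with one unselected transcript
(preserving $r$) and re-randomizes each code gene with probability 0.1.

## Refinement and evaluation

* `appearance_shortlist()` keeps the top-k (default 30) transcripts by
  appearance count, ties broken by the mean fitness of the solutions
  containing the transcript, then id.
* `sbs()` runs sequential backward selection from the shortlist: at each
  step every single-transcript removal is scored by a full 16×16 grid
  search and the removal with the largest resulting $f$ is taken (a
  removal may *increase* $f$). Ties remove the transcript with the larger
  univariate t-test p-value. Both the highest-$f$ and the
  highest-$A_{surv}$ sets on the trajectory are reported, because a panel
  chosen for survival separation need not maximize $f$.
* `ensemble_train_predict()` evaluates a panel by a random-subspace
  ensemble: 30 SVMs, each on 5 transcripts drawn without replacement,
  each grid-tuned on the training cohort, majority vote with ties going
  to `distant` (favoring sensitivity to metastasis).
* `svr_fit_predict()` regresses DFS months on the panel with
  epsilon-insensitive SVR (RBF kernel, $\varepsilon = 0.1$ months fixed so
  the hyperparameter search stays two-dimensional over the same
  $\gamma/C$ grid, selected by training MAE). The fit is evaluated on the
  training cohort — the usual presentation of such survival-time models —
  so the reported MAE and correlation describe the *fit*, not
  generalization; with a flexible kernel the training MAE can approach
  $\varepsilon$ itself.
* `emt_filter()` is the pre-filter that reduces the candidate pool before
  the GA: keep transcripts in selected regulator categories (the five EMT
  categories by default; transcripts missing from the annotation count as
  `other`), rank by pooled two-sample t-test p-value, truncate to `k`
  (default 474, the published candidate-set size, expressed as a count
  rather than a p threshold for reproducibility).
* `weight_sweep()` estimates held-out accuracy per fitness weight with
  stratified cross-validation folds (stratification avoids degenerate
  folds at small n).

## The SVM engine

The GA evaluates $f$ tens of thousands of times per run, and each
evaluation is a full LOOCV. The package therefore carries a compact
compiled SMO solver for the binary RBF C-SVC (second-order working-set
selection, libsvm's stopping rule at $\epsilon = 10^{-3}$) with two LOOCV
shortcuts: samples that are not support vectors of the full-data solution
need no refit (removing them leaves the KKT system optimal), and
support-vector folds warm-start from the full solution. The solver is
validated in the test suite against `e1071` (libsvm) predictions on
randomized problems across the whole hyperparameter grid; `e1071` also
provides the SVR implementation, where a handful of fits suffice.

## The synthetic cohort generator

`sim_config()` encodes the data structure the method assumes, with
defaults mirroring the targeted lung-cancer study: 78 samples (37
non-distant : 41 distant), 474 candidate transcripts of which 10 are
informative with a 1.5-SD mean shift in the distant class, distant DFS
exponential with mean 14 months capped at a 120-month horizon (all
events), non-distant DFS exponential with mean 90 months right-censored
by a uniform 60-120-month window (mostly censored). Class labels drive
expression and survival independently — exactly the dependence structure
the weighted objective exploits. `make_paperlike_pair()` adds an
independent 26-sample test cohort (6 : 20) from the same process.

What the generator deliberately does **not** emulate: inter-transcript
correlation, batch effects, heavy-tailed intensity noise, or any direct
expression-to-survival link beyond class membership. Passing tests on
synthetic data therefore demonstrate the machinery (estimators,
optimizer, aggregation) under the assumed dependence structure, not
performance on real microarray data.

Distant survival times are `pmin(rexp(mean = 14), horizon)` with
`event = 1`; capping rather than conditional truncation changes the mean
by under 0.03 months at these parameters and keeps the draw one line.

## Study conditions used by the tests and the acceptance script

Scaled-down problem sizes were fixed once, as this package's own choices:

* *Shortlist recovery*: default 78 × 474 cohorts, univariate pre-filter to
  the top 60 transcripts, GA at `runs = 5`, `gmax = 15`, `pop_size = 20`,
  stages 10-12, five master seeds; at these conditions the appearance
  shortlist recovers on average ≥ 70% of planted transcripts in the top
  20.
* *Verified-optimum recovery*: a 60-sample, 30-transcript cohort with
  three *complementary* planted genes — each inverted on a different third
  of samples, so each is individually weak, the triple separates the
  classes, and low-variance background transcripts contribute almost
  nothing to the RBF kernel. This construction makes the planted triple
  the unique fitness optimum (verified by exhaustive C(30,3) evaluation in
  the test), giving the GA a known target; independent draws with equal
  per-gene shifts do not reliably produce a unique optimum at this scale
  because LOOCV extreme-value noise across 4060 subsets exceeds the
  accuracy margin. The GA at its published settings recovers the triple in
  ≥ 80% of 20 seeded runs.
* *Weight trend*: ten 50-sample, 40-transcript pairs at effect size 1.0
  (an overfitting regime); the median held-out advantage of `w = 0.8`
  over `w = 1.0` is non-negative.
* The acceptance script (`scripts/acceptance.R`) runs the full pipeline —
  simulate, filter, select, shortlist, SBS, test evaluation, SVR — on a
  default-size synthetic pair at the reduced GA budget and recomputes the
  published rank-table correlation; it completes in a few minutes on one
  CPU.

## Numerical and degenerate-input conventions

* Grid-search ties prefer the smallest `c_code`, then the smallest
  `gamma_code` (smoother models, deterministic).
* A LOOCV training fold reduced to one class predicts that fold's
  majority class (with a warning) instead of aborting a GA run.
* Constant transcripts get t-test p = 1; constant SVR targets are an
  error; empty predicted groups make the survival area 0 by convention,
  flagged by a zero in `group_sizes`.
* Ensemble vote ties (15-15) go to `distant`.
* All randomness flows from explicit seeds; a fixed seed makes
  `multi_run()` bit-identical.

## Known limitations

* The appearance score for $S_b$ is one fixed realization of a loosely
  specified idea; alternative weightings are plausible.
* The SVR metrics are training-set fits by design and should not be read
  as generalization estimates.
* The t-test variant underlying filters and rankings is the
  pooled-variance Student test (Welch is exposed in `dfs_t_test()`);
  published summaries rarely state which was used.
* Reproducing the published cohort numbers requires the original
  expression/clinical tables, which cannot be redistributed here; the
  reproduction workflow is implemented and activates once the files are
  placed under `inst/extdata/real/` (see the acceptance test for the
  expected layout and tolerances).
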