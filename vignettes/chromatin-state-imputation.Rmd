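---
title: "Imputing chromatin states from gene expression: model and methods"
author: "chromcast"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Imputing chromatin states from gene expression: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chromcast)
```

## The problem

Chromatin-state segmentations — genome annotations at 200-bp resolution into
an alphabet of states such as active promoter, enhancer, transcribed,
Polycomb-repressed and quiescent, typically produced by ChromHMM from
several histone-modification ChIP-seq tracks — exist for far fewer
biological samples than RNA-seq does. Many samples have gene expression and
nothing else. `chromcast` imputes a sample's full chromatin-state annotation
from its expression vector alone, by exploiting a reference compendium of
samples that have both: expression similarity between samples predicts
chromatin-state similarity, so the states of a sample's expression-nearest
neighbours are highly informative features for its own states.

## The model

Each 200-bp genome bin is a "position". For every reference sample
$T$ the package trains one multinomial logistic regression with lasso
penalty:

* **Features.** The $L$ reference samples most correlated with $T$
  (Spearman correlation of preprocessed expression; ties keep input order)
  are its *feature samples*. At each position their hard states are one-hot
  encoded, giving $L \times S$ binary features for an $S$-state alphabet
  (all $S$ indicator columns per neighbour slot are kept; the L1 penalty
  handles the redundancy, mirroring standard glmnet-multinomial usage).
* **Target.** $T$'s own state labels at a random subsample of positions
  (100,000 genome-wide at full scale; smaller on synthetic genomes).
* **Fit.** `glmnet` with `family = "multinomial"`, `alpha = 1`, per-state
  intercepts, no standardization of the binary features, and a fixed
  penalty $\lambda$ chosen by the tuning procedure below.

To annotate a new sample, its $R$ expression-nearest reference samples are
found the same way and the probability matrices of their $R$ trained models
are averaged with equal weight (the soft annotation); the hard annotation
takes the per-position argmax, ties to the lowest state index. States that a
model never saw in its training subsample receive probability exactly 0 from
that model, so rows always sum to 1 and the ensemble remains a proper
probability distribution at every stage (enforced at $10^{-6}$).

## Expression preprocessing

Raw TPM values are (1) restricted to protein-coding genes on chr1–chr22 and
chrX when a gene annotation is supplied, (2) quantile-normalized across all
samples — every sample's sorted vector becomes the across-sample mean of
sorted vectors, ties receiving the mean of the tied reference quantiles —
and (3) transformed by $\log_2(x + 1)$. Spearman rankings are invariant to
the monotone log step; normalization matters because reference and query
samples may come from different assay protocols.

## Hyperparameters and tuning

| parameter | meaning | default | grid |
|---|---|---|---|
| $L$ | feature samples per model | 5 | 5, 10, 15 |
| $R$ | models ensembled per query | 3 | 3, 5, 10 |
| $\lambda$ | lasso penalty | $10^{-4}$ | 0.1, 0.01, 0.001, 0.0001 |
| positions | training subsample size | 3000 (synthetic scale) | — |

Selection is two-stage, run on a tuning set of held-aside reference samples
(6% of the non-test samples inside each cross-validation fold, or 20% in a
single production split) and restricted to a tuning region (by default the
first chromosome): first $\lambda$ is chosen to maximize the average number
of states that receive at least one hard-assigned position per tuning
sample — small penalties otherwise leave rare states entirely unassigned in
some samples — with ties to the smaller $\lambda$; then, with $\lambda$
fixed, $(R, L)$ maximize the median tuning-sample accuracy, ties to the
smaller $R$ then smaller $L$. Tuning never touches test samples.

## Baselines and benchmark

* **Majority state**: the per-position modal state across all reference
  samples; frequency ties broken by a seeded uniform draw (one generator
  per call, consumed in bin order).
* **KNN**: the modal state across the query's $k$ expression-nearest
  references, $k$ tuned over {1, 3, 5, 7, 9} by tuning-set accuracy.
* **Closest reference**: the single reference with the highest pairwise
  agreement with the target's *true* annotation — an upper-bound benchmark,
  not a method, since it peeks at the answer.

## Evaluation suite

Soft assignments are scored per state by AUPRC — computed with the
stepwise interpolation $\sum_i (\mathrm{Recall}_i - \mathrm{Recall}_{i-1})
\cdot \mathrm{Precision}_i$ over thresholds at the unique score values in
decreasing order, so constant scores give the prevalence — and by AUROC,
computed with the exact tie-corrected rank formula (equivalently
$P(s_+ > s_-) + \tfrac12 P(s_+ = s_-)$). Hard assignments are scored by
accuracy and by per-state Jaccard and F1 averaged with weights proportional
to mean state size in the reference compendium; states absent from both
tracks are undefined and the weights renormalize. Further analyses:
per-state genome fractions (hard counts or soft probability mass);
50-bin calibration curves with the Pearson correlation between bin-mean
predicted probability and observed state frequency; a 100-bin
observed-state composition with a 100-position minimum per bin; fold
enrichment of states in external interval annotations, for hard
assignments and for soft assignments after truncating probabilities below
0.05 and renormalizing; near-miss analysis of incorrect predictions
against a seven-group biological clustering of the 18 states, with the
expected-by-chance proportion computed analytically (a draw from the
retained positions' observed-state frequencies, excluding the predicted
state itself in the all-positions variant) rather than by sampling, which
has the identical expectation but is deterministic; pairwise sample
relationships (overall agreement, per-state binary or soft Pearson) with
within/between-group summaries and a same-group AUPRC; and per-state
signal averaging (e.g. CpG methylation) with a minimum-coverage filter
(default 3).

## The synthetic compendium generator

Real reference compendia are large and access-controlled, so the package
ships a generator that emulates the statistical structure the method
relies on — expression similarity predicts annotation similarity — at
desk scale. Samples belong to latent groups (round-robin, so groups are
balanced). Each group has a prototype state track drawn bin-wise from a
skewed, quiescent-dominant base distribution (half the genome quiescent,
echoing real 18-state segmentations); each sample copies its prototype
except at a fraction `annotation_noise` of bins, resampled from the base
distribution. Expression is lognormal on the TPM scale: gene baselines
$\log_2$-N(3, 2), a fraction `expression_signal_frac` (default 0.2) of
genes carry group-specific offsets with sd 3 (roughly 8-fold
tissue-specific differences — enough that within-group expression Spearman
exceeds between-group by at least 0.2 at the defaults), and samples add
N(0, 0.5) log-scale noise. Everything is deterministic given the seed.
Default scale: 30 samples, 4 groups, 500 genes, 5000 bins, noise 0.1.

**What the generator does not emulate.** Group-mate states are drawn
independently, so there is no biological similarity between states and no
spatial autocorrelation along the genome; expression is not mechanistically
linked to the states near a gene. Consequently, passing tests demonstrate
the pipeline's correctness and its qualitative behaviour (group recovery,
denoising, calibration), not real-data accuracy; and the near-miss
group-enrichment analysis is expected to hover at chance (fold ≈ 1) on
synthetic data because the generator gives it nothing to find. Two
benchmark facts on synthetic data differ from real compendia for the same
reason: samples are conditionally independent noisy copies of their group
prototype, so an ensemble over several same-group references denoises
toward the prototype and can exceed the closest-reference benchmark, whose
agreement with the target is bounded by the pairwise agreement of two
noisy copies.

## Numerical choices

* **Fixed-penalty fits.** A multinomial lasso at a single small $\lambda$
  is unreliable for coordinate descent; fits therefore run down a dense
  60-knot log-spaced path from $\max(0.5, 10\lambda)$ to $\lambda$
  (convergence threshold $10^{-7}$) and read coefficients off the final
  knot. On (near-)separable training data the path saturates — fitted
  probabilities reach 0/1 within machine tolerance — before very small
  penalties; the model then keeps the saturation-point coefficients
  (prediction-equivalent) and records the penalty actually reached as
  `lambda_used`.
* **Small classes.** glmnet rejects multinomial classes with fewer than
  two observations, so states seen at most once in the training subsample
  are treated as untrained (probability 0) and their positions dropped
  from the fit.
* **Ties.** Argmax ties go to the lowest state index; neighbour-ranking
  ties preserve input order; baseline frequency ties use a seeded uniform
  draw; tuning ties prefer the smaller $\lambda$, then smaller $R$, then
  smaller $L$. All choices make reruns bitwise-identical.
* **Missing data.** Bins missing in any annotation a computation touches
  are dropped from that computation (listwise deletion per analysis).
* **Coordinates.** 0-based half-open BED internally; a chromosome's last
  bin may be short and counts as a full-weight position.
* **Undefined quantities** (zero-variance correlation vectors, states
  absent from both tracks, empty calibration bins) are reported as
  missing, never silently as 0.

## Problem sizes

The shipped tests and the reproduction script run entirely on synthetic
compendia: model training on 600–3000-position subsamples of 800–5000-bin
genomes with 12–30 samples, plus one 100,000-bin genome for the calibration
check — sizes chosen so the whole suite completes in a few minutes on one
core while leaving every code path (rare states, untrained classes, path
saturation, tie-breaking) exercised. Full-scale use (a ~15-million-bin
genome, hundreds of reference samples, 100,000 training positions) is a
matter of the same calls with larger inputs; memory scales with
bins × states per model prediction.

## A small worked run

```{r example, eval = FALSE}
cfg <- simulation_config(n_samples = 20, n_groups = 4, n_genes = 300,
                         n_bins = 2000, annotation_noise = 0.1, seed = 7)
comp <- generate_compendium(cfg)
query <- generate_query(comp, group = 2, seed = 99)
res <- impute_states(query$expression, comp, L = 3, R = 3,
                     lambda = 1e-4, n_positions = 1500, seed = 3)
accuracy(res$query$hard, query$annotation)
weighted_state_average(jaccard_per_state(res$query$hard, query$annotation),
                       state_sizes(comp$annotations))
```

## Known limitations

* Accuracy on rare states is limited: they are often untrained in
  individual models and may receive no hard assignment in a sample even
  when the soft assignments detect them in aggregate.
* The method transfers annotations from expression-similar references; a
  query unlike every reference sample degrades toward the compendium
  consensus, with no warning beyond its low neighbour correlations.
* Quantile normalization assumes the query's expression distribution is
  comparable after ranking; strongly truncated assays would violate this.
* The synthetic generator validates machinery, not biology (see above).
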