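---
title: "Methods: supervised tissue-specific TF network mapping"
author: "tfnetmap"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: supervised tissue-specific TF network mapping}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The model

`tfnetmap` treats tissue-specific regulatory network inference as a
supervised classification problem. An *instance* is a candidate (TF,
gene) pair in a tissue; its *label* is whether the TF's ChIP-seq peaks
produce a top-decile binding score in the gene's cis-regulatory elements
(CREs); its *features* are a motif-derived prior edge score and four
expression-derived statistics. A gradient-boosted tree classifier
(XGBoost, logistic objective) is trained per tissue, and the out-of-fold
predicted probability that the TF binds in the gene's CREs is used as the
edge score of the tissue's network.

The design rests on three assumptions. First, binding (direct evidence)
is a better training target than co-expression, which conflates direct
and indirect regulation; using expression-derived *features* to predict
*binding* keeps the functional signal while anchoring predictions in
physical interaction. Second, regulatory effects are not exclusively
linear: a saturating or thresholded TF–target relationship is invisible
to a linear coefficient but not to a sum-of-trees regression, so both
families contribute features. Third, regulation is partly shared and
partly tissue-specific, so each regression family is fit twice — on the
tissue's samples and on all samples pooled.

## Binding labels

Peaks with FDR q-value above 0.01 are discarded (`filter_peaks()`; the
boundary itself is retained). Within each chromosome, transitively
overlapping peaks form a cluster and only the cluster's
highest-confidence peak survives (ties: leftmost start, then input
order); each element is scored as the sum over surviving peaks of
confidence × overlap length in bp, and a gene's score sums its elements'
scores (`score_gene_binding()`). Peak de-duplication is applied globally
rather than within each element: with per-element winners, a gene's
score would change if an annotation release split one element into two
abutting halves while a losing peak fell entirely into one half. Global
clustering makes the score additive over any subdivision of elements,
which we consider the defensible invariant; the overlap-length weighting
(peak-by-element overlap, not full peak length) likewise prevents a peak
spanning two elements from double-counting.

Genes with positive scores are candidate positives; if they exceed
`ceiling(0.10 * n_genes)` for a TF, only the top scorers up to that cap
are labeled 1, with ties broken by gene id so labels are a deterministic
function of scores (`binarize_labels()`).

## Expression-derived features

Counts are CPM-normalized and genes with CPM ≤ 3 in ≥ 98.5% of samples
are removed; the kept set applies to both counts and TPM
(`filter_low_expression()`). Both regressions run on log2(TPM + 1):
the transform is a deliberate choice — raw TPM spans orders of magnitude
and the log stabilizes variance for the linear fit without harming the
tree fit.

*LASSO coefficient* (`lasso_features()`): per gene, an L1-penalized
regression of the gene on all TFs (the gene excluded from its own
predictors when it is a TF), predictors standardized within the fit, the
penalty chosen per gene by 5-fold cross-validation with the 1-SE rule
(a `lambda.min` option exists for analyses that need unshrunk
magnitudes). The feature is the signed coefficient; zeros and absent
pairs are 0.

*Tree relatedness* (`bart_features()`): per gene, a bagged ensemble of
shallow regression trees (default 50 trees, depth ≤ 3, bootstrap
resampling per tree, greedy splits over all TFs). The feature is the
TF's variable-inclusion proportion — the fraction of all splitting rules
in the ensemble that use the TF — the canonical sum-of-trees variable
importance: nonnegative, at most 1, summing to ≤ 1 per gene. Shallow
trees matter here: with deep trees the ensemble keeps splitting on noise
after the signal is exhausted, diluting the proportion.

Per-gene RNG streams are derived by hashing the gene id into the seed,
so feature extraction is invariant to gene order and to which other
genes are in the batch.

## Training and the no-leakage contract

Instances are split into 10 outer folds stratified by label; each outer
training set into 5 stratified inner folds (`make_cv_plan()`).
Hyperparameters (learning rate, depth, boosting rounds, subsampling,
column sampling, minimum child weight, L1/L2 penalties) are tuned per
outer fold by a Tree of Parzen Estimators search (`tpe_optimize()`):
after a default setting (trial 0) and random startup trials, observed
trials are split into a good quartile and the rest, univariate Gaussian
Parzen densities l(x) and g(x) are fit per parameter on the transformed
scale, and the candidate maximizing Σ log l − log g is evaluated next.
The proposal bandwidth tracks the spread of *all* observations so the
kernel cannot collapse onto an early local optimum. The inner objective
is mean average precision across inner folds — labels are ~5–10%
positive, and average precision is the natural objective under that
imbalance. Class weights stay at their defaults.

The final model for each outer fold is fit on its nine training folds
and scores only its held-out fold, so every instance is scored exactly
once by a model that never saw it. `train_and_score()` stores per-fold
training indices and hyperparameters, and `audit_no_leakage()` verifies
the partition; the test suite additionally refits a fold's model from
its stored state and checks bit-identical held-out predictions.

Variant models reuse the same folds so comparisons are paired:
`METANet` (all five features), `ETANet` (expression only),
`META-LASSO`/`META-BART` (one regression family), `META-TSEx`/
`META-TAEx` (one sample scope).

## Evaluation battery

Continuous networks are thresholded to the top `n_TFs × targets_per_TF`
edges globally (ties broken by weight, then TF and gene id), so
individual TFs may exceed or fall short of the average. Four metrics:

* **Binding** — fraction of retained edges with binding support, with
  the analytic random expectation (fraction of supported candidate
  pairs) reported alongside; TFs lacking binding data are excluded from
  both numerator and denominator.
* **GO** — per TF, one-sided hypergeometric over-representation of each
  GO term among its targets; terms with fewer than 5 or more than 300
  annotated genes *within the analysis universe* are skipped (the
  universe-relative count is standard over-representation practice). A
  term is significant at Bonferroni-adjusted p < 0.05 within the TF's
  tested terms; the TF's score is the maximum −log10 p over significant
  terms, 0 otherwise, and the network score is the median across TFs.
  The −log base is 10.
* **GO-directness** — among a TF's retained targets annotated with its
  best term, the fraction with binding support, averaged over TFs that
  have a significant term; with no such TF the metric is undefined and
  reported as missing rather than 0, since averaging in undefined TFs
  would dilute the metric with an arbitrary value.
* **PPI** — Jaccard similarity of target sets for all present TF pairs,
  the fraction of the 100 most similar pairs supported by physical
  interactions (score ≥ 0.7 pairs when scores are present, applied at
  I/O), and the fraction of all present pairs supported as the
  expectation.

Empirical nulls are 50 copies of the full network with edge scores
shuffled across the whole edge set, thresholded identically.

## Tissue specificity

An edge is eQTL-supported in a tissue when one of the tissue's
significant variants for the target gene lies inside an interval that is
both one of the target's elements and one of the TF's retained peaks.
Per network and tissue this yields a support fraction and a count.
Ranking all networks within each tissue (rank 1 = highest metric,
average ranks on ties) and summing the matching-pair ranks gives S_obs;
the null shuffles the network labels once globally per permutation
(10000 by default; an exhaustive mode enumerates all label permutations
for ≤ 8 networks) and p = #{S_perm ≤ S_obs}/n. The p-value is the
literal proportion; a `(b+1)/(n+1)` option exists for users who want the
conservative estimator. Tissues are put in canonical (sorted) order
before sampling so the result does not depend on caller row order.
Paired network comparisons use a two-sided Wilcoxon signed-rank test on
matching ranks, computed exactly (dynamic programming over the possibly
tied ranks) for up to 25 informative pairs and by normal approximation
with continuity and tie corrections beyond.

Tissue-specific edges are called by the IQR rule: per edge, the median
and interquartile range of its weight across tissues (quartiles by
linear interpolation, R's type-7 default — the convention matters near
the threshold and is therefore fixed and documented), and
s(t) = (w(t) − median)/IQR; s > 2 flags the edge in tissue t. Edges with
zero IQR are never flagged — s is undefined there, and calling them
specific would be unfalsifiable — and are reported in a `dropped`
attribute. Filtered tissue-specific networks are evaluated without
top-k thresholding, since their sizes vary drastically across tissues.

## The synthetic world

`simulate_world()` generates, from one master seed split into
independent per-layer streams, a planted network and every evidence
layer the pipeline consumes. The reference ("low-noise") defaults are 20
TFs among 400 genes, 3 tissues, 80 samples per tissue, 5% edge density
(~20 targets per TF), 30% single-tissue edges, 30% nonlinear effects
(hill-type saturation or hard threshold, chosen per edge by seed),
expression noise SD 0.25 on the log2 scale, 5% peak false-negative rate,
~2 spurious peaks per TF, 10% of true peaks given failing q-values, and
motif noise SD 0.2. The false-peak rate is the binding-label noise
floor: each spurious peak creates a positive label with no recoverable
signal, so the default is set where label noise (~10% of positives)
does not dominate the planted signal — that is what "low-noise
reference world" means here. A fifth of TFs form co-regulating pairs
with ~70% shared targets so the PPI layer has true structure.

Per tissue, every true edge's motif score is indicator(active in the
tissue) plus truncated Gaussian noise — so single-tissue edges have
continuous, noisy off-tissue profiles, which is what the IQR filter
consumes in real data — and a fraction of non-edges gets spurious
scores. Expression: TF activities are log-normal; targets sum their
active edges' responses plus Gaussian noise; TPM is the exponentiated
log2 expression in abundance units (deliberately not renormalized per
sample, so that noiseless worlds stay exactly monotone; library-size
variation is emulated in the counts, which are Poisson draws of the TPM
composition scaled to a 2–4M library). eQTLs are planted inside
element-peak intersections of tissue-active edges, with positional
decoys.

What the generator does *not* emulate: genome sequence and motif
content, read-level noise, correlated TF activities, batch effects,
linkage between eQTL variants, and the annotation errors of real
promoter/enhancer maps. Passing the suite therefore demonstrates that
the implementation recovers signal it is designed to recover under its
own assumptions — not that those assumptions hold in any particular
dataset.

## Problem sizes and budgets in the test suite

The test suite exercises the full pipeline on the reference world at its
native size (three seeds), with a 6-trial TPE budget and 30-tree
relatedness ensembles — deliberately small budgets that the acceptance
properties are insensitive to. Exact-oracle checks (brute-force overlap
scans, hypergeometric tail summation, exhaustive sign and label
permutation enumeration) run on instances small enough to enumerate
(≤ 20 peaks, ≤ 5 networks, ≤ 10 tissues). Tissue-specificity recovery
uses a 6-tissue world: with very few tissues the IQR is estimated from
almost no values and the matching-rank test's smallest attainable p is
1/n!, so 6 is about the smallest size at which both properties are
meaningfully testable.

## Known limitations

* Binding labels are tissue-aggregate (as with real ChIP compendia), so
  a tissue's model is asked to score edges whose binding evidence comes
  from other tissues; the tissue-aggregate expression features carry
  most of that signal.
* The relatedness feature is a bagged greedy tree ensemble; unlike a
  fully Bayesian sum-of-trees sampler it provides no posterior
  uncertainty, and correlated TFs split inclusion mass winner-take-all.
* The TPE implementation models hyperparameters independently
  (univariate Parzen estimators); interactions between hyperparameters
  are explored only through the joint candidate draws.
* `threshold_topk()` is global; per-TF target counts are averages, and
  TFs with uniformly weak scores can vanish from thresholded networks.
* The permutation test shuffles network labels once globally per
  permutation; per-tissue independent shuffling would break the
  matched-rank structure and is not offered.
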