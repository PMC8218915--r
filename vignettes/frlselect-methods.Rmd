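---
title: "Two-stage feature selection for expression biomarkers: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two-stage feature selection for expression biomarkers: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Microarray and RNA expression studies of tumour versus normal tissue
typically measure 10,000–22,000 genes on a few dozen samples. Picking the
handful of genes that actually separate the classes — candidate
biomarkers — is a feature-selection problem in the worst regime: tiny m,
huge n, heavy noise. `frlselect` implements a two-stage selector for this
regime: a fast univariate *filter layer* that discards the great majority
of genes, followed by an *embedded layer* in which selection is
interleaved with classifier training, and finally a *consensus* step that
keeps only genes recurring across runs or datasets.

The package consumes normalised expression matrices (for microarrays,
typically the output of RMA background correction run in external
tooling). Background correction and quantile normalisation are
deliberately outside its boundary; `log2_transform()` and
`collapse_probes()` cover the remaining pre-processing the pipeline
needs.

## Filter layer: Fisher score and the inflection cut

Each gene $i$ is scored with the Fisher score
$$
F(x_i) \;=\; \frac{\sum_{k} n_k\,(\mu_k - \mu)^2}{\sum_{k} n_k\,\sigma_k^2},
$$
where $n_k$, $\mu_k$, $\sigma_k^2$ are the size, mean and population
variance of class $k$ for that gene and $\mu$ its grand mean. The
denominator sums class-weighted within-class variances — the standard
form, well defined for any number of classes and matching the per-class
structure of the numerator. A second reading, in which a single pooled
variance $\sigma^2$ over all samples divides the between-class spread, is
available as `denominator = "pooled"`; the two orderings usually agree
closely, but the within-class form is the default because the pooled
denominator also contains the between-class spread and therefore
compresses exactly the scores one is ranking by.

Degenerate genes need guards: a gene constant everywhere scores 0; a gene
constant *within* each class but separated *between* classes has a zero
denominator with a positive numerator, and is scored as
`numerator / 1e-12` capped at `1e12` — effectively "rank first, but keep
arithmetic finite".

Scores are sorted in descending order (ties broken lexicographically by
gene id so the ranking is deterministic) and the ranking is cut at its
inflection point. Score curves from real two-class expression data fall
steeply over the first few hundred genes and then flatten; the elbow of
that curve is a natural, data-driven cut. `detect_inflection()`
implements the max-distance-to-chord rule: both axes are min–max
normalised to $[0,1]$, and the elbow is the point of maximum
perpendicular distance from the curve to the chord joining its first and
last points. The retained head of the ranking is everything strictly
before the elbow, clamped into `[min_keep, max_keep]` (defaults 50 and
4000 — generous bounds around the post-filter dimensionalities seen in
practice, roughly 750–3500). A perfectly linear or flat curve has no
elbow (all chord distances zero) and falls back to `min_keep`. Because
elbow detection is a heuristic on a curve a human would otherwise
eyeball, `rank_genes(keep = N)` provides a manual override.

## Embedded layer: RFE around a from-scratch logistic classifier

The surviving genes (matrix $A_1$, dimension $d_1$) enter recursive
feature elimination (RFE) wrapped around logistic regression:

$$
\varphi(x) = \frac{1}{1 + e^{-(\omega^T x + b)}},\qquad
J(\omega, b) = \frac{1}{m}\sum_{i=1}^{m}
  \big[-y_i \ln a_i - (1 - y_i)\ln(1 - a_i)\big].
$$

The classifier is trained by full-batch gradient descent on $J$ from a
zero start. It is written from first principles rather than delegated to
`glm`, because the embedded layer's feature-importance rule is defined on
this exact optimiser's weight vector and the elimination path must be
reproducible from the documented defaults: learning rate 0.1 (safe for
z-scored features), at most 2000 iterations, stopping when the cost
improves by less than `1e-7`, probabilities clipped at `1e-12` inside the
logarithms, no penalty by default (an optional L2 term is exposed as
`lambda`). The cost trace is retained and verified non-increasing to
`1e-9`; an increase aborts with an error naming the learning rate, since
a too-large step is almost always the cause. The sigmoid clips its
argument at $\pm 700$ and clamps its output strictly inside $(0,1)$, so
saturated samples never produce `Inf`/`NaN`.

Each RFE round fits the classifier on every training fold of a
stratified K-fold split (default $K = 4$; the split is made once and
reused across rounds), z-scoring features with training-fold statistics
only — validation folds are transformed with the training fold's mean
and scale, so no information leaks. The round records the CV accuracy
and F1 of the current feature set from pooled out-of-fold predictions,
ranks features by mean $|\omega|$ across folds (the canonical importance
for linear models), and drops the `pace` least important. The pace is
keyed to the post-filter dimension: 5 when $d_1 > 2000$, 3 when
$1000 < d_1 \le 2000$, 2 when $d_1 \le 1000$ — a coarse-to-fine schedule
that keeps the number of refits manageable at high dimension. At the
open boundaries (exactly 2000 or 1000) the finer pace is taken: a slower
search is never wrong, merely slower.

Two selection modes close the layer. With `target_dim` set (default 78,
the subset size at which classification on data of this shape
saturates), the elimination floor equals the target and the final,
floor-sized step is returned, so the selected subset $A_2$ has exactly
`target_dim` genes — required whenever subsets of fixed size are compared
across methods or datasets. With `target_dim = NULL` the step maximising
CV accuracy is returned, ties resolved toward the smaller set
(parsimony), which suits exploratory use. All remaining ties anywhere in
the pipeline break lexicographically on gene id, so a fixed seed yields a
bit-identical selection.

## Consensus across runs and datasets

Genes that recur across independent selections are more trustworthy than
any single run's list. `stability_select()` reruns the pipeline under
several seeds; `pairwise_recurrence()` intersects every unordered pair of
selection sets and returns the union of those intersections, each gene
annotated with its support — the number of pairs whose intersection
contains it ($\binom{k}{2}$ for a gene present in $k$ of the sets). The
minimum support defaults to one pair and is configurable; no single
threshold is canonical, and raising it trades module size for
reproducibility. Cross-dataset aggregation can fold identifier case
(`harmonize = TRUE`) since symbol capitalisation varies between
platforms; identifiers that still match nothing pass through untouched.

## Evaluation

`confusion_metrics()` computes ACC $=(TP+TN)/(TP+TN+FP+FN)$,
F1 $=2TP/(2TP+FP+FN)$ and precision $=TP/(TP+FP)$ (reported as `NA` when
nothing was called positive). `roc_curve()` sweeps descending unique
scores — a sample is called positive when its score is at or above the
threshold, tied scores collapse to one threshold, the $(0,0)$ and $(1,1)$
endpoints are always present — and integrates by the trapezoidal rule;
under this convention the AUC equals the Mann–Whitney concordant-pair
fraction with ties counted one half, and the Gini index is $2\cdot
\mathrm{AUC} - 1$ identically. `pr_curve()` reports average precision
(step-wise interpolation), which is conservative at small positive
counts. For heatmaps, samples are ordered by average-linkage
hierarchical clustering of their Euclidean distance matrix on the
selected genes; a sharp block structure in the reordered matrix is the
visual signature of a subset that separates the classes.

## The synthetic-data generator

`simulate_expression()` emulates the data shape this selector is built
for: $n$ background genes drawn $\mathcal N(\mu_0, \sigma)$ on the log2
scale in both classes (default baseline 7, noise SD 1 — typical
normalised microarray intensities), and a planted set of informative
genes whose class-1 mean is shifted by `effect_size` noise-SD units. The
default configuration — 2000 genes, 30 + 30 samples, 20 informative
genes at a 2.0-SD shift — was chosen once as a realistic desk-scale
stand-in for a strongly differential two-class series: large enough that
the filter layer has real work to do, small enough that the complete
pipeline runs in seconds. An optional Student-t noise mode (variance
matched to `noise_sd`) stresses robustness to heavy tails.

What the generator does *not* emulate matters for interpreting green
tests: genes are independent (no co-expression blocks or pathway
structure), noise is homoscedastic, there are no batch effects, no
probe-level artefacts, and classes are balanced by default. Recovery of
planted genes under these conditions demonstrates that the machinery —
scoring, cut, elimination, bookkeeping — is correct, not that the
selector will dominate on any particular clinical dataset.

## Validation protocol and problem sizes

The test suite validates each formula against an independently coded
term-by-term oracle (Fisher score on 1000 random fixtures to `1e-10`;
cost gradients against central finite differences to `1e-6` relative on
100 instances; trapezoidal AUC against exhaustive pair counting;
average precision against threshold enumeration; pace-1 elimination
against an independently coded greedy backward-elimination loop on
8-feature instances). End-to-end behaviour is checked on seeded
replicates of the default generator: 20 replicates at 60 samples x 2000
genes with a 40-gene target, requiring median planted-gene recovery of
at least 0.8 and a sign-test win over equal-size random subsets under
the same folds. These sizes keep the full suite within a few minutes on
a single core while leaving each property statistically meaningful.
`scripts/acceptance.R` reruns the same protocol from scratch and writes
the resulting quantities as JSON.

## Known limitations

* The elbow cut is a heuristic; on score curves without a clear knee it
  degenerates to `min_keep`, and judgement-driven per-dataset cuts can
  differ. The `keep` override exists for exactly that case.
* Gradient descent with a fixed step is simple and auditable but slow
  near ill-conditioned optima; with thousands of post-filter genes and a
  low floor the embedded layer is the runtime bottleneck.
* Logistic importance is linear; interactions among genes that are
  individually uninformative are invisible to both layers.
* The consensus rule treats all selection sets symmetrically; it does
  not model differing dataset sizes or qualities.
* Multi-class scoring is defined (the Fisher score sums over classes)
  but the embedded layer is strictly binary.
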