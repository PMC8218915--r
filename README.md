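# frlselect

Two-stage supervised feature selection for labelled gene expression
matrices, aimed at candidate biomarker discovery in the classic
expression-profiling regime: tens of samples, 10k–22k genes, heavy
noise. It is for bioinformaticians and statisticians who have a
normalised tumour/normal expression matrix and want a small,
reproducible, cross-validated gene subset — plus a measure of how stable
that subset is across runs or datasets.

## Method

1. **Filter layer.** Every gene is scored with the Fisher score

   $$F(x_i) = \frac{\sum_k n_k (\mu_k - \mu)^2}{\sum_k n_k \sigma_k^2}$$

   (class sizes $n_k$, class means $\mu_k$, grand mean $\mu$,
   within-class population variances $\sigma_k^2$). Scores are ranked in
   descending order and the ranking is cut at its inflection point
   (maximum distance to the chord of the min–max-normalised curve),
   keeping the steep head — typically a few hundred to a few thousand
   genes out of tens of thousands.

2. **Embedded layer.** Recursive feature elimination around a
   from-scratch logistic regression ($\varphi(x) = 1/(1+e^{-(\omega^T x + b)})$,
   trained by full-batch gradient descent on the mean cross-entropy
   $J(\omega,b)$) under stratified K-fold cross-validation. Each round
   drops the `pace` features with the smallest mean $|\omega|$ across
   folds; the pace is 5/3/2 for post-filter dimensions >2000 /
   1001–2000 / ≤1000. With a target dimension set (default 78) the
   returned subset has exactly that many genes.

3. **Consensus.** Selections from repeated runs or multiple datasets are
   compared in pairs; genes recurring in pairwise intersections form the
   biomarker module, each with a support count.

Evaluation utilities (confusion metrics, ROC/AUC/Gini, precision–recall,
Euclidean-distance clustering for heatmaps) and a seeded synthetic-data
generator with planted differential genes round out the package.

## Worked example

```r
library(frlselect)

# 2000 genes, 30 normal + 30 cancer samples, 20 planted genes shifted by
# 2 noise-SDs in the cancer class
sim <- simulate_expression(sim_config(seed = 7))
sim$matrix
#> ExpressionMatrix: 2000 genes x 60 samples [log2 scale]
#>   labels: 30 normal (0), 30 cancer (1)

res <- run_frl(sim$matrix, frl_config(target_dim = 40), seed = 7)
res
#> Two-stage feature selection result
#>   filter layer: 2000 genes scored, d1 = 50 retained
#>   embedded layer: pace 2, 4 folds, 40 genes selected
#>   held-out folds: ACC 1.0000  F1 1.0000  AUC 1.0000  Gini 1.0000

recovery_score(res$selected_features, sim$informative)
#> [1] 1
```

The filter layer cut the 2000-gene ranking at its elbow (d1 = 50), RFE
eliminated down to the requested 40 genes at pace 2, and the selected
subset classifies the held-out folds perfectly (accuracy, F1, AUC and
Gini all 1) — as it should at this effect size; all 20 planted genes
were recovered. Stability across reruns:

```r
sc  <- stability_select(sim$matrix, frl_config(target_dim = 40), seeds = 1:3)
pairwise_recurrence(sc, min_support = 3)
#> BiomarkerModule: 38 gene(s)
#>    G000001(3) G000002(3) G000003(3) G000004(3) G000005(3) ...
```

38 genes appear in all three runs (support `choose(3,2) = 3`), including
every planted gene.

With real data, replace the simulated matrix by
`read_matrix("series.txt", dialect = "series_matrix")` (or a plain TSV),
`attach_labels()`, optionally `collapse_probes()` and
`log2_transform()`.

A command-line front end over the same functions ships at
`inst/cli/frl.R` with subcommands `simulate`, `rank`, `run`,
`consensus`, `evaluate` and `heatmap`:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli/frl.R", package="frlselect"))')" \
    run --input matrix.tsv --labels labels.tsv --target-dim 78 --seed 1 --out out/
```

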