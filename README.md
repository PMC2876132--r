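# dcim — differential co-expression infinite mixtures

`dcim` is for transcriptomics analysts who suspect that groups of samples in
an expression dataset differ not (only) in expression *levels* but in which
genes are co-expressed with which. It implements an unsupervised Bayesian
nonparametric model that simultaneously discovers:

* **contexts** — groups of samples sharing the same gene co-clustering
  structure (not necessarily similar expression levels),
* **global gene clusters** — genes following one expression pattern across
  all samples — and, within each context, **local clusters** merging
  globally distinct patterns that are indistinguishable there,
* **differentially co-expressed genes** — genes whose co-clustering
  partners change between two contexts, ranked by a score in [0, 1].

## The model in brief

For an N × M matrix X, allocation vectors C (genes → global clusters),
D (samples → contexts) and L (global cluster × context → local cluster)
carry Chinese-restaurant-process priors with concentrations α, β, φ, so no
cluster or context counts are fixed in advance. Expression in each (local
cluster, context, sample) cell is Gaussian with a conjugate
Normal–Inverse-Gamma prior on its mean and variance, both integrated out
analytically. A collapsed Gibbs sampler (`run_chain()`, Rcpp backend)
samples (C, L, D); posterior pairwise probabilities (PPPs — the fraction of
sweeps two items are co-grouped) feed average-linkage dendrograms on the
distance 1 − PPP. The differential co-expression score of gene *i* is

    DCS(i) = max over clusters g from all cut levels of both context trees
             of  sum_{j in g, j != i} |PPP_c1 - PPP_c2|_{ij} / (|g| - 1)

See `vignettes/dcim-methods.Rmd` for the full model, defaults, and design
rationale.

## Worked example

Generate a synthetic dataset in which three planted sample contexts share
*no* expression-level signature (scenario "D": mean signs are flipped in
half the samples), then recover the contexts:

```r
library(dcim)
d   <- generate_scenario(simulation_spec("D", sigma = 0.5, seed = 11))
fit <- run_chain(d$X, chain_config(n_burnin = 300, n_keep = 700, seed = 12,
                                   track_local = "none"))
fit
#> chain_summary: 200 genes x 15 samples, 700 kept sweeps (seed 12)
#>   mean global gene clusters: 6.17; mean contexts: 3.23

sp  <- ppp_from_counts(fit$co_sample_counts, fit$n_kept)
tr  <- average_linkage(sp)
extract_contexts(tr, k = 3)
#> sample_01 sample_02 sample_03 sample_04 sample_05 sample_06 ... sample_15
#>         1         1         1         1         1         2 ...         3

roc_points(tr, d$true_contexts)$auc                          # 1.0
roc_points(baseline_tree(d$X, "pearson"), d$true_contexts)$auc  # 0.547
```

The model recovers the planted contexts perfectly (AUC 1.0, all 15 samples
in their true groups) where Pearson-distance clustering is at chance
(~0.55): expression-level similarity carries no context signal in this
scenario, co-clustering structure does. For differential co-expression,
`local_ppp_per_context()` + `dcs_genes()` rank genes by how much their
co-clustering changes between two contexts; on this design the 40
context-informative genes occupy the top of the ranking.

A command-line pipeline covering the same steps is installed at
`inst/cli/dcim` (`simulate`, `preprocess`, `fit`, `dcs`, `benchmark`), each
run writing a JSON manifest with seed, config and file checksums so any
result can be replayed bit-identically.

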