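# batmodules

Gene-expression-module discovery for clonal brown adipocyte transcriptomes.

Brown adipose tissue harbours functionally distinct adipocyte subtypes, but
clonal preadipocyte lines from a single mouse do not separate into lineages
by hierarchical clustering or PCA of their bulk RNA-seq profiles.
`batmodules` implements a gene-centric alternative: genes are embedded as
points in clone-expression space with a **Laplacian eigenmap** built on a
**Mahalanobis-distance kNN graph**, uninformative genes near the
**geometric median** of the embedding are removed by an exact 1-D 2-means
split of their standardized distances, and the remaining "distal" genes are
grouped into **gene expression modules (GEMs)** by silhouette-guided
k-means. Modules are then screened by

* gene-wise Pearson correlation to per-sample **BATness** scores (an
  externally estimated 0–1 similarity to reference brown fat, consumed as
  an input table),
* a **paired stability screen** selecting genes whose clone profile is
  preserved between the preadipocyte and differentiated state
  (two-sided *p* < 0.05, *r* > 0),
* **hypergeometric gene-set over-representation** with BH adjustment and a
  module–pathway network export.

A negative-binomial clonal-expression simulator with planted modules,
planted stable genes and planted BATness provides ground truth, so the
whole pipeline is testable without external downloads.

## The core computation

Counts are normalized by median-of-ratios size factors, then two quartile
filters run per state: genes whose values all sit at or below the pooled
25th percentile of the matrix, and genes in the lowest variance quartile,
are removed. On the filtered preadipocyte matrix (log2 scale), pairwise
gene distances d(x,y) = sqrt((x−y)ᵀ S⁻ (x−y)) use the pseudo-inverse of the
across-gene sample covariance S. The k = 23 nearest-neighbour graph
(union-symmetrized, binary weights) defines the generalized eigenproblem
L v = λ D v; the first 8 nontrivial eigenvectors embed the genes. Weiszfeld
iteration finds the geometric median; an exact 1-D 2-means on standardized
distances labels genes proximal (removed) or distal; k-means (k-means++,
25 restarts) with a silhouette scan over k = 2..15 assigns modules.
Defaults reproduce the reference settings (k = 23, m = 8, α = 0.05).

## Worked example

```r
library(batmodules)

ds  <- generate_clonal_dataset(synthetic_config(seed = 1))
res <- run_pipeline(ds$counts_pre, ds$counts_diff, ds$batness,
                    config = pipeline_config(seed = 1),
                    truth_labels = ds$true_module_labels)
res
#> pipeline_result
#>   retained genes: pre = 2247, diff = 2249
#>   proximal/distal: 1841 / 406
#>   chosen k = 5; module sizes: M1=111, M2=88, M3=87, M4=61, M5=59
#>   stable genes: 148
round(res$run_record$ari_distal, 3)
#> [1] 0.942
round(res$modules$scan$silhouette_by_k[1:7], 3)
#>     2     3     4     5     6     7     8
#> 0.131 0.153 0.208 0.257 0.232 0.200 0.170
```

Reading the output: of 3000 simulated genes, 2247 preadipocyte genes
survive normalization and the two quartile filters; the 2-means split
keeps 406 distal genes; the silhouette curve peaks at k = 5 — the number
of planted modules — and the recovered module labels agree with the
planted ones at an adjusted Rand index of 0.94 on the distal genes. The
stability screen recovers 148 genes whose clone profile persists across
differentiation (the simulator plants ~30% of module genes as stable).
Per-gene tables (`modules.tsv`, `stable_genes.tsv`, `embedding.tsv`,
BATness correlations, enrichment results) and a `run_record.json` with
config, seed and output checksums are written when `output_dir` is given.

A thin command-line wrapper is installed at
`inst/scripts/gem-pipeline.R` (`simulate` and `run-all` subcommands) for
running the same pipeline from a shell on TSV/GMT inputs.

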