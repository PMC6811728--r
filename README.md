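# markerpanels

Marker gene panel discovery for cell clusters in single-cell (or bulk)
expression data.

Differential-expression tests answer "is this gene's distribution different
in cluster K?". A sorting experiment needs a stronger property: a single
expression cutoff above which the positive cells are mostly cluster K cells,
and below which they are mostly background. `markerpanels` ranks genes — and
2-, 3- and 4-gene AND-combinations — by how well such a threshold isolates a
cluster, the intended use being panel design for flow cytometry or probe
selection.

## The statistic at the core

For gene *G* and cluster *K* (size *m* of *n* cells), sort the 0/1 membership
vector by decreasing expression. At threshold *t* (top *t* cells positive),
enrichment is the hypergeometric tail P(X ≥ k_t) with k_t in-cluster cells
among the top *t*. The XL-mHG statistic is

    S = min{ p_t^HG : 1 ≤ t ≤ L, k_t ≥ X }

with an exact p-value computed by dynamic programming over the
(position, ones-seen) lattice (the minimum is a selection and needs its own
null). Defaults X = ⌈0.15 m⌉, L = min(2m, n): a usable marker must capture
≥ 15% of the cluster, and at most 2m cells may be called positive. The chosen
threshold maps to an expression cutoff with a *slide-up* policy (only values
strictly above the boundary value are positive), every gene also contributes
a negation track (−1 × expression, so absence can be a marker), and panels
combine binarized genes with AND logic, scored by hypergeometric enrichment
plus a Cluster Clear Score for pairs. A Monte Carlo benchmark module
(Gaussian, negative-binomial and noisy Poisson–Gamma engines; Scaled Sum of
Ranks metric) compares the ranking against Welch's t, Wilcoxon, KS, logistic
LRT and tree-ensemble classifiers. See `vignettes/marker-panels.Rmd` for the
full model description and design decisions.

## Worked example

```r
library(markerpanels)
td <- tempfile()
mp_cli(c("fixtures", "--output", td, "--seed", "7"))   # toy dataset
mp_cli(c("run", "--matrix", file.path(td, "matrix.tsv"),
         "--clusters", file.path(td, "clusters.tsv"),
         "--output", file.path(td, "out"), "--panel-sizes", "1,2"))
read.delim(file.path(td, "out/cluster_K/singles/ranked_all.tsv"))[1:3, ]
```

```
      gene rank xlmhg_pvalue threshold_index   cutoff   tp_rate   tn_rate  log2_fc pvalue_rank fc_rank
1 gene0001    1 1.997449e-08               6 2.716752 1.0000000 1.0000000 4.023378           1       5
2 gene0002    2 4.708323e-02               8 1.117993 0.5000000 0.9074074 7.215520           5       1
3 gene0013    3 4.086461e-02               3 1.817672 0.3333333 0.9814815 2.647266           4       6
```

`gene0001` is the planted marker: at its cluster-specific cutoff 2.72 every
cluster cell is positive (`tp_rate` 1.0) and every background cell negative
(`tn_rate` 1.0); the exact XL-mHG p-value is 2.0e-08 at threshold index 6
(the six cluster cells). The final `rank` averages the p-value rank and the
|log2 fold change| rank. Pair tables add the hypergeometric p-value of the
AND-positive set, the Cluster Clear Score in true-negative percent points
(`ccs`), and the averaged `final_rank` — on this two-cluster toy a perfect
single marker leaves nothing to clear, so its pairs sit mid-table while
pairs of weaker leads gain CCS credit, which is the intended behavior of the
score.

The same pipeline runs from the shell via the installed `exec/markerpanels`
script, and `mp_cli(c("simulate", ...))` drives the benchmark engines from a
flat key=value config file.

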