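---
title: "Marker panel discovery with the XL-mHG test: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Marker panel discovery with the XL-mHG test: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(markerpanels)
```

## The problem

Given a clustered single-cell expression matrix, which small set of genes —
read out jointly, with AND logic — isolates one cluster from everything else?
This is not the differential-expression question. A gene can be highly
significantly differentially expressed and still be useless as a sorting
marker, because a marker must support a *threshold*: above the cutoff you
want mostly cluster cells (sensitivity), below it mostly background
(specificity). `markerpanels` ranks candidate single genes and 2-, 3- and
4-gene panels for each cluster by how well a thresholded readout isolates the
cluster, the use case being panel design for flow sorting or probe selection.

## The XL-mHG test

For a gene $G$ and cluster $K$ (size $m$ among $n$ cells), sort the 0/1
cluster-membership vector by decreasing expression of $G$. For a threshold
$t$ (top-$t$ cells called positive), enrichment of $K$ above the threshold is
measured by the hypergeometric tail probability of observing at least $k_t$
cluster cells among the top $t$. The minimal-hypergeometric (mHG) statistic
is the minimum of this tail probability over thresholds; because the minimum
is itself a selection, its null distribution is computed exactly by a dynamic
program over the (position, ones-seen) lattice, giving a proper p-value.

The XL variant constrains the search: thresholds must contain at least $X$
cluster cells (bounding false negatives) and may not exceed depth $L$
(bounding false positives by $L - X$). Defaults are
$X = \lceil 0.15\,m \rceil$ and $L = \min(2m, n)$: a usable marker must
capture at least 15% of the cluster, and the positive population may be at
most twice the cluster. With $X = 0$, $L = n$ the plain mHG test is
recovered.

Numerical choices:

* The DP accumulates the probability mass absorbed into the significant
  lattice region (a sum of positive terms) rather than computing
  $1 - P(\text{avoid})$, which would cancel catastrophically for strong
  markers; the result is clamped to $(0, 1]$.
* Tail probabilities that underflow to 0 in double precision are clamped to
  the smallest normal double, so reported statistics stay in $(0, 1]$.
* The significant-region membership test uses a $10^{-12}$ relative slack so
  that a statistic supplied at slightly different rounding (e.g. a literal
  `1/6`) selects the same region as the internally computed value.
* Ties in expression are ordered background-first ("conservative"): under
  ties, the reported enrichment is a lower bound, never an inflation. The
  ordering is a package decision — the alternative (cluster-first) is
  available as `tie_policy = "optimistic"`.
* The threshold search starts at $t = 1$: an empty top set carries no
  enrichment information.
* Degenerate genes (constant expression) get statistic 1, p-value 1,
  threshold index 0.

## Binarization and single-gene ranking

The chosen threshold index is mapped back to an expression cutoff: the value
at rank $t^\* + 1$, with cells called positive only when *strictly* above it.
This implements the slide-up policy: if the boundary falls inside a run of
tied values, every tied cell is excluded, so a cutoff of zero means
"anything above zero". A consequence is that the positive count can fall
below $X$ when ties are skipped — the only way the 15% true-positive filter
can trigger for a gene that passed the XL constraint.

Every gene also contributes a negation track ($-1 \times$ expression, a
free-standing gene named `<gene>_negation`), so absence of expression can
mark a cluster. Genes are ranked by the average of two competition ranks
("1, 2, 2, 4"): the XL-mHG p-value rank and the |log2 fold change| rank.
The fold change uses a pseudocount $\delta = 10^{-6}$ on the input scale;
for a negation track the parent's fold change with flipped sign is used,
because means of negated values are negative and have no direct log2. Both
conventions are package decisions where the method description is silent.
Filters: genes with true-positive rate < 15% are dropped from the ranked
tables; negation tracks with true-negative rate < 50% likewise. The full
unfiltered statistics table is always written alongside.

## Panels

Panels combine binarized genes with AND logic, so true-positive rates can
only fall and true-negative rates only rise with panel size. For pairs,
co-positive counts for all gene pairs come from two matrix products
$R = \tilde A \tilde A^T$ and $R_{|K}$ (the same restricted to cluster
cells), where $\tilde A$ is the binary matrix restricted to genes with
TP ≥ 15%. Each pair gets a hypergeometric enrichment p-value for its
AND-positive set, and — for the top 1000 hypergeometric-ranked pairs — a
Cluster Clear Score: the summed gain in per-cluster true-negative percent
over the pair's lead gene (the member with the smaller single-gene p-value;
lexicographic tie-break). The final pair rank averages the hypergeometric
rank and the CCS rank. Two open conventions resolved here: CCS ranks are
computed *within* the top-1000 subset, and pairs outside it keep their
hypergeometric rank as the final rank.

Triples and quads use the same construction one level up: a matrix $Q$ of
row-wise ANDs of gene pairs gives triple counts as $Q \tilde A^T$ and quad
counts as the upper triangle of $Q Q^T$, deduplicated to unique gene sets
and ranked by hypergeometric p-value. $Q$ is evaluated in row blocks; block
size does not affect results (asserted in the tests).

The heuristic search restricts candidates to combinations with at least
$m - 1$ members from a core of the top $N$ single genes (all four for
quads; default $N = 50$). Candidate spaces are nested in $N$ and equal the
exhaustive space once $N$ reaches the number of retained genes, so heuristic
top-$k$ agreement with the exhaustive ranking grows monotonically in $N$.

Output caps keep results browsable: a lead gene appears in at most 10
plotted panels and any gene at most 200 times among emitted panels, applied
greedily from the top of the ranking.

## Simulation benchmark

The simulation module is first-class code used to validate the method
against standard alternatives.

**Single-gene engines.** Gaussian: cluster cells $\sim N(\varepsilon, 1)$,
background $\sim N(0, 5)$, cluster fraction 0.1 — the wide background makes
small mean shifts useless for thresholding even when highly significant.
Negative binomial: background counts $\sim NB(1, 0.1)$ (mean 9), cluster
counts $4 + \varepsilon + NB(5, 0.5)$ (mean $9 + \varepsilon$), so the mean
difference is exactly $\varepsilon$.

**Matrix engines** (500 cells, 1000 genes, 10% cluster): 5% good markers,
a configurable fraction of poor markers expressed in only a fraction
(default 10%) of cluster cells at high mean (default 30), the rest
non-markers. The Gaussian engine's good-marker shift defaults to 1 (cluster
$N(1,1)$ vs background $N(0,1)$): the method description prints identical
distributions for both clusters, an evident typo; a shift of 1 is the
reading consistent with the companion count model (good markers only
twofold above background) and preserves the benchmark's point — poor
markers with huge fold change mislead fold-change-driven and
classification-driven rankings, while the $X$ constraint shields the
XL-mHG ranking, since poor markers cover less than 15% of the cluster. With
a large shift every method ranks the good markers perfectly and the
comparison degenerates.

The noisy Poisson–Gamma engine emulates UMI count data: per gene and
population a mean is drawn from $\Gamma(\alpha, \beta = 0.1)$, true counts
from Poisson, then a per-cell efficiency factor
$s_i \sim U(1 - e, 1 + e)$ ($e = 0.2$) scales the counts, which are
Poisson-resampled — efficiency noise plus sampling noise. The printed shape
shorthand is read as powers of two (good markers $2^5$ in-cluster vs $2^4$
background; poor markers $2^{10}$ inside their expressing subset); all
shapes are free parameters of `pg_config()`. What the generators do *not*
emulate: library-size normalization artifacts, dropout beyond Poisson
sampling, correlated genes, batch effects, more than two clusters. A green
simulation test therefore establishes correct behavior under the stated
generative world, not on any particular real dataset.

**Comparators and metric.** Welch's t, Wilcoxon rank-sum (normal
approximation, no continuity correction, matching `scipy.stats.ranksums`),
Kolmogorov–Smirnov, and the logistic-regression likelihood-ratio test.
Tree ensembles (random forest and extra trees, 250 trees, $\sqrt p$
features per split, Gini importance) come from scikit-learn through a
bundled Python bridge — the established implementation route; no R forest
package is assumed. Rankings are scored with the Scaled Sum of Ranks,
$SSR = \frac{2}{s(s+1)} \sum_{j=1}^s \mathrm{rank}_j$, which is 1 exactly
when the $s$ good markers fill the top $s$ positions and is invariant to
permutations among them.

## Known limitations

* Exhaustive triple/quad enumeration is $O(\tilde p^3)$/$O(\tilde p^4)$ in
  memory-bounded blocks; for thousands of retained genes use the heuristic.
* OR-logic and mixed panels, panels beyond size 4, and multi-class (>2
  group) extensions of the threshold test are out of scope.
* The DP p-value is exact but assumes exchangeable cells under the null;
  structured backgrounds (batch, depth) are the caller's responsibility to
  normalize away.
* Two effect-size anchors in the source description ("close to 4" vs
  "approximately 3.6" for the Gaussian crossing) depend on an unprinted
  sample size; the benchmark exposes $n$ and the acceptance checks treat
  the crossing as approximate (one grid step).
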