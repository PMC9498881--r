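---
title: "Methods: multigraph min-max cut clustering of SNP brain-association profiles"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multigraph min-max cut clustering of SNP brain-association profiles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(snpmincut)
```

This vignette documents the statistical model behind `snpmincut`, the
tunable parameters and their defaults, the numerical choices inside the
solver, what the synthetic-data generator does and does not emulate, and
the package's known limitations.

## The model

### Stage 1: covariate-adjusted association mapping

For a SNP with additive dosage $g \in \{0,1,2\}$ and an ROI quantitative
trait $y$, we fit by ordinary least squares

$$ y = \alpha\, g + \Gamma Z + \epsilon, $$

where $Z$ holds the nuisance covariates (age in years, sex as 0/1,
education in years) plus an intercept. The map entry for the pair is
$-\log_{10} p$ from the two-sided $t$-test of $\alpha \ne 0$. Design
choices:

* **Intercept always included** — without it the covariate block cannot
  absorb the trait mean and $\alpha$ would be biased.
* **Diagnosis is not a covariate.** The cohort (cases plus controls)
  defines *who* is analyzed; disease status is the phenotypic contrast of
  interest, not a nuisance. The covariate list is configurable for users
  who prefer otherwise.
* **Missing dosages are dropped pairwise per SNP**, maximizing the usable
  sample per pair, as in common GWAS practice.
* **Cap at 300**: $-\log_{10} p$ is truncated at 300, the edge of double
  underflow, so map entries are always finite.
* **Degenerate pairs** (zero-variance dosage in the cohort, rank
  deficiency) record $p = 1$, i.e. map entry 0, with an aggregated
  warning — one bad SNP must not abort a 54 × 116 map.

Each SNP row is then rescaled to unit Euclidean norm, making every SNP a
*direction* in ROI space. All-zero rows (possible only if every $p = 1$)
are left at zero and flagged rather than divided by zero.

### Stage 2: five similarity views

Pairs of normalized profiles are scored by Pearson correlation, Spearman
correlation (average ranks on ties), cosine similarity, and Manhattan and
Euclidean distance. Correlations and cosine are folded by absolute value;
distances are mapped through a Gaussian radial basis function

$$ s(i,j) = \exp\!\left(-\tfrac12 \left(\frac{d(i,j) - d_{\min}}{\sigma}\right)^2\right),
   \qquad \sigma = \frac{d_{\max} - d_{\min}}{3}. $$

Two numerical points deserve emphasis:

* $d_{\min}$ and $d_{\max}$ are taken over **all** entries including the
  zero diagonal, hence $d_{\min}=0$ and the kernel is genuinely centered at
  distance zero; the largest observed distance maps to
  $\exp(-4.5) \approx 0.0111$. An implementation that excluded the
  diagonal would shift the whole kernel; we flag this because the
  difference is silent and systematic.
* The bounded raw scores are clamped into $[-1, 1]$: floating-point cosine
  of exactly proportional vectors can exceed 1 by an ulp, and the clamp
  makes the "direction measures score proportional profiles as exactly 1"
  property hold identically.
* If all pairwise distances are equal ($d_{\max}=d_{\min}$) the similarity
  is defined as 1 everywhere — the degenerate case carries no information
  to spread.

Zero-variance profiles, for which correlations are undefined, get weight 0
(maximal dissimilarity) with a warning; the diagonal is forced to exactly 1
after every transform, which the downstream silhouette distances and the
positivity of the within-cluster weight $q_k^\top A q_k$ both rely on.

### Stage 3: multigraph min-max cut

Given $m$ views $A_v$ with degree matrices $D_v = \mathrm{diag}(A_v
\mathbf 1)$, the K-way partition minimizes

$$ J = \sum_{v=1}^m \sum_{k=1}^K
   \frac{q_k^\top D_v q_k}{q_k^\top A_v q_k}, $$

with $q_k$ the indicator of cluster $k$. Since
$q_k^\top D_v q_k = q_k^\top A_v q_k + \mathrm{cut}_v(k)$, every term is at
least 1 and $J \ge mK$ with equality exactly at a zero cut — this bound
doubles as a self-test on random instances. "Diagonal matrix of A" is read
as the **degree matrix**, the standard min-max-cut convention; the literal
alternative ($\mathrm{diag}(A_{ii}) = I$ here) would make the objective a
constant-free ratio with no cut interpretation.

The solver:

1. **Initialization.** Spectral embedding of the view-averaged
   symmetric-normalized adjacency $\bar D^{-1/2}\bar A\bar D^{-1/2}$ (top
   $K$ eigenvectors, rows normalized), then seeded k-means
   (`stats::kmeans`, 10 restarts under the caller's seed). The smoothed
   indicator $H + 0.2$ is projected to the feasible set.
2. **Projected gradient descent** on the relaxed objective with
   denominator guard $\varepsilon = 10^{-12}$ (relaxed columns can have
   near-zero support mid-descent). Steps use backtracking line search and
   only non-increasing steps are accepted, giving a testable monotonicity
   contract; descent stops when the relative change drops below `tol`
   (default `1e-6`) or at `max_iter` (default 1000).
3. **Projection.** A nonnegative matrix with orthonormal columns must have
   disjoint row supports, so the projection keeps each row's largest
   entry, rescues any emptied column with its best-aligned row, and
   rescales columns to unit norm — both constraints then hold exactly
   (the Gram error is at machine precision, well inside the $10^{-6}$
   contract).
4. **Discretization** by row argmax, ties toward the lowest cluster index
   for determinism.
5. **Empty-cluster repair.** Clusters are explicitly required to be
   nonempty: any empty cluster is filled by moving, one node at a time,
   the node whose transfer least increases the hard objective (evaluated
   over the currently nonempty clusters), donors keeping at least one
   node.
6. **Greedy polish.** A deterministic single-node local search on the hard
   objective (the classic Kernighan–Lin-style cleanup) runs after
   discretization. The relaxed optimum can discretize to a locally
   suboptimal hard partition on weakly structured instances; greedy moves
   only ever decrease the hard objective and close most of that gap — on
   random 8-node two-view instances the final objective stays within 5% of
   the exhaustive global optimum (typically within 1%). Disable with
   `refine = FALSE` to inspect the raw discretization.

Cluster labels are canonicalized by first occurrence, so the same partition
always prints the same way. Under SNP reordering the *partition* is
equivariant; the k-means restarts mean the raw label numbers may differ
before canonicalization, which is why tests compare partitions (adjusted
Rand index 1), not label vectors.

The exhaustive enumerator (`minmax_cut_exhaustive`) walks all set
partitions into exactly $K$ nonempty blocks via restricted growth strings;
it refuses instances beyond $S = 15$, $K = 3$, and exists purely as a
correctness oracle.

### Stage 4: silhouette model selection

Similarities become distances by $d = 1 - s$. Per SNP,
$a(i)$ is the mean intra-cluster distance (excluding self), $b(i)$ the
minimum over other clusters of the mean distance, and
$s(i) = (b - a)/\max(a, b)$; members of singleton clusters score 0, the
standard convention. For each $K$ the per-cell mean silhouettes are
averaged over the whole (measure × cohort) grid — 25 cells in the full
five-measure, five-cohort design. The **same multigraph assignment** is
scored against all of a cohort's measure networks; single-graph mode
re-clusters per measure and is provided for comparison.

Selection prefers small $K$: the chosen $K$ is the smallest one whose
averaged score is within `tolerance` (default 0.01) of the maximum. The
tolerance operationalizes "similar scores" explicitly rather than leaving
it to visual judgement; at `tolerance = 0` the rule is the exact argmax
with ties to the lowest $K$.

### Stages 5–6: annotation exports

Mean brain patterns are computed on the **normalized** map (so each SNP
contributes a direction, not a magnitude) as the plain arithmetic mean of
member rows; consequently the whole-panel pattern equals the cluster-size
weighted mean of cluster patterns, which is asserted in tests. Gene lists
are produced from a user-supplied SNP→gene table (closest gene upstream or
downstream, as such tables are usually built), deduplicated and sorted, with
unmapped SNPs reported separately. There are deliberately no live web
queries: enrichment and brain-map services consume the exported files.

## The synthetic-data generator

`simulate_cohort()` emulates the *shape* of a candidate-panel
imaging-genetics cohort: per-SNP binomial genotypes
$g_{ij} \sim \mathrm{Bin}(2, \mathrm{MAF}_j)$; covariates age
$\sim N(75, 6)$, sex $\sim \mathrm{Bernoulli}(0.5)$, education
$\sim N(16, 2)$ (plausible for an elderly memory-clinic cohort; any fixed,
documented choice suffices for testing); diagnosis labels drawn
independently of genotype with proportions AD 0.208, LMCI 0.225, EMCI
0.305, HC 0.262 (a typical four-group case–control composition); and a
burden-style genetic signal: every ROI in cluster $c$'s signature receives
`effect_size` $\times \sum_{j \in c} g_{ij}$, plus covariate effects, plus
$N(0, \texttt{noise\_sd})$ noise.

**Why the default MAF range is (0.2, 0.45).** Under the burden model the
marginal regression of a signature ROI on one SNP treats the rest of the
cluster's burden as noise, so the per-SNP $t$-statistic is bounded by
$\sqrt{n\,\mathrm{var}(g_j)/\sum_{j' \ne j}\mathrm{var}(g_{j'})}$
*independently of effect size and noise level*. With 27-SNP clusters and
$n = 500$, a MAF-0.05 variant caps at $|t| \approx 2$ — indistinguishable
from noise — while common variants (MAF ≥ 0.2) give every SNP $|t| > 3.5$.
Real candidate panels are common GWAS index variants anyway, so the default
generates common alleles; the full admissible range remains available.

**What the generator does not emulate** — and therefore what passing tests
do *not* establish about real data: no linkage disequilibrium (SNPs are
independent, whereas real panels are correlated), no population
stratification, no spatial covariance among ROIs (real atlas regions are
strongly correlated), diagnosis independent of genotype (no case–control
confounding), homoscedastic Gaussian noise, and disjoint ROI signatures
(real variant groups overlap in their brain targets). Recovery of planted
clusters shows the pipeline is *internally correct*, not that two clusters
exist in any particular real cohort.

## Validation problem sizes

The test suite exercises: the solver against exhaustive enumeration on
20 random instances of 8 nodes × 2 views × $K{=}2$ plus zero-cut planted
instances (where it must attain the $mK$ bound exactly); the regression
path against a closed-form normal-equations + $t$-CDF oracle on 100 random
fixtures at $10^{-8}$; and the full pipeline on 20 synthetic cohorts of
500 subjects × 54 SNPs × 116 ROIs with two planted clusters, requiring
$K{=}2$ selection with perfect partition recovery in at least 18 of the 20
cohorts. On the two occasional imperfect cohorts the solver's objective is
*better* than the planted partition's — the map itself, not the solver,
favours the deviating assignment, which is the expected behaviour of
sampling noise at this effect size. These sizes keep the whole suite
around half a minute while still covering every contract.

## Known limitations

* Dense networks only: no sparsification or k-NN graphs, so memory is
  $O(S^2)$ per view — fine for candidate panels, not for genome-wide SNP
  sets.
* The solver is a local method; global optimality is only verified at toy
  sizes. Multiple seeds are cheap and advisable for small or weakly
  structured panels.
* One run covers one modality and one phenotype table; cross-modality
  comparisons are scripted over runs.
* No mixed models, kinship adjustment, or multiple-testing correction: the
  pipeline deliberately consumes raw per-pair p-values, because the map is
  an intermediate representation, not an inferential endpoint.
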