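---
title: "Methods: co-occurrence networks, Laplacian gene scoring, and annealed module search"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: co-occurrence networks, Laplacian gene scoring, and annealed module search}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(drivermod)
```

## The model

`drivermod` treats driver-gene discovery as an unsupervised network
problem. The only modeling assumption about the biology is that driver
genes occupy distinctive positions in the *mutation co-occurrence
network*: genes that are mutated together across many patients, or that
bridge groups of co-mutated genes, carry information that per-gene
mutation frequency does not.

### The mutation network

For a catalog of (case, gene) incidence records, `C(g)` is the set of
cases carrying a mutation in `g`. Two genes are adjacent iff they share at
least one case, with weight

$$\omega(g_i g_j) = \frac{|C(g_i) \cap C(g_j)|}{\min\{|C(g_i)|, |C(g_j)|\}} \in (0, 1].$$

Normalizing by the *smaller* case count makes the weight a containment
index: a rare gene whose few cases all also mutate a common gene is fully
connected to it (ω = 1), which is exactly what lets infrequently mutated
genes compete. A gene mutated by several distinct variants in one case
counts once — the catalog is an incidence structure, not a variant table.

A path's cost is the **sum of the ω along it**, and `d_w` is the minimum
cost. This is the method's stated path semantics, and it is deliberately
unusual: ω is a similarity, so minimum-cost paths prefer *weak* edges.
The consequence is that closeness and betweenness are highest for genes
embedded among weak co-occurrences, i.e. they pull in a direction opposite
to strength, PageRank and eigenvector centrality. We keep this semantics
as the default (`cost = "raw"`) because the downstream behavior of the
whole pipeline — partial rather than saturated recovery of planted drivers,
see below — only emerges with it; a conventional similarity-to-distance
transform (`cost = "inverse"`, edge cost 1/ω) is available for users who
prefer classical centralities.

### The six features

Per node: strength (sum of incident ω); closeness `(r−1)/Σ d_w` within the
node's `r`-node component (unreachable pairs are excluded rather than
imputed — no convention for them is stated, and exclusion keeps the value
finite without a magic constant); unnormalized betweenness with
minimum-cost paths counted multiply (Brandes semantics — interpreting the
path-ratio as a count ratio is the only reading under which a pair with a
unique shortest path contributes a well-defined term); a PageRank variant
`PR_i = (1−d) + d\sum_j (\omega_{ij}/s_j) PR_j` with `d = 0.85`, iterated
from all ones — note the anchor is `(1−d)`, not `(1−d)/n`, so an isolated
node scores exactly 0.15 and a regular graph fixes PR ≡ 1; eigenvector
centrality as the Perron vector of the weighted adjacency, computed per
connected component, unit Euclidean norm, nonnegative, with isolated nodes
at 0; and the entropy effect
`ε(g) = |En(G) − En(G \setminus g)|` where `En` is the Shannon entropy
(natural log — the log base only rescales the feature by a constant) of
the node-strength distribution.

Numerical choices: PageRank stops at a max-change below 1e-10 (cap 1000
iterations, warning on non-convergence); the power iteration applies a
positive diagonal shift `1 + max strength` so that bipartite components —
where the extreme eigenvalues ±λ tie in magnitude and the unshifted
iteration oscillates — converge to the Perron vector; `0·ln 0 = 0` in the
entropy; the entropy effect is computed by subtracting the removed node's
column from the strength vector rather than rebuilding graphs, which makes
the per-node sweep O(n²) overall.

### Laplacian gene scoring

Given the m×6 feature matrix X, an affinity graph over *genes* is built:
`s_ij = exp(−|p_i − p_j|²/t)` when the Euclidean distance between feature
vectors is strictly below δ, else 0 (`δ = 5`, `t = 100`). With `D` the
diagonal of row sums and `L = D − S`, each feature's score is the Rayleigh
quotient of its D-centered column,
`L_j = F̃_j' L F̃_j / F̃_j' D F̃_j`, and each gene's score is
`LS(g_i) = Σ_j x_{ij} L_j` on the same matrix. High `L_j` is treated as
high importance — the method uses the score to *weight* features into the
gene aggregate, not to discard smooth features as canonical Laplacian-score
selection would.

**Features are left unscaled by default.** δ and t are magnitude-coupled
parameters: on raw features (strengths of order 20–50, closeness of order
2–5) the δ = 5 ball is genuinely selective and the heat kernel
discriminates. If the columns are first compressed to [0, 1], every
pairwise distance is at most √6 ≈ 2.45 < δ, S becomes a complete
near-uniform affinity matrix, every `L_j` collapses to ≈ 1, and the gene
score degenerates to an unweighted row sum — the feature weighting stops
doing anything. On the planted-driver simulation this degeneracy is
visible directly: scaled features recover 19–20 of 20 planted genes (the
row sum is trivially separating), unscaled features recover a median of
12, which is the method's published single-run behavior on that design.
`scaling = "minmax"` and `"zscore"` remain available, applied column-wise
after the raw computation.

Degenerate cases: constant feature columns get `L_j = 0`; if every gene is
isolated in the affinity graph (`L = 0`) all scores are 0. Ties in LS are
broken lexicographically by gene symbol so ranks are deterministic.
Selection keeps genes with LS *strictly* above the mean (`above_mean`) or
the best k (`top_k`); the infrequent flag is a strict `|C(g)| < 100`.

## The module search

The biological graph places the top-N genes as nodes, joined when they
share a biological-process term or interact physically (union of the two
evidence sources), each node weighted by its LS. A *module* is a connected
subgraph balancing high mean LS with high density; finding the optimum is
NP-hard, so a simulated-annealing seed expansion (the MG heuristic) is
used.

From a seed, each cooling step proposes the highest-LS neighbor of the
current module (ties lexicographic). It is accepted outright when its LS
exceeds the module's mean, otherwise with probability
`exp((W(g) − W(S))/T)`; a uniform draw is consumed every step so the
random stream is independent of which branch fires. The temperature cools
geometrically, `T ← 0.9 T`, from 10 down to 0.01 — 66 steps, so a module
never exceeds 67 genes. The printed loop guard in the source algorithm
("while T < T_low") can never execute with T starting above the floor; we
run the loop while `T > T_low`, which matches the prose description of
repeated probabilistic additions with decreasing likelihood. A candidate
rejected at one temperature may be proposed again at a lower one. At
exact weight equality the acceptance probability is `exp(0) = 1`, an
implementation-forced consequence of the formula.

`find_modules()` takes seeds in decreasing LS among nodes not yet placed
in any module, but expansion may absorb genes that already belong to
earlier modules — modules overlap, only seeds must be fresh, which mirrors
how hub genes recur across published driver modules. Results are ordered
by mean LS. All stochasticity flows from a single integer seed, so a run
is bitwise reproducible.

## Evaluation statistics

* **Benchmark agreement**: the benchmark set is intersected with the gene
  universe before counting TP/FP/FN/TN; precision, recall and F follow the
  standard formulas, with degenerate denominators returning 0 plus a
  warning.
* **Exceeding value (EV)**: 1000 uniform gene subsets of the module's size
  are drawn from the top-gene pool — node subsets, connectivity *not*
  required, since the null is "an arbitrary same-size selection of top
  genes". A sample exceeds when it strictly beats the module in both mean
  LS and induced density; EV is the exceeding fraction and the module is
  significant when EV < 0.05. The reference values are the tested module's
  own statistics (the null asks how often a random set performs better
  than *this* module), not the sample averages.
* **Enrichment**: the hypergeometric point probability
  `C(K,k) C(N−K, n−k) / C(N,n)` is reported verbatim, alongside the
  upper-tail `P[X ≥ k]`, which is the conventional enrichment p-value and
  the headline number. No multiple-testing correction is applied by
  default.
* **Co-mutation counts**: per primary site, the number of cases mutated in
  at least `min_genes` (default 2) of a module's genes, plus each gene's
  mutated-case fraction partitioned at 10%.

## The synthetic generator

`simulate_catalog()` reproduces the planted-driver study design: 20
"related" genes mutated independently in each of 200 cases with
probability 0.40, 80 background genes at 0.20. Every (gene, case) pair is
an independent Bernoulli draw — the design states per-class rates and
nothing else, so no case-level mutation budget and no mutual-exclusivity
structure is imposed. That also delimits what the recovery experiment can
show: it validates that the pipeline finds *rate-elevated, co-occurring*
gene groups, not that it separates mutually exclusive driver pathways, and
real catalogs additionally have heavy-tailed per-case mutation loads and
site-specific structure that the generator does not emulate.

`recovery_experiment()` runs simulate → network → features → LS → top-20
and counts planted genes. Across 25 seeds the median is 12 (interquartile
range about [10, 13]) under the defaults, 4 under equal rates (the
exchangeable null), and 20 under extreme separation (rates 1 and 0.01).

## Problem sizes and test design

The test suite validates closeness and betweenness against exhaustive
simple-path enumeration on graphs of up to 8 nodes (edge weights drawn
from dyadic rationals so tied path costs compare exactly), PageRank
against a dense linear solve, eigenvectors against their residual
equation, and the Laplacian scores against an independent loop-written
dense reference at 1e-12. The annealing search is compared to exhaustive
enumeration of connected subgraphs on planted-clique fixtures of at most
10 nodes, best of 50 seeded runs. Entropy bounds are checked on 1000
random graphs of up to 10 nodes, and the recovery experiment uses the full
100-gene × 200-case design over 25 seeds. These sizes keep every oracle
exact (enumeration, not approximation) while the full suite runs in under
a minute.

## Known limitations

* The summed-similarity path semantics makes closeness/betweenness values
  hard to compare with conventional weighted centralities; use
  `cost = "inverse"` when comparability matters more than fidelity.
* Betweenness path counting on floating-point costs treats near-ties as
  distinct; fixtures avoid this with dyadic weights, but real data can
  have exactly tied alternative paths only up to rounding.
* The annealing heuristic offers no optimality guarantee beyond the
  tested fixture scales; `restarts` trades time for quality.
* The EV null samples with equal probability over gene subsets; it does
  not condition on degree or connectivity.
* The generator's independence assumption means planted "modules" are
  co-occurrence clusters only; it cannot benchmark mutual-exclusivity
  detection.
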