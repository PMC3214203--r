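---
title: "Co-expression networks: inference, null models, communities, enrichment"
author: "geconet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Co-expression networks: inference, null models, communities, enrichment}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(geconet)
```

# The model

geconet treats a transcriptional experiment as a genes-by-samples matrix and
asks which gene pairs move together across conditions. Similarity is the
Pearson correlation coefficient (PCC) of the two expression profiles; a
network is obtained by keeping every pair with `|r| >= tau` as an edge of an
undirected simple graph. The threshold is inclusive, and thresholding is on
the magnitude by default so that strongly anti-correlated genes — which are
just as informative about co-regulation — are linked too; the signed `r` is
retained as the edge weight so downstream consumers can still distinguish
activation-like from repression-like co-expression, and export can strip
weights when an unweighted network is wanted.

Everything downstream speaks one currency, the `Graph` S4 class: a canonical
edge list over opaque string identifiers, no self-loops, no duplicates, all
orderings lexicographic. Canonical representation is what makes every writer
byte-stable, which in turn is what makes pipeline reruns byte-identical —
determinism here is a contract, not an accident.

# Topology and what "non-random" means

Global statistics (average degree, link density, diameter, mean shortest
path) and local ones (degree, Brandes betweenness, local clustering
coefficients, degree assortativity) are all computed natively on the
unweighted graph. Conventions worth knowing:

* **Diameter on disconnected graphs** is the diameter of the largest
  component, with a warning. Thresholded co-expression networks are usually
  disconnected, and a single scalar is what gets reported and compared.
* **Betweenness** is unnormalized by default, summed over unordered pairs
  with endpoints excluded; unnormalized values are what the null-model
  z-scores consume. A normalization flag applies `2/((n-1)(n-2))`.
* **Global clustering** is the average of local coefficients
  (Watts–Strogatz), with nodes of degree < 2 contributing 0; the
  triangle-to-triad transitivity is available separately because the two
  diverge on hub-dominated graphs.
* **Assortativity** is the Pearson correlation of end degrees over the
  directed expansion of the edge list. On regular graphs the end-degree
  variance is zero and the quantity is undefined; we return `NA` with a
  warning rather than a silent `NaN`.
* **Scale-free assessment** is a least-squares fit on `(log k, log p(k))`
  with the slope magnitude and R² reported, and "scale-free-like" attached
  only as a descriptive label at R² >= 0.8. It is explicitly not a
  maximum-likelihood power-law test with cutoff selection; it answers "does
  a line describe the log-log histogram", nothing stronger.

Whether an observed topology is "non-random" is answered empirically: a
`NullEnsemble` holds replicate random graphs, per-metric null distributions,
z-scores `(obs - mean_null)/sd_null`, and percentile ranks. A zero-spread
null (e.g. rewiring a cycle, whose degree sequence determines it up to
isomorphism) flags the z-score as undefined instead of dividing by zero.
Significance wording is left to the user — with 10 replicates a z-score is a
signal, not a p-value.

# Null models

Three generators, all explicitly seeded:

* **Degree-preserving rewiring** (Maslov–Sneppen): `round(10 |E|)` attempted
  double-edge swaps `(a,b)+(c,d) -> (a,d)+(c,b)` by default; swaps creating
  self-loops or duplicates are rejected but still count as attempts, keeping
  runtime linear and the RNG stream reproducible. Ten attempts per edge is
  the common practice for this model; the degree sequence is preserved
  exactly, by construction. Connectivity is not enforced after rewiring.
* **Erdős–Rényi**, both `G(n,m)` (uniform without replacement, exact edge
  count) and `G(n,p)` (independent pairs).
* **Planted modular graph**: `k` near-equal modules, `round(avgDegree*n/2)`
  edges, a fixed fraction placed within modules; the ground-truth partition
  is returned so recovery can be scored. This planted-partition
  parameterization (k, average degree, intra-module fraction) is our
  reading of the usual random-modular-graph construction.

Replicate `i` of an ensemble uses `masterSeed + i`, so ensembles are
reproducible as a whole and replicates are independent streams.

# Community detection

Four native algorithms return the same canonical `Partition` (clusters
numbered by decreasing size, ties by smallest member):

* **Greedy agglomeration (CNM)** merges the connected community pair with
  the largest modularity gain until no gain is positive. Ties are broken by
  the lexicographically smallest (min member, max member) pair, so the
  algorithm is deterministic without a seed.
* **Louvain** does local moving plus aggregation at resolution 1; the seed
  shuffles only the visit order. Internally the aggregated super-graph is
  weighted with self-loops, as the algorithm requires; the reported Q is
  always the unweighted Newman–Girvan modularity on the input graph, so the
  two heuristics are directly comparable.
* **MCL** alternates expansion (matrix squaring) and inflation (entrywise
  power + column renormalization) on the column-stochastic walk matrix with
  unit self-loops (standard practice; prevents parity oscillation). Pruning
  at 1e-5 and a 1e-8 max-norm convergence threshold are desk-scale
  stability choices, exposed as arguments. MCL's attractor systems may
  overlap; a node claimed by two systems goes to the lower cluster index
  (with a reported count) because the enrichment flow needs a hard
  partition. Dense matrices are used; this is intended for networks up to a
  few hundred nodes.
* **Spectral bisection** splits by the sign pattern of the Fiedler vector
  of the unnormalized Laplacian (dense symmetric eigensolver; fine to ~500
  nodes). Eigenvector sign is normalized so the first nonzero entry in node
  order is positive, and entries within 1e-10 of zero join the non-negative
  side — the zero-entry convention had to be fixed somewhere, and fixing it
  by sign normalization keeps the split deterministic. Disconnected input
  is an error directing the user to per-component application, since the
  Fiedler value of a disconnected graph is 0 and the "bisection" would just
  re-discover components.

Modularity itself is `Q = sum_c [e_c/m - (d_c/2m)^2]`, unweighted; tests
verify it against the equivalent double-sum form on exhaustive small cases,
and both heuristics against the exhaustive-search optimum over all set
partitions of small graphs (they may fall short of the optimum on rare
instances — the test asserts >= 90% attainment and never exceeding it).

# Enrichment

Cluster function is scored by the one-sided hypergeometric upper tail: a
cluster of size `n` in a universe of `N` genes, `K` of which carry a term,
containing `k` carriers, gets `P(X >= k)`. The default universe is the
intersection of network genes with annotated genes — using all annotated
genes would reward clusters merely for being in the network, and using all
network genes would deflate `K` for sparsely annotated schemes. Both
alternatives are available. Benjamini–Hochberg correction is applied across
all cluster-term tests jointly; raw p-values are always reported alongside.
Clusters below 5 in-universe genes are skipped by default — single-gene
"enrichment" is degenerate. Only over-representation is tested.

# The synthetic generator

`simulateModularExpression` draws one latent standard-normal sample profile
per module and sets each member gene to
`sqrt(w)*latent + sqrt(1-w)*noise`, noise independent per gene. This is the
simplest generator whose population within-module PCC is exactly `w`,
making every statistical expectation in the tests computable by hand;
between-module correlation is 0 in expectation. A sign-flip option loads
half of each module negatively so that `|r|` thresholding is exercised.
What it does **not** emulate: probe- or batch-effects, count noise,
mean-variance coupling, overlapping modules, or correlated latent factors.
Tests passing on this generator therefore demonstrate algorithmic
correctness and pipeline integrity, not robustness to real microarray or
RNA-seq noise.

Default study conditions used by tests and the acceptance script: 120
genes, 4 modules, 40 samples, within-module correlation 0.8, threshold
`tau = 0.6`; the planted modular graph for community recovery uses n = 100,
k = 4, average degree 10, intra-fraction 0.9. Oracle-equivalence checks run
exhaustively over all labeled connected graphs on up to 5 nodes plus
fixed-seed random 6–7-node graphs (all labeled 7-node graphs would number
2^21 — the exhaustive-plus-sampled design covers the same structural
variety at desk scale), and modularity/assortativity over 200 random
graphs on up to 8 nodes.

# Numerical choices and degenerate inputs

* Pearson correlation uses pairwise-complete samples with a minimum of 3
  complete pairs; sparser pairs and zero-variance genes yield undefined
  entries that thresholding skips (with counts reported).
* The hypergeometric tail is evaluated in log space; exactness is verified
  against direct combinatorial summation over the full `N <= 25` grid.
* Duplicate edges collapse with a warning (keeping the first weight) rather
  than erroring, so noisy edge lists load; self-loops are rejected outright
  because the rewiring null and the simple-graph model both require their
  absence.
* Empty graphs, edgeless graphs, and single-node graphs produce errors
  exactly where a statistic is undefined (average degree, density,
  diameter, modularity), not silent zeros.

# Known limitations

Correlation networks inherit all the caveats of marginal correlation:
indirect co-expression is not distinguished from direct co-regulation (no
partial correlations), and a hard threshold discards the dense-but-weak
structure soft-thresholding approaches retain. The dense-matrix MCL and
spectral routines do not scale past a few hundred nodes. The degree
histogram fit is descriptive. Annotation terms are used as given, with no
ontology-graph propagation.
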