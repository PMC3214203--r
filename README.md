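# geconet

Gene co-expression network analysis for systems biology: infer networks from
expression matrices by Pearson-correlation thresholding, characterize their
topology against random-graph null models, detect communities, compare
networks, and score cluster-level functional enrichment — with
Cytoscape-compatible export and a fully offline synthetic-data module.

It is aimed at researchers who have a genes × samples expression matrix (or
an existing edge list / STRING protein-links file) and want system-wide
structure rather than per-gene differential expression: which genes move
together, whether the resulting wiring is non-random, which modules it
decomposes into, and what those modules do.

## The core methods

* **Inference.** Pairwise PCC
  `r(i,j) = Σ(x−x̄)(y−ȳ) / sqrt(Σ(x−x̄)² Σ(y−ȳ)²)` across samples; gene
  pairs with `|r| ≥ τ` become edges of an undirected simple graph (signed
  `r` kept as edge weight).
* **Topology.** Degree, link density, BFS shortest paths and diameter,
  Brandes betweenness, local/average clustering coefficients, degree
  assortativity, and a log-log least-squares degree-distribution fit.
* **Null models.** Maslov–Sneppen degree-preserving rewiring, Erdős–Rényi
  `G(n,m)`/`G(n,p)`, and a planted modular graph; observed metrics are
  reported with empirical z-scores `(obs − mean_null)/sd_null` against the
  replicate ensemble.
* **Communities.** Greedy modularity agglomeration (CNM), Louvain, native
  Markov clustering (expansion/inflation), and spectral bisection via the
  Fiedler vector. Modularity is `Q = Σ_c [e_c/m − (d_c/2m)²]`.
* **Comparison.** Edge-set Jaccard index and union/intersection/difference.
* **Enrichment.** One-sided hypergeometric upper tail
  `P(X ≥ k) = Σ_i C(K,i) C(N−K,n−i) / C(N,n)` per cluster × term, with
  Benjamini–Hochberg correction across all tests.

All graph algorithms are native implementations over the package's own
`Graph` S4 class; every writer is byte-deterministic, and every random step
takes an explicit seed.

## Worked example

```r
library(geconet)

# 120 genes in 4 planted co-expression modules, 40 samples
fx  <- simulateModularExpression(nGenes = 120, nModules = 4, nSamples = 40,
                                 withinCorr = 0.8, seed = 1)
net <- thresholdNetwork(pearsonSimilarity(fx$expr), tau = 0.6)
net
#> Graph with 120 nodes and 1718 weighted edges
#>   nodes: g001, g002, g003, g004, g005, g006 ...

topologySummary(net)$global
#>  n_nodes n_edges average_degree link_density diameter mean_shortest_path
#>      120    1718       28.63333    0.2406162        2           1.012644
#>  global_clustering assortativity
#>          0.9886018    0.06872887

nullCompare(net, model = "rewire", nReps = 10, seed = 42)
#> NullEnsemble [rewire] with 10 replicates (seed 42)
#>   average_clustering   obs = 0.9886, null mean = 0.2285, z = 259.920
#>   assortativity        obs = 0.06873, null mean = -0.009438, z = 4.174
#>   mean_betweenness     obs = 0.1833, null mean = 45.19, z = -8001.647

lv <- louvainClusters(net, seed = 1)
lv$partition
#> Partition of 120 nodes into 4 clusters
#>   sizes: 30, 30, 30, 30

ann <- simulateAnnotation(fx$truth, coverage = 1, decoyTerms = 2, seed = 1)
head(enrichClusters(lv$partition, ann), 4)
#>  cluster term_id      description  k  n  K   N      p_value      q_value
#>        1      M1 planted module 1 30 30 30 120 5.891176e-29 1.767353e-28
#>        2      M2 planted module 2 30 30 30 120 5.891176e-29 1.767353e-28
#>        3      M3 planted module 3 30 30 30 120 5.891176e-29 1.767353e-28
#>        4      M4 planted module 4 30 30 30 120 5.891176e-29 1.767353e-28
```

Reading the output: at `τ = 0.6` the four planted modules emerge as four
dense blocks (average clustering 0.99 vs 0.23 in the degree-matched
rewired nulls — a strongly non-random topology); Louvain recovers them
exactly (`Q = 0.75`, the theoretical block structure), and each planted
annotation term is most enriched in its own module with `k = n = K` (the
entire term inside the matching cluster), giving the minimal attainable
hypergeometric p for those counts.

For Cytoscape, `writeSIF(net, "network.sif")` and
`writeNodeAttributes(...)` export the network and the cluster/topology
attribute table; `runPipeline()` (or `inst/cli/geconet.R run --config
demo.cfg`) chains every stage and writes `net.tsv`, topology and null
reports, `clusters.tsv`, `enrichment.tsv`, `network.sif`,
`node_attributes.tsv`, and a `run.log` that records every parameter and
seed. Reruns with the same configuration are byte-identical.

## Command line

A thin Rscript front end over the package functions lives at
`inst/cli/geconet.R`:

```sh
Rscript inst/cli/geconet.R fixture  --genes 120 --modules 4 --samples 40 --within 0.8 --seed 1 --out-prefix fx_
Rscript inst/cli/geconet.R infer    --expr fx_expr.tsv --tau 0.9 --out net.tsv
Rscript inst/cli/geconet.R topology --net net.tsv --out summary.tsv --per-node nodes.tsv
Rscript inst/cli/geconet.R nullcmp  --net net.tsv --model rewire --reps 10 --seed 42 --out null_report.tsv
Rscript inst/cli/geconet.R cluster  --net net.tsv --method louvain --seed 7 --out clusters.tsv
Rscript inst/cli/geconet.R compare  --net1 a.tsv --net2 b.tsv --op jaccard --out cmp.tsv
Rscript inst/cli/geconet.R enrich   --clusters clusters.tsv --gmt annotations.gmt --out enrichment.tsv
Rscript inst/cli/geconet.R run      --config demo.cfg
```

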