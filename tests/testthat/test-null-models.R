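test_that("rewiring preserves the degree sequence exactly", {
  for (s in 1:30) {
    g <- randomTestGraph(sample(5:10, 1), p = 0.45, seed = s)
    if (numEdges(g) < 2) next
    rw <- rewireEdges(g, seed = s)
    expect_identical(degreeSequence(rw), degreeSequence(g))
    expect_identical(nodes(rw), nodes(g))
  }
})

test_that("rewiring a triangle is a fixed point and seeds are reproducible", {
  k3 <- completeGraph(3)
  rw <- rewireEdges(k3, seed = 9)
  expect_identical(edgeTable(rw), edgeTable(k3)[, c("from", "to")])

  g <- randomTestGraph(8, p = 0.5, seed = 2)
  expect_identical(edgeTable(rewireEdges(g, seed = 42)),
                   edgeTable(rewireEdges(g, seed = 42)))
  expect_error(rewireEdges(buildGraph(rbind(c("a", "b")))), "2 edges")
})

test_that("rewiring actually randomizes wiring on a large sparse graph", {
  g <- erdosRenyiGraph(60, m = 120, seed = 3)
  rw <- rewireEdges(g, seed = 4)
  expect_lt(jaccardIndex(g, rw)$jaccardEdges, 0.5)
})

test_that("Erdos-Renyi G(n,m) and G(n,p) honor their contracts", {
  expect_identical(numEdges(erdosRenyiGraph(5, m = 10, seed = 1)), 10L)
  expect_identical(numEdges(erdosRenyiGraph(10, p = 0, seed = 1)), 0L)
  expect_identical(numNodes(erdosRenyiGraph(10, p = 0, seed = 1)), 10L)
  expect_error(erdosRenyiGraph(5, m = 11), "exceeds")
  expect_error(erdosRenyiGraph(5), "exactly one")
  expect_error(erdosRenyiGraph(5, m = 2, p = 0.1), "exactly one")
  for (s in 1:20)
    expect_identical(numEdges(erdosRenyiGraph(20, m = 37, seed = s)), 37L)
})

test_that("G(50, 0.1) mean edge count sits at its expectation", {
  counts <- vapply(1:200, function(s)
    numEdges(erdosRenyiGraph(50, p = 0.1, seed = s)), integer(1))
  # E = C(50,2) * 0.1 = 122.5; 5-SD guard on the mean of 200 replicates
  se <- sqrt(1225 * 0.1 * 0.9 / 200)
  expect_lt(abs(mean(counts) - 122.5), 5 * se)
})

test_that("planted modular graphs meet their construction counts", {
  mg <- randomModularGraph(100, 4, avgDegree = 10, intraFraction = 0.9,
                           seed = 1)
  expect_identical(numEdges(mg$graph), 500L)
  sizes <- tabulate(membership(mg$truth))
  expect_identical(sort(sizes), rep(25L, 4))

  mem <- membership(mg$truth)
  et <- edgeTable(mg$graph)
  intra <- sum(mem[et$from] == mem[et$to])
  expect_identical(intra, 450L)        # round(0.9 * 500) by construction

  pure <- randomModularGraph(40, 4, avgDegree = 4, intraFraction = 1,
                             seed = 2)
  memP <- membership(pure$truth)
  etP <- edgeTable(pure$graph)
  expect_true(all(memP[etP$from] == memP[etP$to]))

  expect_error(randomModularGraph(12, 4, avgDegree = 11, intraFraction = 1),
               "intra-module")
})

test_that("planted partitions score positive modularity when assortative", {
  for (s in 1:5) {
    mg <- randomModularGraph(80, 4, avgDegree = 8, intraFraction = 0.8,
                             seed = s)
    expect_gt(modularityScore(mg$graph, mg$truth), 0)
  }
})

test_that("null comparison reports z-scores, flags degenerate nulls, and is
           deterministic", {
  g <- randomTestGraph(9, p = 0.45, seed = 6, connected = TRUE)
  ens <- suppressWarnings(
    nullCompare(g, model = "rewire", nReps = 8, seed = 11))
  expect_s4_class(ens, "NullEnsemble")
  expect_length(ens@replicates, 8L)
  for (rep_ in ens@replicates)
    expect_identical(degreeSequence(rep_), degreeSequence(g))
  rep1 <- nullReport(ens)
  expect_identical(rep1$metric,
                   c("average_clustering", "assortativity",
                     "mean_betweenness"))

  ens2 <- suppressWarnings(
    nullCompare(g, model = "rewire", nReps = 8, seed = 11))
  expect_identical(nullReport(ens2), rep1)

  # C5's degree sequence forces every rewire to an isomorphic cycle:
  # all null values equal the observed value, z undefined and flagged
  c5 <- cycleGraph(5)
  expect_warning(
    ensC <- nullCompare(c5, model = "rewire", nReps = 5,
                        metrics = "mean_shortest_path", seed = 1),
    "zero null spread")
  expect_true(all(ensC@metricNulls$mean_shortest_path ==
                    ensC@observed[["mean_shortest_path"]]))
  expect_true(is.na(ensC@zScores[["mean_shortest_path"]]))

  expect_error(nullCompare(g, nReps = 0), "at least 1")
  expect_error(nullCompare(g, metrics = "no_such_metric"), "unknown metric")

  ensER <- suppressWarnings(
    nullCompare(g, model = "erdos_renyi", nReps = 5, seed = 2))
  for (rep_ in ensER@replicates)
    expect_identical(numEdges(rep_), numEdges(g))
})
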