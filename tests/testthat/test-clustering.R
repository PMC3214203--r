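twoK3 <- buildGraph(rbind(c("a", "b"), c("b", "c"), c("a", "c"),
                          c("x", "y"), c("y", "z"), c("x", "z")))
twoK4 <- buildGraph(rbind(
  t(utils::combn(c("a", "b", "c", "d"), 2)),
  t(utils::combn(c("w", "x", "y", "z"), 2))))

test_that("modularity matches its closed form and the double-sum oracle", {
  g <- completeGraph(3)
  expect_equal(modularityScore(g, Partition(c(a = 1, b = 1, c = 1))), 0)
  expect_equal(modularityScore(twoK3,
    Partition(c(a = 1, b = 1, c = 1, x = 2, y = 2, z = 2))), 0.5)
  expect_equal(modularityScore(g, Partition(c(a = 1, b = 2, c = 3))), -1 / 3)

  expect_error(modularityScore(buildGraph(NULL, nodes = c("a", "b")),
                               Partition(c(a = 1, b = 1))), "edgeless")
  expect_error(modularityScore(twoK3, Partition(c(a = 1, b = 1))),
               "does not cover")

  for (s in 1:25) {
    g <- randomTestGraph(sample(4:8, 1), p = 0.5, seed = s)
    if (numEdges(g) == 0) next
    set.seed(s)
    p <- Partition(stats::setNames(sample(1:3, numNodes(g), replace = TRUE),
                                   nodes(g)))
    expect_equal(modularityScore(g, p), oracleModularity(g, p),
                 tolerance = 1e-9)
  }
})

test_that("greedy agglomeration recovers clean community structure", {
  res <- greedyModularity(twoK4)
  expect_identical(nClusters(res$partition), 2L)
  expect_equal(res$q, 0.5)
  expect_equal(res$q, oracleBestModularity(twoK4), tolerance = 1e-9)

  k5 <- completeGraph(5)
  expect_identical(nClusters(greedyModularity(k5)$partition), 1L)

  expect_error(greedyModularity(buildGraph(NULL, nodes = "a")), "edge")
})

test_that("Louvain recovers clean structure and is seed-deterministic", {
  res <- louvainClusters(twoK4, seed = 3)
  expect_identical(nClusters(res$partition), 2L)
  expect_equal(res$q, 0.5)

  res2 <- louvainClusters(twoK4, seed = 3)
  expect_identical(membership(res2$partition), membership(res$partition))
})

test_that("greedy and Louvain reach the exhaustive optimum on most small
           graphs and never exceed it", {
  hits <- 0L; total <- 0L
  for (s in 1:20) {
    g <- randomTestGraph(sample(5:7, 1), p = 0.5, seed = s + 100,
                         connected = TRUE)
    best <- oracleBestModularity(g)
    qG <- greedyModularity(g)$q
    qL <- louvainClusters(g, seed = s)$q
    expect_lte(qG, best + 1e-9)
    expect_lte(qL, best + 1e-9)
    total <- total + 2L
    hits <- hits + (qG >= best - 1e-9) + (qL >= best - 1e-9)
  }
  expect_gte(hits / total, 0.9)
})

test_that("both modularity heuristics recover planted modules", {
  for (s in 1:3) {
    mg <- randomModularGraph(100, 4, avgDegree = 10, intraFraction = 0.9,
                             seed = s)
    truth <- membership(mg$truth)
    expect_gte(ari(membership(louvainClusters(mg$graph, seed = s)$partition),
                   truth), 0.9)
    expect_gte(ari(membership(greedyModularity(mg$graph)$partition),
                   truth), 0.9)
  }
})

test_that("MCL separates components, handles degenerate graphs, and grows
           cluster counts with inflation", {
  p <- mclClusters(twoK3, inflation = 2)
  expect_identical(nClusters(p), 2L)
  mem <- membership(p)
  expect_identical(unname(mem[c("a", "b", "c")]), rep(mem[["a"]], 3))
  expect_identical(unname(mem[c("x", "y", "z")]), rep(mem[["x"]], 3))

  e4 <- buildGraph(NULL, nodes = paste0("i", 1:4))
  expect_identical(nClusters(mclClusters(e4)), 4L)

  single <- mclClusters(buildGraph(rbind(c("a", "b"))))
  expect_identical(nClusters(single), 1L)

  expect_error(mclClusters(twoK3, inflation = 1), "inflation")

  mg <- randomModularGraph(60, 4, avgDegree = 8, intraFraction = 0.95,
                           seed = 4)
  ks <- vapply(c(1.4, 2, 4), function(infl)
    nClusters(mclClusters(mg$graph, inflation = infl)), integer(1))
  expect_true(all(diff(ks) >= 0L))
})

test_that("spectral bisection finds the sparse cut", {
  bridged <- graphSetOp(twoK4, buildGraph(rbind(c("d", "w"))), "union")
  p <- spectralBisection(bridged)
  expect_identical(nClusters(p), 2L)
  sides <- list(clusterMembers(p, 1), clusterMembers(p, 2))
  mc <- oracleMinCutBisections(bridged)
  expect_true(any(vapply(mc$sides, function(side)
    setequal(side, sides[[1]]) || setequal(side, sides[[2]]), logical(1))))

  p4 <- buildGraph(rbind(c("a", "b"), c("b", "c"), c("c", "d")))
  sp <- spectralBisection(p4)
  expect_true(setequal(clusterMembers(sp, 1), c("a", "b")) ||
                setequal(clusterMembers(sp, 1), c("c", "d")))

  k2 <- buildGraph(rbind(c("a", "b")))
  expect_identical(nClusters(spectralBisection(k2)), 2L)

  expect_error(spectralBisection(twoK3), "disconnected")
})

test_that("returned partitions always satisfy their own invariants", {
  checkPartition <- function(p, g) {
    mem <- membership(p)
    expect_identical(.rsortTest(names(mem)), nodes(g))
    expect_identical(sort(unique(mem)), seq_len(nClusters(p)))
    sizes <- tabulate(mem, nClusters(p))
    expect_true(all(diff(sizes) <= 0) ||
      all(vapply(seq_len(nClusters(p) - 1), function(i) {
        sizes[i] > sizes[i + 1] ||
          (sizes[i] == sizes[i + 1] &&
             min(clusterMembers(p, i)) < min(clusterMembers(p, i + 1)))
      }, logical(1))))
  }
  for (s in 1:6) {
    g <- randomTestGraph(sample(5:9, 1), p = 0.4, seed = s + 50,
                         connected = TRUE)
    checkPartition(louvainClusters(g, seed = s)$partition, g)
    checkPartition(greedyModularity(g)$partition, g)
    checkPartition(mclClusters(g), g)
    checkPartition(spectralBisection(g), g)
  }
})
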