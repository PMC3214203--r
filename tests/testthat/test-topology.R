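test_that("global scalar statistics match hand values", {
  expect_equal(averageDegree(completeGraph(3)), 2.0)
  expect_equal(averageDegree(buildGraph(NULL, nodes = paste0("i", 1:5))), 0.0)
  expect_error(averageDegree(buildGraph(NULL)), "empty")

  expect_equal(linkDensity(completeGraph(5)), 1.0)
  expect_equal(linkDensity(pathGraph(4)), 0.5)
  expect_equal(linkDensity(buildGraph(NULL, nodes = paste0("i", 1:10))), 0.0)
  expect_error(linkDensity(buildGraph(NULL, nodes = "a")), "2 nodes")
})

test_that("BFS shortest paths drop unreachable nodes", {
  p4 <- buildGraph(rbind(c("a", "b"), c("b", "c"), c("c", "d")))
  expect_identical(shortestPathLengths(p4, "a"),
                   c(a = 0L, b = 1L, c = 2L, d = 3L))
  disc <- buildGraph(rbind(c("a", "b"), c("x", "y")))
  expect_identical(names(shortestPathLengths(disc, "a")), c("a", "b"))
  k4 <- completeGraph(4)
  expect_true(all(shortestPathLengths(k4, "a")[-1] == 1L))
  expect_error(shortestPathLengths(p4, "zz"), "zz")
})

test_that("diameter follows the largest-component convention", {
  expect_identical(graphDiameter(pathGraph(4)), 3L)
  expect_identical(graphDiameter(cycleGraph(6)), 3L)
  expect_identical(graphDiameter(completeGraph(5)), 1L)
  expect_error(graphDiameter(buildGraph(NULL, nodes = "a")), "edgeless")
  disc <- buildGraph(rbind(c("a", "b"), c("b", "c"), c("x", "y")))
  expect_warning(d <- graphDiameter(disc), "largest")
  expect_identical(d, 2L)
  for (n in c(5L, 10L, 25L, 50L)) {
    expect_identical(graphDiameter(pathGraph(n)), n - 1L)
    expect_identical(graphDiameter(cycleGraph(2L * n)), n)
  }
})

test_that("betweenness matches enumeration on canonical small graphs", {
  p3 <- buildGraph(rbind(c("a", "b"), c("b", "c")))
  expect_equal(betweennessCentrality(p3), c(a = 0, b = 1, c = 0))
  st <- starGraph(4)
  bc <- betweennessCentrality(st)
  expect_equal(bc[["c"]], 6)          # C(4,2) leaf pairs through the hub
  expect_true(all(bc[names(bc) != "c"] == 0))
  expect_true(all(betweennessCentrality(completeGraph(4)) == 0))
  # normalized variant rescales by 2/((n-1)(n-2))
  expect_equal(betweennessCentrality(st, normalized = TRUE)[["c"]],
               6 * 2 / (4 * 3))
})

test_that("clustering coefficients count neighbor links correctly", {
  expect_true(all(clusteringCoefficients(completeGraph(3))$perNode == 1))
  expect_equal(clusteringCoefficients(starGraph(4))$perNode[["c"]], 0)
  k4minus <- buildGraph(rbind(c("a", "b"), c("a", "c"), c("a", "d"),
                              c("b", "c"), c("b", "d")))  # K4 minus (c,d)
  expect_equal(clusteringCoefficients(k4minus)$perNode[["a"]], 2 / 3)
})

test_that("assortativity equals the expanded-pair Pearson correlation", {
  expect_warning(a <- degreeAssortativity(cycleGraph(5)), "zero variance")
  expect_true(is.na(a))
  expect_equal(degreeAssortativity(starGraph(4)), -1.0)
  expect_equal(degreeAssortativity(pathGraph(4)), -0.5)
  expect_error(degreeAssortativity(buildGraph(rbind(c("a", "b")))),
               "2 edges")
})

test_that("power-law fits recover an exact exponent and rank fits sensibly", {
  k <- 1:20
  fit <- fitPowerLaw(k, k^-2.5)
  expect_equal(fit$exponent, 2.5, tolerance = 0.01)
  expect_gte(fit$rSquared, 0.999)
  expect_true(fit$scaleFreeLike)

  expect_error(fitDegreeDistribution(cycleGraph(8)), "3 distinct")

  expFit <- fitPowerLaw(k, exp(-k))
  expect_lt(expFit$rSquared, fit$rSquared)
})

test_that("all metrics equal brute-force oracles on every labeled connected
           graph with up to 5 nodes", {
  graphs <- c(allConnectedGraphs(3), allConnectedGraphs(4),
              allConnectedGraphs(5))
  for (g in graphs) {
    D <- oracleDistances(g)
    for (s in nodes(g)) {
      sp <- shortestPathLengths(g, s)
      expect_equal(unname(sp[colnames(D)]), unname(D[s, ]),
                   tolerance = 1e-9)
    }
    expect_equal(betweennessCentrality(g), oracleBetweenness(g),
                 tolerance = 1e-9)
    expect_equal(clusteringCoefficients(g)$perNode, oracleClustering(g),
                 tolerance = 1e-9)
    if (numEdges(g) >= 2)
      expect_equal(suppressWarnings(degreeAssortativity(g)),
                   oracleAssortativity(g), tolerance = 1e-9)
  }
})

test_that("metrics agree with igraph on random 6-7 node graphs", {
  for (s in 1:15) {
    g <- randomTestGraph(sample(6:7, 1), p = 0.45, seed = s,
                         connected = TRUE)
    ig <- toIgraph(g)
    expect_equal(unname(betweennessCentrality(g)[nodes(g)]),
                 unname(igraph::betweenness(ig)[nodes(g)]),
                 tolerance = 1e-9)
    itr <- igraph::transitivity(ig, type = "local", isolates = "NaN")
    itr[is.nan(itr)] <- 0
    expect_equal(unname(clusteringCoefficients(g)$perNode), unname(itr),
                 tolerance = 1e-9)
    expect_identical(graphDiameter(g), as.integer(igraph::diameter(ig)))
    expect_equal(meanShortestPath(g), igraph::mean_distance(ig),
                 tolerance = 1e-9)
    if (numEdges(g) >= 2 &&
        !is.na(suppressWarnings(degreeAssortativity(g))))
      expect_equal(degreeAssortativity(g),
                   igraph::assortativity_degree(ig), tolerance = 1e-9)
  }
})

test_that("betweenness on trees sums to the pairwise interior-length total", {
  for (s in 1:10) {
    set.seed(s)
    n <- sample(5:12, 1)
    ids <- sprintf("v%02d", 1:n)
    parent <- vapply(2:n, function(i) sample(i - 1, 1), integer(1))
    tree <- buildGraph(cbind(ids[parent], ids[2:n]))
    D <- oracleDistances(tree)
    expected <- sum(D[upper.tri(D)] - 1)
    expect_equal(sum(betweennessCentrality(tree)), expected,
                 tolerance = 1e-9)
  }
})

test_that("topology summary is internally consistent", {
  g <- randomTestGraph(8, p = 0.4, seed = 4, connected = TRUE)
  ts <- topologySummary(g)
  expect_equal(ts$global$average_degree,
               2 * ts$global$n_edges / ts$global$n_nodes)
  expect_equal(ts$global$link_density,
               2 * ts$global$n_edges /
                 (ts$global$n_nodes * (ts$global$n_nodes - 1)))
  expect_identical(ts$perNode$node, nodes(g))
  expect_identical(sum(ts$perNode$degree), 2L * numEdges(g))
})
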