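test_that("hypergeometric upper tail matches closed forms", {
  expect_equal(hypergeomTest(0, 5, 5, 20), 1.0)
  expect_equal(hypergeomTest(5, 5, 5, 20), 1 / choose(20, 5),
               tolerance = 1e-12)
  expect_equal(hypergeomTest(3, 10, 20, 20), 1.0)  # term covers universe

  expect_error(hypergeomTest(-1, 5, 5, 20), "non-negative")
  expect_error(hypergeomTest(6, 5, 5, 20), "min\\(n, K\\)")
  expect_error(hypergeomTest(1, 21, 5, 20), "universe")
  expect_error(hypergeomTest(1, 5, 21, 20), "universe")
})

test_that("hypergeometric p equals exact combinatorial summation on a small
           grid and is non-increasing in k", {
  for (N in c(8, 12)) for (n in seq_len(N)) for (K in seq_len(N)) {
    ks <- 0:min(n, K)
    ps <- vapply(ks, function(k) hypergeomTest(k, n, K, N), numeric(1))
    expected <- vapply(ks, function(k) oracleHypergeom(k, n, K, N),
                       numeric(1))
    expect_equal(ps, expected, tolerance = 1e-10)
    expect_true(all(diff(ps) <= 1e-12))
  }
})

test_that("BH adjustment reproduces the step-up evaluation", {
  expect_equal(bhAdjust(0.04), 0.04)
  expect_equal(bhAdjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bhAdjust(c(0.05, 0.05)), c(0.05, 0.05))
  expect_error(bhAdjust(c(0.5, 1.2)), "\\[0, 1\\]")

  for (s in 1:10) {
    set.seed(s)
    p <- runif(sample(2:30, 1))
    adj <- bhAdjust(p)
    expect_equal(adj, oracleBH(p), tolerance = 1e-12)
    # monotone when sorted by raw p
    expect_true(all(diff(adj[order(p)]) >= -1e-12))
  }
})

test_that("cluster enrichment reproduces the worked example", {
  genes <- sprintf("g%02d", 1:20)
  mem <- stats::setNames(rep(1:4, each = 5), genes)
  p <- Partition(mem)
  ann <- AnnotationSet(list(T1 = clusterMembers(p, 1)))
  res <- enrichClusters(p, ann, universe = genes, minCluster = 5)
  hit <- res[res$term_id == "T1" & res$k == 5, ]
  expect_identical(nrow(hit), 1L)
  expect_identical(hit$n, 5L)
  expect_identical(hit$K, 5L)
  expect_identical(hit$N, 20L)
  expect_equal(hit$p_value, 1 / choose(20, 5), tolerance = 1e-12)
})

test_that("enrichment respects universe choice, min size, and coverage", {
  genes <- sprintf("g%02d", 1:20)
  p <- Partition(stats::setNames(rep(1:2, each = 10), genes))
  ann <- AnnotationSet(list(T1 = genes[1:5], T2 = c(genes[11:14], "zz1")))

  # network universe = annotated clustered genes (zz1 excluded)
  res <- enrichClusters(p, ann, universe = "network")
  expect_true(all(res$N == 9))
  # annotation universe includes zz1
  resA <- enrichClusters(p, ann, universe = "annotation")
  expect_true(all(resA$N == 10))

  # clusters smaller than minCluster are skipped
  small <- Partition(stats::setNames(c(rep(1, 8), rep(2, 2)), genes[1:10]))
  resS <- enrichClusters(small, ann, universe = genes[1:10], minCluster = 5)
  expect_true(all(resS$cluster == 1))

  expect_error(enrichClusters(p, AnnotationSet(list(T1 = "none")),
                              universe = "network"), "empty universe")

  # clusters whose genes carry no term produce no rows
  annPart <- AnnotationSet(list(T1 = genes[1:5]))
  resP <- enrichClusters(p, annPart, universe = genes)
  expect_true(all(resP$cluster == 1))
})

test_that("each planted term attains its best q in its own module", {
  mg <- simulateModularExpression(nGenes = 60, nModules = 3, nSamples = 30,
                                  withinCorr = 0.85, seed = 3)
  ann <- simulateAnnotation(mg$truth, coverage = 0.8, decoyTerms = 3,
                            seed = 3)
  res <- enrichClusters(mg$truth, ann, universe = "network")
  truthTerm <- paste0("M", 1:3)
  for (i in 1:3) {
    rows <- res[res$term_id == truthTerm[i], ]
    best <- rows$cluster[which.min(rows$q_value)]
    # module i's genes are cluster i of the truth partition by construction
    planted <- membership(mg$truth)[termGenes(ann, truthTerm[i])[1]]
    expect_identical(best, unname(planted))
  }
})
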