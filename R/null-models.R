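# Random-graph null models and empirical null comparison of topology metrics.

# Run expr under a fixed RNG seed without touching the caller's RNG state.
.withSeed <- function(seed, expr) {
  withr::with_seed(as.integer(seed), expr)
}

#' Degree-preserving edge rewiring (Maslov-Sneppen)
#'
#' Randomizes a graph's wiring while preserving every node's degree exactly,
#' by repeated double-edge swaps: two edges `(a,b)` and `(c,d)` are replaced
#' by `(a,d)` and `(c,b)`. A candidate swap that would create a self-loop or
#' a duplicate edge is rejected; rejected swaps still count as attempts, so
#' runtime is linear in the attempt budget and runs are reproducible per
#' seed. `round(swapFactor * |E|)` swaps are attempted.
#'
#' @param g A [Graph] with at least 2 edges.
#' @param swapFactor Attempted swaps per edge (default 10).
#' @param seed Integer seed; same graph + seed always gives the same output.
#' @return An unweighted [Graph] with the same node set and the same degree
#'   sequence as `g`.
#' @export
rewireEdges <- function(g, swapFactor = 10, seed = 1L) {
  stopifnot(is(g, "Graph"))
  m <- numEdges(g)
  if (m < 2L) stop("rewiring needs at least 2 edges")
  n <- numNodes(g)
  a <- match(g@from, g@nodes)
  b <- match(g@to, g@nodes)
  keyOf <- function(u, v) (pmin(u, v) - 1) * n + pmax(u, v)
  present <- new.env(hash = TRUE, parent = emptyenv())
  for (i in seq_len(m)) assign(as.character(keyOf(a[i], b[i])), TRUE,
                               envir = present)
  attempts <- max(1L, as.integer(round(swapFactor * m)))
  .withSeed(seed, {
    for (t in seq_len(attempts)) {
      e <- sample.int(m, 2L)
      i <- e[1]; j <- e[2]
      # random orientation of the second edge
      if (stats::runif(1) < 0.5) { c_ <- a[j]; d_ <- b[j] }
      else { c_ <- b[j]; d_ <- a[j] }
      u1 <- a[i]; v1 <- d_     # proposed (a, d)
      u2 <- c_;  v2 <- b[i]    # proposed (c, b)
      if (u1 == v1 || u2 == v2) next
      k1 <- keyOf(u1, v1); k2 <- keyOf(u2, v2)
      if (k1 == k2) next
      if (exists(as.character(k1), envir = present, inherits = FALSE) ||
          exists(as.character(k2), envir = present, inherits = FALSE)) next
      rm(list = c(as.character(keyOf(a[i], b[i])),
                  as.character(keyOf(a[j], b[j]))), envir = present)
      a[i] <- min(u1, v1); b[i] <- max(u1, v1)
      a[j] <- min(u2, v2); b[j] <- max(u2, v2)
      assign(as.character(k1), TRUE, envir = present)
      assign(as.character(k2), TRUE, envir = present)
    }
  })
  buildGraph(cbind(g@nodes[a], g@nodes[b]), nodes = g@nodes)
}

#' Erdos-Renyi random graphs
#'
#' `G(n, m)`: exactly `m` distinct edges drawn uniformly without replacement.
#' `G(n, p)`: each of the `n(n-1)/2` pairs linked independently with
#' probability `p`. Exactly one of `m`, `p` must be given. Nodes are labeled
#' `"n1".."n<n>"`.
#'
#' @param n Number of nodes.
#' @param m Edge count (G(n, m) variant).
#' @param p Edge probability (G(n, p) variant).
#' @param seed Integer seed.
#' @return A [Graph].
#' @export
erdosRenyiGraph <- function(n, m = NULL, p = NULL, seed = 1L) {
  stopifnot(n >= 1)
  if (is.null(m) == is.null(p))
    stop("give exactly one of 'm' (edge count) or 'p' (edge probability)")
  labels <- paste0("n", seq_len(n))
  maxM <- n * (n - 1) / 2
  pairIdx <- which(upper.tri(matrix(FALSE, n, n)), arr.ind = TRUE)
  if (!is.null(m)) {
    if (m > maxM) stop("m = ", m, " exceeds the ", maxM, " possible edges")
    sel <- if (m > 0) .withSeed(seed, sample.int(nrow(pairIdx), m))
           else integer()
  } else {
    stopifnot(p >= 0, p <= 1)
    sel <- .withSeed(seed, which(stats::runif(nrow(pairIdx)) < p))
  }
  buildGraph(cbind(labels[pairIdx[sel, 1]], labels[pairIdx[sel, 2]]),
             nodes = labels)
}

#' Planted-partition random modular graph
#'
#' Splits `n` nodes into `kModules` near-equal modules and places
#' `round(avgDegree * n / 2)` edges: a fraction `intraFraction` uniformly
#' among within-module pairs and the remainder among between-module pairs,
#' without duplicates. The ground-truth module assignment is returned
#' alongside, so community-detection recovery can be scored.
#'
#' @param n Number of nodes.
#' @param kModules Number of modules.
#' @param avgDegree Target average degree.
#' @param intraFraction Fraction of edges placed within modules, in \[0, 1\].
#' @param seed Integer seed.
#' @return List with `graph` (a [Graph]) and `truth` (a [Partition]).
#' @export
randomModularGraph <- function(n, kModules, avgDegree, intraFraction,
                               seed = 1L) {
  stopifnot(n >= kModules, kModules >= 1, intraFraction >= 0,
            intraFraction <= 1)
  labels <- sprintf("n%03d", seq_len(n))
  base <- n %/% kModules
  sizes <- rep(base, kModules) + c(rep(1L, n %% kModules),
                                   rep(0L, kModules - n %% kModules))
  module <- rep(seq_len(kModules), sizes)
  pairIdx <- which(upper.tri(matrix(FALSE, n, n)), arr.ind = TRUE)
  intra <- module[pairIdx[, 1]] == module[pairIdx[, 2]]
  m <- as.integer(round(avgDegree * n / 2))
  mi <- as.integer(round(intraFraction * m))
  me <- m - mi
  if (mi > sum(intra))
    stop("requested ", mi, " intra-module edges but only ", sum(intra),
         " within-module pairs exist")
  if (me > sum(!intra))
    stop("requested ", me, " inter-module edges but only ", sum(!intra),
         " between-module pairs exist")
  sel <- .withSeed(seed, {
    c(if (mi > 0) which(intra)[sample.int(sum(intra), mi)],
      if (me > 0) which(!intra)[sample.int(sum(!intra), me)])
  })
  g <- buildGraph(cbind(labels[pairIdx[sel, 1]], labels[pairIdx[sel, 2]]),
                  nodes = labels)
  list(graph = g, truth = Partition(stats::setNames(module, labels)))
}

.nullMetrics <- list(
  average_clustering = function(g) clusteringCoefficients(g)$globalAverage,
  assortativity = function(g)
    suppressWarnings(degreeAssortativity(g)),
  mean_betweenness = function(g) mean(betweennessCentrality(g)),
  diameter = function(g) suppressWarnings(as.numeric(graphDiameter(g))),
  mean_shortest_path = function(g) meanShortestPath(g)
)

#' Compare observed topology against a random-graph null ensemble
#'
#' Generates `nReps` randomized replicates of the observed graph under the
#' chosen null model (degree-preserving rewiring, Erdos-Renyi with matched
#' node and edge counts, or a planted modular graph with matched average
#' degree), evaluates each requested metric on the observed graph and on
#' every replicate, and reports empirical z-scores
#' `(obs - mean_null) / sd_null` and percentile ranks. A z-score whose null
#' spread is zero is reported as `NA` and flagged with a warning.
#'
#' @param g The observed [Graph].
#' @param model `"rewire"`, `"erdos_renyi"`, or `"modular"`.
#' @param nReps Number of replicates (>= 1).
#' @param metrics Subset of `c("average_clustering", "assortativity",
#'   "mean_betweenness", "diameter", "mean_shortest_path")`.
#' @param seed Master integer seed; replicate `i` uses `seed + i`.
#' @param kModules,intraFraction Extra parameters for the `"modular"` model.
#' @param swapFactor Attempted swaps per edge for `"rewire"`.
#' @return A [NullEnsemble].
#' @export
nullCompare <- function(g, model = c("rewire", "erdos_renyi", "modular"),
                        nReps = 10L,
                        metrics = c("average_clustering", "assortativity",
                                    "mean_betweenness"),
                        seed = 1L, kModules = 4L, intraFraction = 0.8,
                        swapFactor = 10) {
  stopifnot(is(g, "Graph"))
  model <- match.arg(model)
  if (nReps < 1L) stop("'nReps' must be at least 1")
  unknown <- setdiff(metrics, names(.nullMetrics))
  if (length(unknown))
    stop("unknown metric(s): ", paste(unknown, collapse = ", "))
  makeRep <- switch(model,
    rewire = function(i) rewireEdges(g, swapFactor = swapFactor,
                                     seed = seed + i),
    erdos_renyi = function(i) erdosRenyiGraph(numNodes(g), m = numEdges(g),
                                              seed = seed + i),
    modular = function(i) randomModularGraph(numNodes(g), kModules,
                                             averageDegree(g), intraFraction,
                                             seed = seed + i)$graph)
  reps <- lapply(seq_len(nReps), makeRep)
  evalMetrics <- function(gg)
    vapply(metrics, function(m) .nullMetrics[[m]](gg), numeric(1))
  obs <- evalMetrics(g)
  nullMat <- vapply(reps, evalMetrics, numeric(length(metrics)))
  if (length(metrics) == 1L) nullMat <- matrix(nullMat, nrow = 1L)
  rownames(nullMat) <- metrics
  nulls <- lapply(metrics, function(m) unname(nullMat[m, ]))
  names(nulls) <- metrics
  z <- vapply(metrics, function(m) {
    s <- stats::sd(nulls[[m]])
    if (is.na(s) || s == 0) NA_real_ else (obs[[m]] - mean(nulls[[m]])) / s
  }, numeric(1))
  if (anyNA(z))
    warning("zero null spread for metric(s): ",
            paste(metrics[is.na(z)], collapse = ", "), " (z undefined)")
  pct <- vapply(metrics, function(m)
    mean(nulls[[m]] < obs[[m]]), numeric(1))
  new("NullEnsemble", model = model, replicates = reps,
      seed = as.integer(seed), observed = obs, metricNulls = nulls,
      zScores = z, percentiles = pct)
}

setMethod("show", "NullEnsemble", function(object) {
  cat("NullEnsemble [", object@model, "] with ",
      length(object@replicates), " replicates (seed ", object@seed, ")\n",
      sep = "")
  for (m in names(object@observed)) {
    z <- object@zScores[[m]]
    cat(sprintf("  %-20s obs = %.4g, null mean = %.4g, z = %s\n", m,
                object@observed[[m]], mean(object@metricNulls[[m]]),
                if (is.na(z)) "undefined (zero null spread)"
                else sprintf("%.3f", z)))
  }
})

#' Tabulate a NullEnsemble as a data.frame
#'
#' @param ens A [NullEnsemble].
#' @return data.frame with one row per metric: observed, null mean/sd,
#'   z-score, percentile.
#' @export
nullReport <- function(ens) {
  stopifnot(is(ens, "NullEnsemble"))
  data.frame(
    metric = names(ens@observed),
    observed = as.numeric(ens@observed),
    null_mean = vapply(ens@metricNulls, mean, numeric(1)),
    null_sd = vapply(ens@metricNulls, stats::sd, numeric(1)),
    z_score = as.numeric(ens@zScores),
    percentile = as.numeric(ens@percentiles),
    row.names = NULL
  )
}
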