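# Global and local network topology statistics.

#' Average node degree
#'
#' `2|E| / |V|`: the mean number of links per node.
#'
#' @param g A [Graph] with at least one node.
#' @return Numeric.
#' @export
averageDegree <- function(g) {
  stopifnot(is(g, "Graph"))
  if (numNodes(g) == 0L) stop("average degree undefined on the empty graph")
  2 * numEdges(g) / numNodes(g)
}

#' Link density
#'
#' Fraction of possible node pairs that are linked:
#' `2|E| / (|V| (|V| - 1))`.
#'
#' @param g A [Graph] with at least two nodes.
#' @return Numeric in \[0, 1\].
#' @export
linkDensity <- function(g) {
  stopifnot(is(g, "Graph"))
  n <- numNodes(g)
  if (n < 2L) stop("link density needs at least 2 nodes")
  2 * numEdges(g) / (n * (n - 1))
}

# BFS hop counts from a source index; -1 marks unreachable.
.bfsDist <- function(adj, s) {
  n <- length(adj)
  dist <- rep.int(-1L, n)
  dist[s] <- 0L
  frontier <- s
  while (length(frontier)) {
    nxt <- integer()
    for (v in frontier) {
      nb <- adj[[v]]
      new <- nb[dist[nb] < 0L]
      dist[new] <- dist[v] + 1L
      nxt <- c(nxt, new)
    }
    frontier <- nxt
  }
  dist
}

#' Shortest-path hop counts from a source node
#'
#' Breadth-first distances on the unweighted graph. Unreachable nodes are
#' absent from the result.
#'
#' @param g A [Graph].
#' @param source A node identifier present in the graph.
#' @return Named integer vector of hop counts (including `source` at 0).
#' @export
shortestPathLengths <- function(g, source) {
  stopifnot(is(g, "Graph"))
  s <- match(source, g@nodes)
  if (is.na(s)) stop("unknown source node: ", source)
  d <- .bfsDist(.adjacency(g), s)
  reach <- d >= 0L
  stats::setNames(d[reach], g@nodes[reach])
}

# All-pairs BFS distances restricted to one component's node indices.
.componentDistances <- function(adj, idx) {
  vapply(idx, function(s) .bfsDist(adj, s)[idx], integer(length(idx)))
}

#' Network diameter
#'
#' Maximum eccentricity (longest shortest path). On a disconnected graph the
#' diameter is computed over the largest connected component, with a warning,
#' so a single scalar is always reported.
#'
#' @param g A [Graph] with at least one edge.
#' @return Integer hop count.
#' @export
graphDiameter <- function(g) {
  stopifnot(is(g, "Graph"))
  if (numEdges(g) == 0L) stop("diameter undefined on an edgeless graph")
  comps <- connectedComponents(g)
  if (length(comps) > 1L)
    warning("graph is disconnected; diameter computed on the largest ",
            "component (", length(comps[[1]]), " nodes)")
  adj <- .adjacency(g)
  idx <- match(comps[[1]], g@nodes)
  max(.componentDistances(adj, idx))
}

#' Mean shortest-path length
#'
#' Average breadth-first distance over all reachable unordered node pairs
#' (pairs in different components are excluded).
#'
#' @param g A [Graph] with at least one edge.
#' @return Numeric.
#' @export
meanShortestPath <- function(g) {
  stopifnot(is(g, "Graph"))
  if (numEdges(g) == 0L) stop("mean shortest path undefined without edges")
  adj <- .adjacency(g)
  tot <- 0; cnt <- 0
  for (comp in connectedComponents(g)) {
    if (length(comp) < 2L) next
    idx <- match(comp, g@nodes)
    D <- .componentDistances(adj, idx)
    tot <- tot + sum(D) / 2
    cnt <- cnt + length(idx) * (length(idx) - 1) / 2
  }
  if (cnt == 0) stop("no connected node pairs")
  tot / cnt
}

#' Shortest-path betweenness centrality
#'
#' Brandes' accumulation of the fraction of shortest paths passing through
#' each node, summed over unordered source-target pairs, endpoints excluded;
#' equal-length paths share credit fractionally. Values are unnormalized by
#' default (what the null-model z-scores consume); `normalized = TRUE`
#' rescales by `2 / ((n - 1)(n - 2))`.
#'
#' @param g A [Graph].
#' @param normalized Rescale to \[0, 1\].
#' @return Named numeric vector, node -> betweenness.
#' @export
betweennessCentrality <- function(g, normalized = FALSE) {
  stopifnot(is(g, "Graph"))
  n <- numNodes(g)
  adj <- .adjacency(g)
  bc <- numeric(n)
  for (s in seq_len(n)) {
    # single-source shortest-path counts
    sigma <- numeric(n); sigma[s] <- 1
    dist <- rep.int(-1L, n); dist[s] <- 0L
    preds <- vector("list", n)
    order_ <- integer(0)
    frontier <- s
    while (length(frontier)) {
      order_ <- c(order_, frontier)
      nxt <- integer()
      for (v in frontier) {
        for (w in adj[[v]]) {
          if (dist[w] < 0L) {
            dist[w] <- dist[v] + 1L
            nxt <- c(nxt, w)
          }
          if (dist[w] == dist[v] + 1L) {
            sigma[w] <- sigma[w] + sigma[v]
            preds[[w]] <- c(preds[[w]], v)
          }
        }
      }
      frontier <- unique(nxt)
    }
    # dependency accumulation, reverse BFS order
    delta <- numeric(n)
    for (w in rev(order_)) {
      for (v in preds[[w]])
        delta[v] <- delta[v] + sigma[v] / sigma[w] * (1 + delta[w])
      if (w != s) bc[w] <- bc[w] + delta[w]
    }
  }
  bc <- bc / 2  # each unordered pair visited from both endpoints
  if (normalized) {
    if (n > 2L) bc <- bc * 2 / ((n - 1) * (n - 2)) else bc[] <- 0
  }
  stats::setNames(bc, g@nodes)
}

#' Local and average clustering coefficients
#'
#' Local coefficient `C(v) = 2 T(v) / (k(v)(k(v)-1))` where `T(v)` counts
#' edges among the neighbors of `v`; nodes of degree < 2 get `C(v) = 0`.
#' The global value is the plain average of local coefficients over all nodes
#' (Watts-Strogatz convention); see [globalTransitivity()] for the
#' triangle-to-triad ratio.
#'
#' @param g A [Graph].
#' @return List with `perNode` (named numeric) and `globalAverage` (numeric;
#'   `NaN` on an empty graph).
#' @export
clusteringCoefficients <- function(g) {
  stopifnot(is(g, "Graph"))
  adj <- .adjacency(g)
  n <- numNodes(g)
  cc <- numeric(n)
  for (v in seq_len(n)) {
    nb <- adj[[v]]
    k <- length(nb)
    if (k < 2L) next
    links <- 0L
    for (i in seq_len(k - 1L)) {
      links <- links + sum(adj[[nb[i]]] %in% nb[(i + 1L):k])
    }
    cc[v] <- 2 * links / (k * (k - 1))
  }
  list(perNode = stats::setNames(cc, g@nodes),
       globalAverage = if (n) mean(cc) else NaN)
}

#' Global transitivity
#'
#' `3 x triangles / connected triads`, the alternative global clustering
#' measure.
#'
#' @param g A [Graph].
#' @return Numeric (`NaN` when the graph has no connected triad).
#' @export
globalTransitivity <- function(g) {
  stopifnot(is(g, "Graph"))
  adj <- .adjacency(g)
  deg <- lengths(adj)
  triads <- sum(deg * (deg - 1) / 2)
  if (triads == 0) return(NaN)
  closed <- 0
  for (v in seq_along(adj)) {
    nb <- adj[[v]]
    k <- length(nb)
    if (k < 2L) next
    for (i in seq_len(k - 1L))
      closed <- closed + sum(adj[[nb[i]]] %in% nb[(i + 1L):k])
  }
  # closed counts one linked neighbor pair per triangle corner, i.e. 3T
  closed / triads
}

#' Degree assortativity
#'
#' Pearson correlation of the degrees at the two ends of each edge, computed
#' over the directed expansion of the edge list (each edge contributes both
#' `(k_u, k_v)` and `(k_v, k_u)`). Undefined when the end-degree variance is
#' zero (e.g. regular graphs): returns `NA` with a warning rather than
#' propagating NaN.
#'
#' @param g A [Graph] with at least two edges.
#' @return Numeric in \[-1, 1\], or `NA` when undefined.
#' @export
degreeAssortativity <- function(g) {
  stopifnot(is(g, "Graph"))
  if (numEdges(g) < 2L) stop("assortativity needs at least 2 edges")
  deg <- degreeSequence(g)
  x <- c(deg[g@from], deg[g@to])
  y <- c(deg[g@to], deg[g@from])
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    warning("assortativity undefined: zero variance in end degrees")
    return(NA_real_)
  }
  as.numeric(stats::cor(x, y))
}

#' Fit a power law to a degree histogram
#'
#' Least-squares line on `(log k, log p(k))` over the degree values with
#' positive probability, `k >= 1`. The slope magnitude is reported as the
#' exponent, together with the regression R-squared and the fitted degree
#' range. A high R-squared (>= 0.8) is reported as "scale-free-like"; this is
#' a descriptive label, not a statistical power-law test.
#'
#' @param k Integer vector of degree values (>= 1).
#' @param p Probabilities (or counts; normalized internally) for each `k`.
#' @return List with `exponent`, `rSquared`, `fitRange` (c(kMin, kMax)),
#'   `scaleFreeLike` (logical).
#' @export
fitPowerLaw <- function(k, p) {
  keep <- k >= 1 & p > 0
  k <- k[keep]; p <- p[keep]
  if (length(unique(k)) < 3L)
    stop("power-law fit needs at least 3 distinct degree values")
  p <- p / sum(p)
  fit <- stats::lm(log(p) ~ log(k))
  # an exactly linear log-log input is legitimate here; silence lm's
  # perfect-fit warning
  r2 <- suppressWarnings(summary(fit)$r.squared)
  list(exponent = abs(unname(stats::coef(fit)[2])),
       rSquared = r2,
       fitRange = c(min(k), max(k)),
       scaleFreeLike = r2 >= 0.8)
}

#' Fit the degree distribution of a graph
#'
#' Builds the empirical degree histogram (degrees >= 1) and fits it with
#' [fitPowerLaw()].
#'
#' @param g A [Graph] whose nonzero degrees take at least 3 distinct values.
#' @return As [fitPowerLaw()].
#' @export
fitDegreeDistribution <- function(g) {
  stopifnot(is(g, "Graph"))
  deg <- degreeSequence(g)
  deg <- deg[deg >= 1L]
  tab <- table(deg)
  fitPowerLaw(as.integer(names(tab)), as.numeric(tab))
}

#' Full topology summary
#'
#' Gathers the global statistics (node/edge counts, average degree, link
#' density, diameter and mean shortest path over the largest component,
#' average clustering, assortativity) and the per-node statistics (degree,
#' betweenness, local clustering) in one pass.
#'
#' @param g A [Graph] with at least one edge.
#' @return List with `global` (one-row data.frame) and `perNode` (data.frame
#'   with columns node, degree, betweenness, clustering).
#' @export
topologySummary <- function(g) {
  stopifnot(is(g, "Graph"), numEdges(g) >= 1L)
  deg <- degreeSequence(g)
  cc <- clusteringCoefficients(g)
  bc <- betweennessCentrality(g)
  assort <- if (numEdges(g) >= 2L)
    suppressWarnings(degreeAssortativity(g)) else NA_real_
  global <- data.frame(
    n_nodes = numNodes(g),
    n_edges = numEdges(g),
    average_degree = averageDegree(g),
    link_density = if (numNodes(g) >= 2L) linkDensity(g) else NA_real_,
    diameter = suppressWarnings(graphDiameter(g)),
    mean_shortest_path = meanShortestPath(g),
    global_clustering = cc$globalAverage,
    assortativity = assort
  )
  perNode <- data.frame(
    node = g@nodes,
    degree = as.integer(deg),
    betweenness = as.numeric(bc),
    clustering = as.numeric(cc$perNode)
  )
  list(global = global, perNode = perNode)
}
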