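# Small graph constructors and generators shared across tests.

.rsortTest <- function(x) x[order(x, method = "radix")]

pathGraph <- function(n, ids = sprintf("v%02d", seq_len(n))) {
  buildGraph(cbind(ids[-n], ids[-1]))
}

cycleGraph <- function(n, ids = sprintf("v%02d", seq_len(n))) {
  buildGraph(cbind(ids, ids[c(2:n, 1)]))
}

completeGraph <- function(n, ids = letters[seq_len(n)]) {
  pairs <- t(utils::combn(ids, 2))
  buildGraph(pairs)
}

starGraph <- function(nLeaves, center = "c") {
  leaves <- sprintf("l%02d", seq_len(nLeaves))
  buildGraph(cbind(rep(center, nLeaves), leaves))
}

# Uniform random graph helper (independent of the package's generators).
randomTestGraph <- function(n, p = 0.4, seed = 1, connected = FALSE) {
  ids <- letters[seq_len(n)]
  pairs <- t(utils::combn(ids, 2))
  for (attempt in seq_len(200)) {
    set.seed(seed * 1000 + attempt)
    keep <- stats::runif(nrow(pairs)) < p
    if (!any(keep)) next
    am <- matrix(FALSE, n, n, dimnames = list(ids, ids))
    am[pairs[keep, , drop = FALSE]] <- TRUE
    am <- am | t(am)
    if (connected && !helperIsConnected(am)) next
    return(buildGraph(pairs[keep, , drop = FALSE], nodes = ids))
  }
  stop("could not generate requested random graph")
}

# BFS connectivity on a logical adjacency matrix (test-side, no package code)
helperIsConnected <- function(am) {
  am <- am > 0
  n <- nrow(am)
  seen <- logical(n); seen[1] <- TRUE
  frontier <- 1L
  while (length(frontier)) {
    nxt <- which(apply(am[frontier, , drop = FALSE], 2, any) & !seen)
    seen[nxt] <- TRUE
    frontier <- nxt
  }
  all(seen)
}

# All labeled connected graphs on the given node ids (feasible up to n = 5).
allConnectedGraphs <- function(n) {
  ids <- letters[seq_len(n)]
  pairs <- t(utils::combn(ids, 2))
  np <- nrow(pairs)
  out <- list()
  for (mask in seq_len(2^np - 1)) {
    keep <- bitwAnd(mask, 2^(seq_len(np) - 1)) > 0
    am <- matrix(FALSE, n, n, dimnames = list(ids, ids))
    am[pairs[keep, , drop = FALSE]] <- TRUE
    am <- am | t(am)
    if (!helperIsConnected(am)) next
    out[[length(out) + 1L]] <- buildGraph(pairs[keep, , drop = FALSE])
  }
  out
}

toIgraph <- function(g) {
  igraph::graph_from_data_frame(edgeTable(g)[, c("from", "to")],
                                directed = FALSE,
                                vertices = data.frame(name = nodes(g)))
}

ari <- function(a, b) {
  common <- intersect(names(a), names(b))
  mclust::adjustedRandIndex(a[common], b[common])
}
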