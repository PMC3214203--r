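# Brute-force oracles, independent of the package's algorithm paths.

oracleAdjMatrix <- function(g) {
  ids <- nodes(g)
  am <- matrix(0, length(ids), length(ids), dimnames = list(ids, ids))
  et <- edgeTable(g)
  if (nrow(et)) {
    am[cbind(et$from, et$to)] <- 1
    am[cbind(et$to, et$from)] <- 1
  }
  am
}

# All-pairs distances by Floyd-Warshall.
oracleDistances <- function(g) {
  am <- oracleAdjMatrix(g)
  n <- nrow(am)
  D <- ifelse(am > 0, 1, Inf)
  diag(D) <- 0
  for (k in seq_len(n)) for (i in seq_len(n)) for (j in seq_len(n))
    if (D[i, k] + D[k, j] < D[i, j]) D[i, j] <- D[i, k] + D[k, j]
  D
}

# Betweenness by exhaustive simple-path enumeration (n <= 7 only):
# for each unordered pair, list all simple paths, keep the minimum-length
# ones, and give each interior node 1/(#shortest paths) credit.
oracleBetweenness <- function(g) {
  am <- oracleAdjMatrix(g)
  n <- nrow(am)
  bc <- stats::setNames(numeric(n), rownames(am))
  pathsBetween <- function(s, t) {
    found <- list()
    walk <- function(path) {
      v <- path[length(path)]
      if (v == t) { found[[length(found) + 1L]] <<- path; return() }
      for (w in which(am[v, ] > 0)) if (!w %in% path) walk(c(path, w))
    }
    walk(s)
    found
  }
  for (s in seq_len(n - 1)) for (t in (s + 1):n) {
    ps <- pathsBetween(s, t)
    if (!length(ps)) next
    lens <- lengths(ps)
    shortest <- ps[lens == min(lens)]
    for (p in shortest) {
      interior <- p[-c(1, length(p))]
      bc[interior] <- bc[interior] + 1 / length(shortest)
    }
  }
  bc
}

# Local clustering from the cube of the adjacency matrix.
oracleClustering <- function(g) {
  am <- oracleAdjMatrix(g)
  tri <- diag(am %*% am %*% am) / 2
  k <- rowSums(am)
  cc <- ifelse(k >= 2, 2 * tri / (k * (k - 1)), 0)
  stats::setNames(cc, rownames(am))
}

# Assortativity as a hand-evaluated Pearson correlation on the directed
# expansion of the edge list.
oracleAssortativity <- function(g) {
  deg <- degreeSequence(g)
  et <- edgeTable(g)
  x <- c(deg[et$from], deg[et$to])
  y <- c(deg[et$to], deg[et$from])
  mx <- mean(x); my <- mean(y)
  sxy <- sum((x - mx) * (y - my))
  sxx <- sum((x - mx)^2); syy <- sum((y - my)^2)
  if (sxx == 0 || syy == 0) return(NA_real_)
  sxy / sqrt(sxx * syy)
}

# Modularity by the double-sum definition
# Q = (1/2m) sum_ij (A_ij - k_i k_j / 2m) delta(c_i, c_j).
oracleModularity <- function(g, p) {
  am <- oracleAdjMatrix(g)
  deg <- rowSums(am)
  m <- sum(am) / 2
  mem <- membership(p)[rownames(am)]
  same <- outer(mem, mem, "==")
  sum((am - outer(deg, deg) / (2 * m)) * same) / (2 * m)
}

# All set partitions of 1..n (restricted-growth strings).
allSetPartitions <- function(n) {
  out <- list()
  grow <- function(labels, maxUsed) {
    i <- length(labels) + 1L
    if (i > n) { out[[length(out) + 1L]] <<- labels; return() }
    for (lab in seq_len(maxUsed + 1L))
      grow(c(labels, lab), max(maxUsed, lab))
  }
  grow(integer(), 0L)
  out
}

# Exhaustive-search maximum modularity over every partition (n <= 8).
oracleBestModularity <- function(g) {
  ids <- nodes(g)
  best <- -Inf
  for (labels in allSetPartitions(length(ids))) {
    p <- Partition(stats::setNames(labels, ids))
    q <- oracleModularity(g, p)
    if (q > best) best <- q
  }
  best
}

# Exact upper-tail hypergeometric by combinatorial summation; all binomials
# involved are exact in double precision for N <= 25.
oracleHypergeom <- function(k, n, K, N) {
  i <- k:min(n, K)
  sum(choose(K, i) * choose(N - K, n - i)) / choose(N, n)
}

# Manual BH step-up: adj_i = min_{j >= i}(p_(j) m / j), back in input order.
oracleBH <- function(p) {
  m <- length(p)
  ord <- order(p)
  ranked <- p[ord] * m / seq_len(m)
  adj <- rev(cummin(rev(ranked)))
  adj <- pmin(adj, 1)
  out <- numeric(m)
  out[ord] <- adj
  out
}

# Minimum-cut bisections by exhaustive enumeration (n <= 10): returns the
# set of all node subsets achieving the fewest crossing edges, sides
# non-trivial.
oracleMinCutBisections <- function(g) {
  ids <- nodes(g)
  n <- length(ids)
  am <- oracleAdjMatrix(g)
  best <- Inf; sets <- list()
  for (mask in 1:(2^n - 2)) {
    side <- bitwAnd(mask, 2^(seq_len(n) - 1)) > 0
    cut <- sum(am[side, !side])
    if (cut < best - 1e-9) { best <- cut; sets <- list(ids[side]) }
    else if (abs(cut - best) <= 1e-9) sets[[length(sets) + 1L]] <- ids[side]
  }
  list(cut = best, sides = sets)
}
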