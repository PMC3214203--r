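# Community detection: modularity, greedy agglomeration (CNM), Louvain,
# Markov clustering, and spectral bisection. All algorithms are native
# implementations operating on the package's Graph; modularity is the
# unweighted Newman-Girvan quantity throughout.

#' Newman-Girvan modularity of a partition
#'
#' `Q = sum_c [ e_c / m - (d_c / 2m)^2 ]` where `m` is the edge count, `e_c`
#' the number of within-cluster edges of cluster `c`, and `d_c` the sum of
#' degrees in `c`. Edge weights are ignored (unweighted modularity).
#'
#' @param g A [Graph] with at least one edge.
#' @param p A [Partition] covering every node of `g`.
#' @return Numeric `Q` in \[-0.5, 1\].
#' @examples
#' g <- buildGraph(rbind(c("a","b"), c("b","c"), c("a","c"),
#'                       c("x","y"), c("y","z"), c("x","z")))
#' p <- Partition(c(a=1, b=1, c=1, x=2, y=2, z=2))
#' modularityScore(g, p)  # 0.5
#' @export
modularityScore <- function(g, p) {
  stopifnot(is(g, "Graph"), is(p, "Partition"))
  m <- numEdges(g)
  if (m == 0L) stop("modularity undefined on an edgeless graph")
  mem <- membership(p)
  uncovered <- setdiff(g@nodes, names(mem))
  if (length(uncovered))
    stop("partition does not cover node(s): ",
         paste(utils::head(uncovered, 5), collapse = ", "))
  ci <- mem[g@from]; cj <- mem[g@to]
  eWithin <- tabulate(ci[ci == cj], nClusters(p))
  deg <- degreeSequence(g)
  dSum <- vapply(seq_len(nClusters(p)), function(c)
    sum(deg[names(mem)[mem == c]]), numeric(1))
  sum(eWithin / m - (dSum / (2 * m))^2)
}

#' Greedy modularity agglomeration (CNM)
#'
#' Starts from singleton communities and repeatedly merges the connected
#' community pair with the largest modularity gain until no merge improves
#' `Q`. Equal-gain merges are broken deterministically: the pair whose
#' (smaller, then larger) lexicographically-smallest members sort first is
#' taken, so the algorithm needs no seed.
#'
#' @param g A [Graph] with at least one edge.
#' @return List with `partition` (a [Partition]) and `q` (its modularity).
#' @export
greedyModularity <- function(g) {
  stopifnot(is(g, "Graph"))
  m <- numEdges(g)
  if (m == 0L) stop("community detection needs at least one edge")
  n <- numNodes(g)
  fi <- match(g@from, g@nodes); ti <- match(g@to, g@nodes)
  E <- matrix(0, n, n)                   # between-community edge counts
  for (e in seq_len(m)) E[fi[e], ti[e]] <- E[fi[e], ti[e]] + 1
  E <- E + t(E)                          # symmetric; diagonal = 2 * within
  a <- as.numeric(degreeSequence(g))     # community degree sums
  active <- rep(TRUE, n)
  minMember <- g@nodes                   # smallest node id per community
  comm <- seq_len(n)                     # node -> community index
  repeat {
    D <- E / m - outer(a, a) / (2 * m^2)
    D[E == 0] <- -Inf
    D[!active, ] <- -Inf; D[, !active] <- -Inf
    diag(D) <- -Inf
    best <- max(D)
    if (!is.finite(best) || best <= 1e-12) break
    cand <- which(D >= best - 1e-12 & upper.tri(D), arr.ind = TRUE)
    if (nrow(cand) > 1L) {
      lo <- pmin(minMember[cand[, 1]], minMember[cand[, 2]])
      hi <- pmax(minMember[cand[, 1]], minMember[cand[, 2]])
      cand <- cand[order(lo, hi, method = "radix")[1], , drop = FALSE]
    }
    i <- cand[1, 1]; j <- cand[1, 2]
    # merge j into i
    E[i, ] <- E[i, ] + E[j, ]
    E[, i] <- E[, i] + E[, j]
    E[j, ] <- 0; E[, j] <- 0
    a[i] <- a[i] + a[j]; a[j] <- 0
    active[j] <- FALSE
    minMember[i] <- min(minMember[i], minMember[j])
    comm[comm == j] <- i
  }
  p <- Partition(stats::setNames(comm, g@nodes))
  list(partition = p, q = modularityScore(g, p))
}

# Internal weighted multigraph used by Louvain aggregation:
# edges (i, j, w) with i < j, plus self-loop weights per node.
.louvainLevel <- function(n, nbr, nbrW, deg, m2, order_) {
  comm <- seq_len(n)
  tot <- deg
  improved <- TRUE
  moved <- FALSE
  while (improved) {
    improved <- FALSE
    for (i in order_) {
      ci <- comm[i]
      js <- nbr[[i]]; ws <- nbrW[[i]]
      links <- if (length(js)) tapply(ws, comm[js], sum)
               else stats::setNames(numeric(), character())
      tot[ci] <- tot[ci] - deg[i]
      gainTo <- function(c) {
        l <- links[as.character(c)]
        if (is.na(l)) l <- 0
        unname(l) - deg[i] * tot[c] / m2
      }
      best <- ci; bestGain <- gainTo(ci)
      for (c in as.integer(names(links))) {
        if (c == best) next
        gn <- gainTo(c)
        if (gn > bestGain + 1e-12 ||
            (abs(gn - bestGain) <= 1e-12 && c < best)) {
          best <- c; bestGain <- gn
        }
      }
      tot[best] <- tot[best] + deg[i]
      if (best != ci) { comm[i] <- best; improved <- TRUE; moved <- TRUE }
    }
  }
  list(comm = comm, moved = moved)
}

#' Louvain community detection
#'
#' The standard two-phase heuristic: local moving of nodes to the
#' neighboring community with the best modularity gain until no move helps,
#' then aggregation of communities into super-nodes, repeated until
#' modularity stops improving. Resolution is fixed at 1. The seed controls
#' only the node visit order; the same graph and seed always return the same
#' partition.
#'
#' @param g A [Graph] with at least one edge.
#' @param seed Integer seed for the visit order.
#' @return List with `partition` (a [Partition]) and `q` (its unweighted
#'   modularity on `g`).
#' @export
louvainClusters <- function(g, seed = 1L) {
  stopifnot(is(g, "Graph"))
  if (numEdges(g) == 0L) stop("community detection needs at least one edge")
  nOrig <- numNodes(g)
  # current aggregated graph: edge arrays (i < j, weight) and self-loops
  ei <- match(g@from, g@nodes)
  ej <- match(g@to, g@nodes)
  ew <- rep(1, numEdges(g))
  sl <- numeric(nOrig)
  nodeComm <- seq_len(nOrig)     # original node -> current super-node
  n <- nOrig
  m2 <- 2 * (sum(ew) + sum(sl))
  bestQ <- -Inf
  .withSeed(seed, {
    repeat {
      nbr <- vector("list", n); nbrW <- vector("list", n)
      for (k in seq_along(ei)) {
        i <- ei[k]; j <- ej[k]; w <- ew[k]
        nbr[[i]] <- c(nbr[[i]], j); nbrW[[i]] <- c(nbrW[[i]], w)
        nbr[[j]] <- c(nbr[[j]], i); nbrW[[j]] <- c(nbrW[[j]], w)
      }
      deg <- numeric(n)
      for (i in seq_len(n))
        deg[i] <- sum(nbrW[[i]]) + 2 * sl[i]
      res <- .louvainLevel(n, nbr, nbrW, deg, m2, sample.int(n))
      if (!res$moved) break
      # relabel communities compactly and aggregate
      labs <- sort(unique(res$comm))
      remap <- match(res$comm, labs)
      nodeComm <- remap[nodeComm]
      nNew <- length(labs)
      slNew <- numeric(nNew)
      for (i in seq_len(n)) slNew[remap[i]] <- slNew[remap[i]] + sl[i]
      keyEnv <- new.env(hash = TRUE, parent = emptyenv())
      for (k in seq_along(ei)) {
        ci <- remap[ei[k]]; cj <- remap[ej[k]]
        if (ci == cj) {
          slNew[ci] <- slNew[ci] + ew[k]
        } else {
          key <- as.character((min(ci, cj) - 1) * nNew + max(ci, cj))
          prev <- keyEnv[[key]]
          keyEnv[[key]] <- if (is.null(prev)) ew[k] else prev + ew[k]
        }
      }
      keys <- as.numeric(ls(keyEnv))
      if (length(keys)) {
        ei <- as.integer((keys - 1) %/% nNew + 1)
        ej <- as.integer((keys - 1) %% nNew + 1)
        ew <- vapply(as.character(keys), function(k) keyEnv[[k]], numeric(1))
      } else {
        ei <- integer(); ej <- integer(); ew <- numeric()
      }
      sl <- slNew
      n <- nNew
      if (n == 1L) break
    }
  })
  p <- Partition(stats::setNames(nodeComm, g@nodes))
  list(partition = p, q = modularityScore(g, p))
}

#' Markov clustering (MCL)
#'
#' Native implementation of the expansion/inflation scheme: the adjacency
#' matrix plus unit self-loops is column-normalized into a random-walk
#' transition matrix, then expansion (matrix squaring) and inflation
#' (entrywise power `inflation` followed by column renormalization) alternate,
#' pruning entries below `pruneTol`, until successive matrices differ by less
#' than `convTol` in max-norm or `maxIter` is reached. Clusters are read off
#' the attractor structure: attractor nodes (positive diagonal) connected
#' through mutual attraction form one cluster together with everything they
#' attract; a node attracted by two attractor systems is assigned to the
#' lower cluster index (a message reports the count), yielding a hard
#' partition.
#'
#' @param g A [Graph] with at least one node.
#' @param inflation Inflation exponent, > 1 (default 2).
#' @param maxIter Iteration cap (default 100).
#' @param pruneTol Entries below this are zeroed each iteration.
#' @param convTol Max-norm convergence threshold.
#' @return A [Partition].
#' @export
mclClusters <- function(g, inflation = 2, maxIter = 100L,
                        pruneTol = 1e-5, convTol = 1e-8) {
  stopifnot(is(g, "Graph"), numNodes(g) >= 1L)
  if (inflation <= 1) stop("'inflation' must exceed 1")
  n <- numNodes(g)
  M <- .adjacencyMatrix(g) + diag(n)
  M <- sweep(M, 2L, colSums(M), "/")
  for (iter in seq_len(maxIter)) {
    Mnew <- M %*% M                      # expansion
    Mnew <- Mnew^inflation               # inflation
    Mnew[Mnew < pruneTol] <- 0
    cs <- colSums(Mnew)
    cs[cs == 0] <- 1
    Mnew <- sweep(Mnew, 2L, cs, "/")
    if (max(abs(Mnew - M)) < convTol) { M <- Mnew; break }
    M <- Mnew
  }
  attractors <- which(diag(M) > 0)
  if (!length(attractors)) attractors <- seq_len(n)  # degenerate safeguard
  # attractor systems: attractors linked by mutual mass form one star system
  sysId <- integer(n)
  nSys <- 0L
  for (a in attractors) {
    if (sysId[a]) next
    nSys <- nSys + 1L
    queue <- a; sysId[a] <- nSys
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      linked <- attractors[(M[v, attractors] > 0 | M[attractors, v] > 0) &
                           sysId[attractors] == 0L]
      sysId[linked] <- nSys
      queue <- c(queue, linked)
    }
  }
  # members: every node with mass from an attractor row joins that system
  assign_ <- rep(NA_integer_, n)
  overlap <- 0L
  for (a in attractors) {
    members <- which(M[a, ] > 0)
    for (v in members) {
      if (is.na(assign_[v])) assign_[v] <- sysId[a]
      else if (assign_[v] != sysId[a]) {
        overlap <- overlap + 1L
        assign_[v] <- min(assign_[v], sysId[a])
      }
    }
  }
  if (overlap) message(overlap, " overlapping assignment(s) resolved to the ",
                       "lower cluster index")
  # unattracted nodes (numerically starved columns) become singletons
  orphan <- which(is.na(assign_))
  if (length(orphan))
    assign_[orphan] <- nSys + seq_along(orphan)
  Partition(stats::setNames(assign_, g@nodes))
}

#' Spectral bisection via the Fiedler vector
#'
#' Splits a connected graph in two by the sign pattern of the eigenvector of
#' the second-smallest eigenvalue of the unnormalized Laplacian `L = D - A`.
#' The eigenvector's sign is normalized so that the first nonzero entry (in
#' node order) is positive; entries within `1e-10` of zero join the
#' non-negative side.
#'
#' @param g A connected [Graph] with at least 2 nodes.
#' @return A [Partition] with 2 clusters.
#' @export
spectralBisection <- function(g) {
  stopifnot(is(g, "Graph"), numNodes(g) >= 2L)
  if (length(connectedComponents(g)) != 1L)
    stop("graph is disconnected: apply spectral bisection per component ",
         "(see connectedComponents)")
  n <- numNodes(g)
  A <- .adjacencyMatrix(g)
  L <- diag(rowSums(A)) - A
  es <- eigen(L, symmetric = TRUE)
  fiedler <- es$vectors[, n - 1L]        # second-smallest eigenvalue
  nz <- which(abs(fiedler) > 1e-10)
  if (length(nz) && fiedler[nz[1]] < 0) fiedler <- -fiedler
  side <- ifelse(fiedler > -1e-10, 1L, 2L)
  if (length(unique(side)) == 1L)        # degenerate: split at the median
    side <- ifelse(fiedler >= stats::median(fiedler), 1L, 2L)
  Partition(stats::setNames(side, g@nodes))
}
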