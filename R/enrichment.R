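# Hypergeometric over-representation of annotation terms within clusters.

#' Upper-tail hypergeometric probability
#'
#' Probability of observing at least `k` annotated genes when drawing `n`
#' genes without replacement from a universe of `N` genes of which `K` carry
#' the annotation:
#' `P(X >= k) = sum_{i=k}^{min(n,K)} C(K,i) C(N-K, n-i) / C(N,n)`.
#' Evaluated through the hypergeometric distribution function in log space
#' for numerical stability.
#'
#' @param k Observed annotated genes in the cluster, `0 <= k <= min(n, K)`.
#' @param n Cluster size counted in the universe.
#' @param K Universe genes carrying the annotation.
#' @param N Universe size.
#' @return Numeric p-value in (0, 1\].
#' @examples
#' hypergeomTest(5, 5, 5, 20)  # 1 / choose(20, 5)
#' @export
hypergeomTest <- function(k, n, K, N) {
  if (k < 0) stop("'k' must be non-negative, got ", k)
  if (n > N) stop("cluster size n = ", n, " exceeds universe N = ", N)
  if (K > N) stop("annotated count K = ", K, " exceeds universe N = ", N)
  if (k > min(n, K))
    stop("k = ", k, " exceeds min(n, K) = ", min(n, K))
  if (k == 0) return(1)
  exp(stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE, log.p = TRUE))
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment: p-values are sorted ascending,
#' `adj_i = min_{j >= i} (p_j * m / j)` capped at 1, returned in input order.
#'
#' @param p Numeric vector of p-values in \[0, 1\].
#' @return Adjusted p-values (q-values), same order as input.
#' @export
bhAdjust <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Hypergeometric enrichment of clusters
#'
#' For every cluster large enough (after intersection with the universe) and
#' every annotation term with at least one gene in that cluster, computes the
#' one-sided over-representation p-value with [hypergeomTest()] and adjusts
#' across all tests jointly with Benjamini-Hochberg. The default universe is
#' the statistically defensible one for co-expression networks: the
#' clustered (network) genes that carry at least one annotation; it can be
#' switched to the full annotated gene set or an explicit gene list.
#'
#' @param p A [Partition] of network genes.
#' @param ann An [AnnotationSet].
#' @param universe `"network"` (annotated clustered genes, default),
#'   `"annotation"` (all annotated genes), or an explicit character vector of
#'   gene ids.
#' @param minCluster Smallest in-universe cluster size tested (default 5).
#' @return data.frame with columns `cluster`, `term_id`, `description`,
#'   `k`, `n`, `K`, `N`, `p_value`, `q_value`, sorted by `q_value`,
#'   `p_value`, `term_id`. Zero rows (with a warning) when no cluster gene
#'   carries any term.
#' @export
enrichClusters <- function(p, ann, universe = "network", minCluster = 5L) {
  stopifnot(is(p, "Partition"), is(ann, "AnnotationSet"))
  genes <- names(membership(p))
  annGenes <- annotatedGenes(ann)
  uni <- if (identical(universe, "network")) intersect(genes, annGenes)
         else if (identical(universe, "annotation")) annGenes
         else unique(as.character(universe))
  N <- length(uni)
  if (N == 0L) stop("empty universe: no annotated genes available")
  termSets <- lapply(ann@genes, intersect, uni)
  Ks <- lengths(termSets)
  desc <- termDescriptions(ann)
  rows <- list()
  anyEligible <- FALSE
  for (cl in seq_len(nClusters(p))) {
    members <- intersect(clusterMembers(p, cl), uni)
    n <- length(members)
    if (n < minCluster) next
    anyEligible <- TRUE
    for (t in ann@termIds) {
      K <- Ks[[t]]
      if (K == 0L) next
      k <- length(intersect(members, termSets[[t]]))
      if (k == 0L) next
      rows[[length(rows) + 1L]] <- data.frame(
        cluster = cl, term_id = t, description = unname(desc[[t]]),
        k = k, n = n, K = K, N = N,
        p_value = hypergeomTest(k, n, K, N),
        stringsAsFactors = FALSE)
    }
  }
  if (!anyEligible)
    stop("no cluster reaches minCluster = ", minCluster,
         " genes inside the universe")
  if (!length(rows)) {
    warning("no annotated cluster members; empty enrichment result")
    return(data.frame(cluster = integer(), term_id = character(),
                      description = character(), k = integer(),
                      n = integer(), K = integer(), N = integer(),
                      p_value = numeric(), q_value = numeric()))
  }
  res <- do.call(rbind, rows)
  res$q_value <- bhAdjust(res$p_value)
  res <- res[order(res$q_value, res$p_value, res$term_id,
                   method = "radix"), ]
  rownames(res) <- NULL
  res
}
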