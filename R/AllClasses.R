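#' @import methods
NULL

#' Undirected graph over string node identifiers
#'
#' Central data structure of the package: a simple undirected graph (no
#' self-loops, no duplicate edges) whose nodes are opaque string identifiers.
#' Edges are stored in canonical order (lexicographically smaller endpoint
#' first, rows sorted), so two structurally equal graphs are representation
#' equal and every writer is byte-stable. Edge weights are optional; when
#' present there is exactly one weight per edge.
#'
#' @slot nodes Character vector of node identifiers, sorted, unique.
#' @slot from,to Character vectors of edge endpoints with `from < to`
#'   elementwise, rows sorted by (from, to).
#' @slot weight Numeric vector of edge weights (length 0 for an unweighted
#'   graph, otherwise one per edge).
#' @slot nodeAttrs A data.frame of per-node attributes with a `node` column
#'   (may have zero rows).
#'
#' @seealso [buildGraph()], [degreeSequence()], [connectedComponents()],
#'   [inducedSubgraph()]
#' @export
setClass("Graph",
  representation(
    nodes = "character",
    from = "character",
    to = "character",
    weight = "numeric",
    nodeAttrs = "data.frame"
  ),
  prototype(
    nodes = character(), from = character(), to = character(),
    weight = numeric(), nodeAttrs = data.frame(node = character())
  )
)

setValidity("Graph", function(object) {
  msg <- character()
  if (anyDuplicated(object@nodes))
    msg <- c(msg, "duplicate node identifiers")
  if (length(object@from) != length(object@to))
    msg <- c(msg, "from/to length mismatch")
  if (any(object@from == object@to))
    msg <- c(msg, "self-loop stored")
  if (!all(object@from <= object@to))
    msg <- c(msg, "edges not in canonical order (from < to)")
  ep <- unique(c(object@from, object@to))
  if (!all(ep %in% object@nodes))
    msg <- c(msg, "edge endpoint not among nodes")
  if (length(object@weight) && length(object@weight) != length(object@from))
    msg <- c(msg, "weight vector must be empty or one weight per edge")
  key <- paste(object@from, object@to, sep = "\r")
  if (anyDuplicated(key))
    msg <- c(msg, "duplicate edges stored")
  if (length(msg)) msg else TRUE
})

#' Hard partition of graph nodes into clusters
#'
#' Assigns every node to exactly one cluster. Cluster labels are the integers
#' `1..nClusters`, with clusters numbered by decreasing size and, among equal
#' sizes, by their lexicographically smallest member, so any membership vector
#' has a unique canonical `Partition`.
#'
#' @slot membership Named integer vector, node -> cluster label, names sorted.
#' @slot nClusters Integer, number of clusters.
#'
#' @seealso [modularityScore()], [louvainClusters()], [greedyModularity()],
#'   [mclClusters()], [spectralBisection()], [enrichClusters()]
#' @export
setClass("Partition",
  representation(membership = "integer", nClusters = "integer"),
  prototype(membership = integer(), nClusters = 0L)
)

setValidity("Partition", function(object) {
  m <- object@membership
  msg <- character()
  if (length(m)) {
    if (is.null(names(m)) || anyDuplicated(names(m)))
      msg <- c(msg, "membership must be named with unique node ids")
    labs <- sort(unique(m))
    if (!identical(labs, seq_len(object@nClusters)))
      msg <- c(msg, "cluster labels must be contiguous 1..nClusters")
    if (anyNA(m)) msg <- c(msg, "every node must be assigned")
  } else if (object@nClusters != 0L) {
    msg <- c(msg, "empty membership implies 0 clusters")
  }
  if (length(msg)) msg else TRUE
})

#' Term-to-gene annotation sets
#'
#' Maps annotation terms (e.g. GO biological-process terms, pathway ids, or
#' any custom schema such as gene-disease associations) to the genes they
#' annotate. Input to cluster enrichment.
#'
#' @slot termIds Character vector of unique term identifiers.
#' @slot descriptions Character vector of term descriptions (parallel to
#'   `termIds`).
#' @slot genes Named list (by term id) of character vectors of gene ids; each
#'   term annotates at least one gene, gene sets are deduplicated and sorted.
#' @slot namespace Free-form label for the annotation scheme (e.g. "GO-BP").
#'
#' @seealso [readAnnotations()], [enrichClusters()], [simulateAnnotation()]
#' @export
setClass("AnnotationSet",
  representation(
    termIds = "character",
    descriptions = "character",
    genes = "list",
    namespace = "character"
  ),
  prototype(
    termIds = character(), descriptions = character(),
    genes = list(), namespace = "custom"
  )
)

setValidity("AnnotationSet", function(object) {
  msg <- character()
  if (anyDuplicated(object@termIds)) msg <- c(msg, "duplicate term ids")
  if (length(object@descriptions) != length(object@termIds))
    msg <- c(msg, "descriptions must parallel termIds")
  if (length(object@genes) != length(object@termIds))
    msg <- c(msg, "gene list must parallel termIds")
  if (length(object@genes) &&
      !identical(names(object@genes), object@termIds))
    msg <- c(msg, "gene list names must equal termIds")
  if (any(lengths(object@genes) == 0L))
    msg <- c(msg, "every term must annotate at least one gene")
  if (length(msg)) msg else TRUE
})

#' Null ensemble of randomized graphs with per-metric empirical distributions
#'
#' Result of comparing an observed graph's topology against replicate random
#' graphs (degree-preserving rewiring, Erdos-Renyi, or planted modular).
#' Holds the observed metric values, the per-replicate null values, empirical
#' z-scores `(obs - mean_null) / sd_null`, and percentile ranks. A z-score is
#' `NA` (flagged in `show`) when the null distribution has zero spread.
#'
#' @slot model One of "rewire", "erdos_renyi", "modular".
#' @slot replicates List of the randomized [Graph] replicates.
#' @slot seed Integer master seed used for the ensemble.
#' @slot observed Named numeric of observed metric values.
#' @slot metricNulls Named list of numeric vectors (one null value per
#'   replicate).
#' @slot zScores Named numeric of empirical z-scores.
#' @slot percentiles Named numeric: fraction of null values strictly below the
#'   observed value.
#'
#' @seealso [nullCompare()], [rewireEdges()], [erdosRenyiGraph()],
#'   [randomModularGraph()]
#' @export
setClass("NullEnsemble",
  representation(
    model = "character",
    replicates = "list",
    seed = "integer",
    observed = "numeric",
    metricNulls = "list",
    zScores = "numeric",
    percentiles = "numeric"
  )
)

setValidity("NullEnsemble", function(object) {
  msg <- character()
  if (!object@model %in% c("rewire", "erdos_renyi", "modular"))
    msg <- c(msg, "unknown null model label")
  if (!identical(names(object@observed), names(object@metricNulls)))
    msg <- c(msg, "observed and metricNulls must cover the same metrics")
  if (length(msg)) msg else TRUE
})
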