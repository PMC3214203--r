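# Graph construction and elementary structural queries.

.rsort <- function(x) x[order(x, method = "radix")]

.edgeKey <- function(from, to) paste(from, to, sep = "\r")

#' Build an undirected Graph from an edge list
#'
#' Constructs the canonical [Graph] from node pairs: each edge is stored once
#' with its lexicographically smaller endpoint first, duplicate pairs collapse
#' to the first occurrence (keeping the first weight, with a warning), and
#' self-loops are rejected. Nodes not incident to any edge can be supplied
#' through `nodes` so isolated nodes survive construction.
#'
#' @param edges Two-column matrix or data.frame of node identifier pairs
#'   (character), one row per edge; may have zero rows.
#' @param weights Optional numeric vector of edge weights, one per row of
#'   `edges`.
#' @param nodes Optional character vector of additional (possibly isolated)
#'   node identifiers.
#'
#' @return A [Graph].
#'
#' @examples
#' g <- buildGraph(rbind(c("b", "a"), c("a", "b"), c("b", "c")))
#' numEdges(g)        # 2: the duplicate ("a","b") collapsed
#' degreeSequence(g)
#' @export
buildGraph <- function(edges, weights = NULL, nodes = NULL) {
  if (is.null(edges) || length(edges) == 0L) {
    edges <- matrix(character(), ncol = 2)
  }
  if (is.data.frame(edges)) edges <- as.matrix(edges[, 1:2])
  if (!is.matrix(edges) || ncol(edges) < 2L)
    stop("'edges' must be a two-column matrix or data.frame of node pairs")
  from <- as.character(edges[, 1]); to <- as.character(edges[, 2])
  if (!is.null(weights)) {
    if (length(weights) != length(from))
      stop("length of 'weights' (", length(weights),
           ") does not match number of edge pairs (", length(from), ")")
    weights <- as.numeric(weights)
  }
  loop <- from == to
  if (any(loop))
    stop("self-loop edge not permitted: (", from[which(loop)[1]], ", ",
         to[which(loop)[1]], ")")
  swap <- from > to
  tmp <- from[swap]; from[swap] <- to[swap]; to[swap] <- tmp
  key <- .edgeKey(from, to)
  dup <- duplicated(key)
  if (any(dup)) {
    warning(sum(dup), " duplicate edge(s) collapsed (first weight kept)")
    from <- from[!dup]; to <- to[!dup]
    if (!is.null(weights)) weights <- weights[!dup]
  }
  ord <- order(from, to, method = "radix")
  from <- from[ord]; to <- to[ord]
  if (!is.null(weights)) weights <- weights[ord]
  allNodes <- .rsort(unique(c(from, to, as.character(nodes))))
  new("Graph", nodes = allNodes, from = from, to = to,
      weight = if (is.null(weights)) numeric() else weights,
      nodeAttrs = data.frame(node = character()))
}

#' Graph accessors
#'
#' @param object A [Graph].
#' @return `nodes`: character vector of node ids; `numNodes`, `numEdges`:
#'   integer counts; `edgeTable`: data.frame with columns `from`, `to` and,
#'   for weighted graphs, `weight`; `isWeighted`: logical.
#' @name Graph-accessors
#' @aliases nodes numNodes numEdges edgeTable isWeighted
NULL

#' @rdname Graph-accessors
#' @export
setMethod("nodes", "Graph", function(object) object@nodes)

#' @rdname Graph-accessors
#' @export
setMethod("numNodes", "Graph", function(object) length(object@nodes))

#' @rdname Graph-accessors
#' @export
setMethod("numEdges", "Graph", function(object) length(object@from))

#' @rdname Graph-accessors
#' @export
setMethod("edgeTable", "Graph", function(object) {
  et <- data.frame(from = object@from, to = object@to,
                   stringsAsFactors = FALSE)
  if (length(object@weight)) et$weight <- object@weight
  et
})

#' @rdname Graph-accessors
#' @export
setMethod("isWeighted", "Graph", function(object) length(object@weight) > 0L)

setMethod("show", "Graph", function(object) {
  cat("Graph with", numNodes(object), "nodes and", numEdges(object),
      if (isWeighted(object)) "weighted edges\n" else "edges\n")
  if (numNodes(object)) {
    shown <- utils::head(object@nodes, 6L)
    cat("  nodes:", paste(shown, collapse = ", "),
        if (numNodes(object) > 6L) "...\n" else "\n")
  }
})

# Adjacency list of integer neighbor indices, nodes indexed by position in
# nodes(g). The workhorse for every traversal in the package.
.adjacency <- function(g) {
  n <- numNodes(g)
  adj <- vector("list", n)
  if (n == 0L || numEdges(g) == 0L) {
    for (i in seq_len(n)) adj[[i]] <- integer()
    return(adj)
  }
  fi <- match(g@from, g@nodes)
  ti <- match(g@to, g@nodes)
  ends <- split(c(ti, fi), c(fi, ti))
  for (i in seq_len(n)) adj[[i]] <- integer()
  idx <- as.integer(names(ends))
  for (j in seq_along(idx)) adj[[idx[j]]] <- sort(ends[[j]])
  adj
}

# Dense adjacency matrix (0/1 or weights), nodes in graph order.
.adjacencyMatrix <- function(g, weighted = FALSE) {
  n <- numNodes(g)
  A <- matrix(0, n, n, dimnames = list(g@nodes, g@nodes))
  if (numEdges(g)) {
    fi <- match(g@from, g@nodes); ti <- match(g@to, g@nodes)
    w <- if (weighted && isWeighted(g)) g@weight else rep(1, numEdges(g))
    A[cbind(fi, ti)] <- w
    A[cbind(ti, fi)] <- w
  }
  A
}

#' Node degrees
#'
#' Degree of every node, isolated nodes included with degree 0. The handshake
#' identity `sum(degreeSequence(g)) == 2 * numEdges(g)` always holds.
#'
#' @param object A [Graph].
#' @return Named integer vector, node -> degree, in node order.
#' @examples
#' g <- buildGraph(rbind(c("a", "b"), c("b", "c")))
#' degreeSequence(g)  # a=1, b=2, c=1
#' @export
setMethod("degreeSequence", "Graph", function(object) {
  n <- numNodes(object)
  deg <- integer(n)
  names(deg) <- object@nodes
  if (numEdges(object)) {
    tab <- table(c(object@from, object@to))
    deg[names(tab)] <- as.integer(tab)
  }
  deg
})

#' Connected components
#'
#' Breadth-first decomposition of a graph into its connected components.
#'
#' @param object A [Graph].
#' @return List of character vectors (each sorted), one per component,
#'   ordered by decreasing size then by lexicographically smallest member.
#'   The empty graph yields an empty list.
#' @export
setMethod("connectedComponents", "Graph", function(object) {
  n <- numNodes(object)
  if (n == 0L) return(list())
  adj <- .adjacency(object)
  comp <- integer(n)
  nc <- 0L
  for (s in seq_len(n)) {
    if (comp[s]) next
    nc <- nc + 1L
    queue <- s; comp[s] <- nc
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      nb <- adj[[v]]
      new <- nb[comp[nb] == 0L]
      comp[new] <- nc
      queue <- c(queue, new)
    }
  }
  comps <- split(object@nodes, comp)
  comps <- lapply(comps, .rsort)
  ord <- order(-lengths(comps), vapply(comps, `[`, character(1), 1L),
               method = "radix")
  unname(comps[ord])
})

#' Induced subgraph
#'
#' Restricts a graph to a node subset, keeping all edges with both endpoints
#' in the subset; weights and node attributes are carried over.
#'
#' @param object A [Graph].
#' @param keep Character vector of node identifiers, all present in the graph.
#' @return The induced [Graph].
#' @export
setMethod("inducedSubgraph", "Graph", function(object, keep) {
  keep <- unique(as.character(keep))
  unknown <- setdiff(keep, object@nodes)
  if (length(unknown))
    stop("unknown node(s): ", paste(utils::head(unknown, 5), collapse = ", "))
  sel <- object@from %in% keep & object@to %in% keep
  g <- buildGraph(cbind(object@from[sel], object@to[sel]),
                  weights = if (isWeighted(object)) object@weight[sel],
                  nodes = keep)
  if (nrow(object@nodeAttrs))
    g@nodeAttrs <- object@nodeAttrs[object@nodeAttrs$node %in% keep, ,
                                    drop = FALSE]
  g
})

#' Per-node attributes
#'
#' Attach or retrieve a per-node attribute table (used for Cytoscape export:
#' cluster labels, degrees, centralities).
#'
#' @param g A [Graph].
#' @param attrs A data.frame with a `node` column; other columns are
#'   attributes.
#' @return `setNodeAttributes` returns the modified [Graph];
#'   `nodeAttributes` the attribute data.frame.
#' @export
setNodeAttributes <- function(g, attrs) {
  stopifnot(is(g, "Graph"), is.data.frame(attrs), "node" %in% names(attrs))
  unknown <- setdiff(attrs$node, g@nodes)
  if (length(unknown))
    stop("attribute rows for unknown node(s): ",
         paste(utils::head(unknown, 5), collapse = ", "))
  g@nodeAttrs <- attrs[order(attrs$node, method = "radix"), , drop = FALSE]
  rownames(g@nodeAttrs) <- NULL
  g
}

#' @rdname setNodeAttributes
#' @export
nodeAttributes <- function(g) g@nodeAttrs
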