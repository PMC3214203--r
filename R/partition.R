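# Partition: canonical hard clustering of node identifiers.

#' Construct a canonical Partition from a membership vector
#'
#' Any named assignment of nodes to cluster labels is relabeled to the
#' canonical form: clusters numbered `1..k` by decreasing size, ties broken by
#' the lexicographically smallest member, nodes sorted by identifier. Two
#' structurally identical clusterings therefore always compare equal.
#'
#' @param membership Named vector (names = node ids) of cluster labels; any
#'   atomic label type.
#' @return A [Partition].
#' @examples
#' Partition(c(a = "x", b = "x", c = "y"))
#' @export
Partition <- function(membership) {
  if (!length(membership))
    return(new("Partition", membership = integer(), nClusters = 0L))
  if (is.null(names(membership)) || anyDuplicated(names(membership)))
    stop("'membership' must be named with unique node identifiers")
  if (anyNA(membership)) stop("every node must carry a cluster label")
  nodes <- names(membership)
  ord <- order(nodes, method = "radix")
  membership <- membership[ord]
  nodes <- nodes[ord]
  groups <- split(nodes, as.character(membership))
  smallest <- vapply(groups, function(v) min(v), character(1))
  cord <- order(-lengths(groups), smallest, method = "radix")
  groups <- groups[cord]
  lab <- integer(length(nodes))
  names(lab) <- nodes
  for (i in seq_along(groups)) lab[groups[[i]]] <- i
  new("Partition", membership = lab[nodes], nClusters = length(groups))
}

#' Partition accessors
#'
#' @param object A [Partition].
#' @param label Integer cluster label in `1..nClusters(object)`.
#' @return `membership`: named integer vector node -> cluster;
#'   `nClusters`: integer; `clusterMembers`: sorted character vector of the
#'   nodes in one cluster.
#' @name Partition-accessors
#' @aliases membership nClusters clusterMembers
NULL

#' @rdname Partition-accessors
#' @export
setMethod("membership", "Partition", function(object) object@membership)

#' @rdname Partition-accessors
#' @export
setMethod("nClusters", "Partition", function(object) object@nClusters)

#' @rdname Partition-accessors
#' @export
setMethod("clusterMembers", "Partition", function(object, label) {
  label <- as.integer(label)
  if (label < 1L || label > object@nClusters)
    stop("no cluster with label ", label)
  .rsort(names(object@membership)[object@membership == label])
})

setMethod("show", "Partition", function(object) {
  sizes <- tabulate(object@membership, object@nClusters)
  cat("Partition of", length(object@membership), "nodes into",
      object@nClusters, "clusters\n")
  if (object@nClusters)
    cat("  sizes:", paste(utils::head(sizes, 10L), collapse = ", "),
        if (object@nClusters > 10L) "...\n" else "\n")
})

#' Read / write a clusters table
#'
#' Two-column TSV `node TAB cluster` used by the pipeline and CLI.
#'
#' @param p A [Partition].
#' @param path File path.
#' @return `writeClusters` invisibly returns `path`; `readClusters` a
#'   [Partition].
#' @export
writeClusters <- function(p, path) {
  stopifnot(is(p, "Partition"))
  df <- data.frame(node = names(p@membership), cluster = p@membership)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE, eol = "\n")
  invisible(path)
}

#' @rdname writeClusters
#' @export
readClusters <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          colClasses = c("character", "integer"))
  Partition(stats::setNames(df$cluster, df$node))
}
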