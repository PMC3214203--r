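# Network similarity and boolean edge-set algebra.

#' Jaccard similarity between two networks
#'
#' `J = |E1 n E2| / |E1 u E2|` over canonical edge pairs (nodes matched by
#' identity), with the node-set Jaccard reported alongside. When both edge
#' sets are empty, `J` is defined as 1 and flagged.
#'
#' @param g1,g2 [Graph] objects sharing a node namespace.
#' @return List with `jaccardEdges`, `jaccardNodes`, `sharedEdges`,
#'   `unionEdges`, and `bothEmpty` (logical flag).
#' @export
jaccardIndex <- function(g1, g2) {
  stopifnot(is(g1, "Graph"), is(g2, "Graph"))
  e1 <- .edgeKey(g1@from, g1@to)
  e2 <- .edgeKey(g2@from, g2@to)
  shared <- length(intersect(e1, e2))
  uni <- length(union(e1, e2))
  bothEmpty <- uni == 0L
  nUni <- length(union(g1@nodes, g2@nodes))
  list(
    jaccardEdges = if (bothEmpty) 1 else shared / uni,
    jaccardNodes = if (nUni == 0L) 1
      else length(intersect(g1@nodes, g2@nodes)) / nUni,
    sharedEdges = shared,
    unionEdges = uni,
    bothEmpty = bothEmpty
  )
}

#' Boolean set operations on networks
#'
#' Edge-set union, intersection, or difference (`g1` minus `g2`) of two
#' graphs over their canonical edge pairs. The result's node set is the
#' endpoints of the resulting edges; the union additionally keeps every input
#' node (so isolated nodes survive a union). On a weight conflict the union
#' keeps `g1`'s weight, with a warning.
#'
#' @param g1,g2 [Graph] objects.
#' @param op One of `"union"`, `"intersection"`, `"difference"`.
#' @return A [Graph].
#' @export
graphSetOp <- function(g1, g2, op = c("union", "intersection", "difference")) {
  stopifnot(is(g1, "Graph"), is(g2, "Graph"))
  op <- match.arg(op)
  e1 <- .edgeKey(g1@from, g1@to)
  e2 <- .edgeKey(g2@from, g2@to)
  w1 <- if (isWeighted(g1)) g1@weight else NULL
  w2 <- if (isWeighted(g2)) g2@weight else NULL
  pick <- function(keys) {
    i1 <- match(keys, e1)
    i2 <- match(keys, e2)
    w <- rep(NA_real_, length(keys))
    if (!is.null(w2)) w[!is.na(i2)] <- w2[i2[!is.na(i2)]]
    if (!is.null(w1)) w[!is.na(i1)] <- w1[i1[!is.na(i1)]]
    parts <- strsplit(keys, "\r", fixed = TRUE)
    list(from = vapply(parts, `[`, character(1), 1L),
         to = vapply(parts, `[`, character(1), 2L),
         w = if (all(is.na(w))) NULL else w)
  }
  keys <- switch(op,
    union = union(e1, e2),
    intersection = intersect(e1, e2),
    difference = setdiff(e1, e2))
  if (op == "union" && !is.null(w1) && !is.null(w2)) {
    both <- intersect(e1, e2)
    conflict <- sum(abs(w1[match(both, e1)] - w2[match(both, e2)]) > 0)
    if (conflict)
      warning(conflict, " conflicting edge weight(s); first operand kept")
  }
  sel <- pick(keys)
  extraNodes <- if (op == "union") union(g1@nodes, g2@nodes) else NULL
  buildGraph(cbind(sel$from, sel$to), weights = sel$w, nodes = extraNodes)
}
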