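#' @rdname Graph-accessors
#' @export
setGeneric("nodes", function(object) standardGeneric("nodes"))

#' @rdname Graph-accessors
#' @export
setGeneric("numNodes", function(object) standardGeneric("numNodes"))

#' @rdname Graph-accessors
#' @export
setGeneric("numEdges", function(object) standardGeneric("numEdges"))

#' @rdname Graph-accessors
#' @export
setGeneric("edgeTable", function(object) standardGeneric("edgeTable"))

#' @rdname Graph-accessors
#' @export
setGeneric("isWeighted", function(object) standardGeneric("isWeighted"))

#' @rdname degreeSequence
#' @export
setGeneric("degreeSequence", function(object) standardGeneric("degreeSequence"))

#' @rdname connectedComponents
#' @export
setGeneric("connectedComponents",
  function(object) standardGeneric("connectedComponents"))

#' @rdname inducedSubgraph
#' @export
setGeneric("inducedSubgraph",
  function(object, keep) standardGeneric("inducedSubgraph"))

#' @rdname Partition-accessors
#' @export
setGeneric("membership", function(object) standardGeneric("membership"))

#' @rdname Partition-accessors
#' @export
setGeneric("nClusters", function(object) standardGeneric("nClusters"))

#' @rdname Partition-accessors
#' @export
setGeneric("clusterMembers",
  function(object, label) standardGeneric("clusterMembers"))

#' @rdname AnnotationSet-accessors
#' @export
setGeneric("termIds", function(object) standardGeneric("termIds"))

#' @rdname AnnotationSet-accessors
#' @export
setGeneric("termGenes", function(object, term) standardGeneric("termGenes"))

#' @rdname AnnotationSet-accessors
#' @export
setGeneric("termDescriptions",
  function(object) standardGeneric("termDescriptions"))
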