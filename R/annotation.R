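# AnnotationSet: term -> gene-set mapping for enrichment.

#' Construct an AnnotationSet
#'
#' @param genes Named list: term id -> character vector of gene ids (each
#'   nonempty; duplicates within a term are dropped).
#' @param descriptions Optional character vector of term descriptions, same
#'   length as `genes` (defaults to the term ids).
#' @param namespace Free-form label for the annotation scheme.
#' @return An [AnnotationSet].
#' @examples
#' AnnotationSet(list(T1 = c("g1", "g2"), T2 = "g3"), namespace = "demo")
#' @export
AnnotationSet <- function(genes, descriptions = NULL, namespace = "custom") {
  stopifnot(is.list(genes), !is.null(names(genes)))
  ids <- names(genes)
  if (is.null(descriptions)) descriptions <- ids
  genes <- lapply(genes, function(g) .rsort(unique(as.character(g))))
  new("AnnotationSet", termIds = ids,
      descriptions = as.character(descriptions),
      genes = genes, namespace = namespace)
}

#' AnnotationSet accessors
#'
#' @param object An [AnnotationSet].
#' @param term A term identifier.
#' @return `termIds`: character vector; `termGenes`: sorted gene ids of one
#'   term; `termDescriptions`: named character vector term -> description.
#' @name AnnotationSet-accessors
#' @aliases termIds termGenes termDescriptions
NULL

#' @rdname AnnotationSet-accessors
#' @export
setMethod("termIds", "AnnotationSet", function(object) object@termIds)

#' @rdname AnnotationSet-accessors
#' @export
setMethod("termGenes", "AnnotationSet", function(object, term) {
  if (!term %in% object@termIds) stop("unknown term: ", term)
  object@genes[[term]]
})

#' @rdname AnnotationSet-accessors
#' @export
setMethod("termDescriptions", "AnnotationSet", function(object)
  stats::setNames(object@descriptions, object@termIds))

setMethod("show", "AnnotationSet", function(object) {
  cat("AnnotationSet [", object@namespace, "] with ",
      length(object@termIds), " terms over ",
      length(unique(unlist(object@genes, use.names = FALSE))),
      " genes\n", sep = "")
})

#' All genes covered by an annotation set
#'
#' @param ann An [AnnotationSet].
#' @return Sorted character vector of every annotated gene.
#' @export
annotatedGenes <- function(ann) {
  stopifnot(is(ann, "AnnotationSet"))
  .rsort(unique(unlist(ann@genes, use.names = FALSE)))
}
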