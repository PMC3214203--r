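# Readers and writers for every file format the toolbox touches.
# All writers are deterministic: the same in-memory object always produces a
# byte-identical file (canonical orders, "\n" line endings, no quoting).

#' Read a genes x samples expression matrix from TSV
#'
#' Expects a header row of sample identifiers, a first column of gene
#' identifiers, and a numeric body. Missing values may be encoded as `NA` or
#' an empty cell; they propagate to pairwise-complete correlation downstream.
#'
#' @param path Path to a tab-separated expression file.
#' @return Numeric matrix (genes in rows, samples in columns) with gene ids
#'   as rownames and sample ids as colnames, in file order.
#' @export
readExpressionMatrix <- function(path) {
  lines <- readLines(path)
  if (length(lines) < 2L) stop("no genes: expression file has no data rows")
  # keep trailing empty cells (strsplit drops them): sentinel-pad each line
  splitRow <- function(x) {
    f <- strsplit(paste0(x, "\x01"), "\t", fixed = TRUE)
    lapply(f, function(v) { v[length(v)] <- sub("\x01$", "", v[length(v)]); v })
  }
  header <- splitRow(lines[1])[[1]]
  body <- splitRow(lines[-1])
  nf <- lengths(body)
  # header may or may not carry a corner label for the gene-id column
  nsamp <- if (all(nf == length(header))) length(header) - 1L
           else length(header)
  bad <- which(nf != nsamp + 1L)
  if (length(bad))
    stop("ragged row at line ", bad[1] + 1L, ": expected ", nsamp + 1L,
         " fields, found ", nf[bad[1]])
  sampleIds <- utils::tail(header, nsamp)
  geneIds <- vapply(body, `[`, character(1), 1L)
  dupG <- geneIds[duplicated(geneIds)]
  if (length(dupG)) stop("duplicate gene id: ", dupG[1])
  cells <- t(vapply(body, function(f) f[-1L], character(nsamp)))
  if (nsamp == 1L) cells <- matrix(cells, ncol = 1L)
  cells[cells == ""] <- NA_character_
  suppressWarnings(vals <- matrix(as.numeric(cells), nrow = length(geneIds)))
  nonNum <- !is.na(cells) & cells != "NA" & is.na(vals)
  if (any(nonNum)) {
    at <- which(nonNum, arr.ind = TRUE)[1, ]
    stop("non-numeric cell '", cells[at[1], at[2]], "' at line ",
         at[1] + 1L, ", column ", at[2] + 1L)
  }
  dimnames(vals) <- list(geneIds, sampleIds)
  vals
}

#' Read a network from a 2- or 3-column edge list
#'
#' Whitespace- or tab-delimited, two node columns plus an optional weight
#' column; lines starting with `#` are comments. Self-loops are rejected and
#' duplicate pairs collapse (first weight kept, with a warning), as in
#' [buildGraph()].
#'
#' @param path Path to the edge-list file.
#' @param weighted Parse a third column as edge weights.
#' @return A [Graph].
#' @export
readEdgeList <- function(path, weighted = FALSE) {
  lines <- readLines(path)
  keep <- !grepl("^\\s*(#|$)", lines)
  lineNo <- which(keep)
  fields <- strsplit(trimws(lines[keep]), "[ \t]+")
  if (!length(fields)) return(buildGraph(NULL))
  nf <- lengths(fields)
  bad <- which(nf < 2L)
  if (length(bad))
    stop("line ", lineNo[bad[1]], ": expected at least 2 columns, found ",
         nf[bad[1]])
  from <- vapply(fields, `[`, character(1), 1L)
  to <- vapply(fields, `[`, character(1), 2L)
  w <- NULL
  if (weighted) {
    if (any(nf < 3L))
      stop("line ", lineNo[which(nf < 3L)[1]],
           ": weighted edge list needs a third column")
    w <- as.numeric(vapply(fields, `[`, character(1), 3L))
    if (anyNA(w))
      stop("line ", lineNo[which(is.na(w))[1]], ": non-numeric weight")
  }
  buildGraph(cbind(from, to), weights = w)
}

#' Write a graph as a 2/3-column edge list
#'
#' @param g A [Graph].
#' @param path Output path.
#' @param keepWeights Write the weight column when the graph is weighted.
#' @return Invisibly, `path`.
#' @export
writeEdgeList <- function(g, path, keepWeights = TRUE) {
  stopifnot(is(g, "Graph"))
  et <- edgeTable(g)
  if (!keepWeights) et$weight <- NULL
  if (!is.null(et$weight)) et$weight <- formatC(et$weight, format = "g",
                                                digits = 15)
  lines <- do.call(paste, c(unname(as.list(et)), sep = "\t"))
  writeLines(lines, path)
  invisible(path)
}

#' Read a STRING protein.links file
#'
#' Parses the STRING database's offline `protein.links` format (header
#' `protein1 protein2 combined_score`, space-delimited, integer scores on a
#' 0-1000 scale, every pair listed in both orientations). Pairs at or above
#' the score threshold are kept as single undirected edges with weight
#' `score / 1000` (STRING's probability convention).
#'
#' @param path Path to a protein.links-format file.
#' @param scoreThreshold Integer in 0-1000; edges with `combined_score`
#'   below it are dropped.
#' @return A weighted [Graph].
#' @export
readStringLinks <- function(path, scoreThreshold = 400) {
  stopifnot(scoreThreshold >= 0, scoreThreshold <= 1000)
  lines <- readLines(path)
  if (!length(lines)) stop("empty STRING links file")
  header <- strsplit(trimws(lines[1]), "[ \t]+")[[1]]
  if (length(header) < 3L ||
      !identical(tolower(header[1:3]),
                 c("protein1", "protein2", "combined_score")))
    stop("malformed STRING header: expected 'protein1 protein2 combined_score'")
  body <- strsplit(trimws(lines[-1]), "[ \t]+")
  body <- body[lengths(body) > 0L]
  if (!length(body)) return(buildGraph(NULL))
  p1 <- vapply(body, `[`, character(1), 1L)
  p2 <- vapply(body, `[`, character(1), 2L)
  sc <- vapply(body, `[`, character(1), 3L)
  scNum <- suppressWarnings(as.integer(sc))
  bad <- which(is.na(scNum) | scNum != as.numeric(sc))
  if (length(bad))
    stop("line ", bad[1] + 1L, ": non-integer combined_score '", sc[bad[1]], "'")
  keep <- scNum >= scoreThreshold
  if (!any(keep)) return(buildGraph(NULL))
  suppressWarnings(  # orientation duplicates collapse by design
    buildGraph(cbind(p1[keep], p2[keep]), weights = scNum[keep] / 1000)
  )
}

#' Read annotations from GMT or 2-column long format
#'
#' By default the format is detected by column count: lines with three or
#' more tab-separated fields are GMT (`term TAB description TAB gene...`);
#' files whose lines all have exactly two fields are long-format
#' `gene TAB term` pairs. Passing `format = "gmt"` or `format = "long"`
#' pins the dialect, turning short GMT lines into errors instead of a
#' silent long-format parse. Duplicate genes within a term are deduplicated.
#'
#' @param path Path to the annotation file.
#' @param namespace Label stored on the returned set.
#' @param format `"auto"` (default), `"gmt"`, or `"long"`.
#' @return An [AnnotationSet].
#' @export
readAnnotations <- function(path, namespace = "custom",
                            format = c("auto", "gmt", "long")) {
  format <- match.arg(format)
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  if (!length(lines)) stop("empty annotation file")
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (format == "long" && any(nf != 2L))
    stop("line ", which(nf != 2L)[1],
         ": long format needs exactly 2 columns")
  if (format != "gmt" && all(nf == 2L)) {   # long format: gene TAB term
    gene <- vapply(fields, `[`, character(1), 1L)
    term <- vapply(fields, `[`, character(1), 2L)
    genes <- split(gene, term)
    return(AnnotationSet(genes[.rsort(names(genes))], namespace = namespace))
  }
  bad <- which(nf < 3L)
  if (length(bad))
    stop("line ", bad[1], ": GMT line needs term, description and >=1 gene")
  ids <- vapply(fields, `[`, character(1), 1L)
  dup <- ids[duplicated(ids)]
  if (length(dup)) stop("duplicate term id: ", dup[1])
  desc <- vapply(fields, `[`, character(1), 2L)
  genes <- lapply(fields, function(f) f[-(1:2)])
  names(genes) <- ids
  AnnotationSet(genes, descriptions = desc, namespace = namespace)
}

#' Write an annotation set in GMT format
#'
#' @param ann An [AnnotationSet].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
writeGMT <- function(ann, path) {
  stopifnot(is(ann, "AnnotationSet"))
  desc <- termDescriptions(ann)
  lines <- vapply(ann@termIds, function(t)
    paste(c(t, desc[[t]], ann@genes[[t]]), collapse = "\t"), character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Export a graph in Cytoscape SIF format
#'
#' One line per edge, `source TAB interaction TAB target`, in canonical edge
#' order; isolated nodes are written as bare single-field lines so they load
#' into Cytoscape too.
#'
#' @param g A [Graph].
#' @param path Output path.
#' @param interactionLabel Interaction type written on every edge
#'   (default "ce", co-expression).
#' @return Invisibly, `path`.
#' @export
writeSIF <- function(g, path, interactionLabel = "ce") {
  stopifnot(is(g, "Graph"))
  edgeLines <- if (numEdges(g))
    paste(g@from, interactionLabel, g@to, sep = "\t") else character()
  isolated <- setdiff(g@nodes, unique(c(g@from, g@to)))
  writeLines(c(edgeLines, .rsort(isolated)), path)
  invisible(path)
}

#' Read a SIF file back into a Graph
#'
#' @param path Path to a SIF file written by [writeSIF()] (or any SIF with
#'   one interaction per line).
#' @return A [Graph] (unweighted; SIF carries no weights).
#' @export
readSIF <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  fields <- strsplit(lines, "[ \t]+")
  nf <- lengths(fields)
  singles <- vapply(fields[nf == 1L], `[`, character(1), 1L)
  eds <- fields[nf >= 3L]
  from <- vapply(eds, `[`, character(1), 1L)
  to <- vapply(eds, `[`, character(1), 3L)
  buildGraph(cbind(from, to), nodes = singles)
}

#' Write a Cytoscape node-attribute table
#'
#' TSV with header `node` plus the attribute keys in sorted order; rows in
#' lexicographic node order; attributes missing for a node are written as
#' `NA`.
#'
#' @param table Either a data.frame with a `node` column, or a named list
#'   node -> (named list key -> value).
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
writeNodeAttributes <- function(table, path) {
  if (!is.data.frame(table)) {
    keys <- unique(unlist(lapply(table, names)))
    keys <- if (is.null(keys)) character() else .rsort(keys)
    rows <- lapply(names(table), function(nd) {
      vals <- lapply(keys, function(k) {
        v <- table[[nd]][[k]]
        if (is.null(v)) NA else v
      })
      stats::setNames(c(list(node = nd), vals), c("node", keys))
    })
    table <- if (length(rows))
      do.call(rbind, lapply(rows, as.data.frame,
                            stringsAsFactors = FALSE))
    else data.frame(node = character())
  }
  stopifnot("node" %in% names(table))
  attrCols <- .rsort(setdiff(names(table), "node"))
  table <- table[order(table$node, method = "radix"),
                 c("node", attrCols), drop = FALSE]
  utils::write.table(table, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE, eol = "\n",
                     na = "NA")
  invisible(path)
}
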