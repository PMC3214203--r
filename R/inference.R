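# Co-expression network inference: Pearson similarity + thresholding.

#' Pairwise Pearson correlation between gene expression profiles
#'
#' Computes the Pearson correlation coefficient for every gene pair across
#' samples, using pairwise-complete observations. A pair's correlation is
#' defined only when at least `minPairs` complete sample pairs support it;
#' otherwise the entry is `NA` and excluded by [thresholdNetwork()]. Rows of
#' zero variance cannot correlate and yield `NA` entries (with a warning
#' naming them).
#'
#' @param expr Numeric matrix, genes in rows (rownames = gene ids), samples
#'   in columns; at least 3 samples.
#' @param minPairs Minimum number of complete sample pairs per correlation
#'   (default 3).
#' @return Symmetric numeric matrix of correlations with unit diagonal and
#'   gene ids as dimnames; attribute `measure` set to `"pearson"`.
#' @examples
#' m <- rbind(g1 = c(1, 2, 3, 4), g2 = c(2, 4, 6, 8), g3 = c(4, 3, 2, 1))
#' pearsonSimilarity(m)
#' @export
pearsonSimilarity <- function(expr, minPairs = 3) {
  stopifnot(is.matrix(expr), is.numeric(expr))
  if (is.null(rownames(expr))) stop("'expr' must carry gene ids as rownames")
  if (ncol(expr) < 3L)
    stop("need at least 3 samples to correlate, got ", ncol(expr))
  ok <- !is.na(expr)
  nPairs <- tcrossprod(ok * 1)            # complete pairs per gene pair
  suppressWarnings(
    r <- stats::cor(t(expr), use = "pairwise.complete.obs",
                    method = "pearson"))
  r[nPairs < minPairs] <- NA_real_
  zeroVar <- apply(expr, 1L, function(x) {
    x <- x[!is.na(x)]
    length(x) < 2L || stats::sd(x) == 0
  })
  if (any(zeroVar)) {
    warning("zero-variance gene(s) yield undefined correlations: ",
            paste(utils::head(rownames(expr)[zeroVar], 5), collapse = ", "))
    r[zeroVar, ] <- NA_real_
    r[, zeroVar] <- NA_real_
  }
  diag(r) <- 1
  attr(r, "measure") <- "pearson"
  r
}

#' Threshold a similarity matrix into a co-expression network
#'
#' Retains the gene pairs whose similarity magnitude reaches the cutoff
#' `tau` (inclusive, \eqn{|r| \ge \tau}; or signed \eqn{r \ge \tau} when
#' `absolute = FALSE`) as edges of an undirected graph. Edge weights store the
#' signed correlation so sign information survives thresholding on magnitude;
#' export can strip weights for an unweighted network. Undefined (`NA`)
#' similarity entries are skipped, with a message reporting the count. By
#' default only genes incident to at least one retained edge become nodes.
#'
#' @param sim Symmetric numeric similarity matrix with ids as dimnames (e.g.
#'   from [pearsonSimilarity()]).
#' @param tau Real cutoff; in (0, 1] for absolute Pearson thresholding.
#' @param absolute Threshold on `|r|` (default) or on signed `r`.
#' @param keepIsolates Keep genes with no retained edge as isolated nodes.
#' @return A weighted [Graph].
#' @examples
#' s <- matrix(c(1, .95, -.92, .95, 1, .3, -.92, .3, 1), 3, 3,
#'             dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
#' numEdges(thresholdNetwork(s, tau = 0.9))            # 2
#' numEdges(thresholdNetwork(s, tau = 0.9, absolute = FALSE))  # 1
#' @export
thresholdNetwork <- function(sim, tau, absolute = TRUE,
                             keepIsolates = FALSE) {
  stopifnot(is.matrix(sim), nrow(sim) == ncol(sim))
  ids <- rownames(sim)
  if (is.null(ids)) stop("'sim' must carry ids as dimnames")
  measure <- attr(sim, "measure")
  if (absolute && identical(measure, "pearson") && (tau <= 0 || tau > 1))
    stop("'tau' must lie in (0, 1] for absolute correlation thresholding")
  ut <- upper.tri(sim)
  rv <- sim[ut]
  idx <- which(ut, arr.ind = TRUE)
  nNA <- sum(is.na(rv))
  if (nNA) message(nNA, " undefined similarity entries skipped")
  keep <- !is.na(rv) & (if (absolute) abs(rv) else rv) >= tau
  g <- buildGraph(cbind(ids[idx[keep, 1]], ids[idx[keep, 2]]),
                  weights = rv[keep],
                  nodes = if (keepIsolates) ids)
  g
}
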