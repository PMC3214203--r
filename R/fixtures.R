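# Synthetic data with known ground truth: expression matrices with planted
# co-expression modules and matched annotation sets. Everything is
# seed-deterministic so tests and demos run fully offline.

#' Simulate an expression matrix with planted co-expression modules
#'
#' Single-latent-factor model per module: module `c` has a latent sample
#' profile `z_c ~ N(0, 1)`; each member gene is
#' `sqrt(w) * z_c + sqrt(1 - w) * noiseSd * eps`, with `eps ~ N(0, 1)`
#' independent per gene. With `noiseSd = 1` the population Pearson
#' correlation between two genes of the same module is exactly
#' `w = withinCorr`, and (in expectation) 0 between modules, which makes the
#' generator easy to reason about in tests. With `signFlip = TRUE` the second
#' half of each module's genes loads negatively on the latent factor, so
#' within-module correlations of magnitude `w` but negative sign appear and
#' absolute-value thresholding is exercised.
#'
#' @param nGenes Number of genes (>= nModules).
#' @param nModules Number of planted modules.
#' @param nSamples Number of samples (>= 4).
#' @param withinCorr Population within-module correlation `w`, in (0, 1).
#' @param noiseSd Standard deviation multiplier of the gene-specific noise
#'   (default 1, which makes the realized within-module correlation equal
#'   `withinCorr`).
#' @param signFlip Give half of each module's genes a negative loading.
#' @param seed Integer seed; outputs are byte-identical per (spec, seed).
#' @return List with `expr` (genes x samples numeric matrix, rownames
#'   `g001...`, colnames `s01...`) and `truth` (the gene-to-module
#'   [Partition]).
#' @export
simulateModularExpression <- function(nGenes = 120L, nModules = 4L,
                                      nSamples = 40L, withinCorr = 0.8,
                                      noiseSd = 1, signFlip = FALSE,
                                      seed = 1L) {
  stopifnot(nModules <= nGenes, nSamples >= 4L,
            withinCorr > 0, withinCorr < 1, noiseSd > 0)
  geneIds <- sprintf("g%03d", seq_len(nGenes))
  sampleIds <- sprintf("s%02d", seq_len(nSamples))
  base <- nGenes %/% nModules
  sizes <- rep(base, nModules) +
    c(rep(1L, nGenes %% nModules), rep(0L, nModules - nGenes %% nModules))
  module <- rep(seq_len(nModules), sizes)
  expr <- .withSeed(seed, {
    latent <- matrix(stats::rnorm(nModules * nSamples), nModules, nSamples)
    eps <- matrix(stats::rnorm(nGenes * nSamples), nGenes, nSamples)
    loading <- rep(1, nGenes)
    if (signFlip) {
      for (c in seq_len(nModules)) {
        idx <- which(module == c)
        loading[idx[seq_len(length(idx) %/% 2)]] <- -1
      }
    }
    sqrt(withinCorr) * loading * latent[module, , drop = FALSE] +
      sqrt(1 - withinCorr) * noiseSd * eps
  })
  dimnames(expr) <- list(geneIds, sampleIds)
  list(expr = expr,
       truth = Partition(stats::setNames(module, geneIds)))
}

#' Simulate an annotation set matched to planted modules
#'
#' One term per true module (`M1..Mk`) containing a random
#' `coverage`-fraction subset of that module's genes, plus `decoyTerms`
#' random gene sets whose sizes are drawn from the range of the true term
#' sizes. Deterministic per seed.
#'
#' @param truth The ground-truth [Partition] from
#'   [simulateModularExpression()].
#' @param coverage Fraction of each module's genes its term annotates,
#'   in (0, 1\].
#' @param decoyTerms Number of random decoy terms.
#' @param seed Integer seed.
#' @return An [AnnotationSet] with namespace `"synthetic"`.
#' @export
simulateAnnotation <- function(truth, coverage = 1, decoyTerms = 0L,
                               seed = 1L) {
  stopifnot(is(truth, "Partition"), coverage > 0, coverage <= 1)
  allGenes <- names(membership(truth))
  k <- nClusters(truth)
  .withSeed(seed, {
    genes <- vector("list", k + decoyTerms)
    names(genes) <- c(paste0("M", seq_len(k)),
                      if (decoyTerms > 0) paste0("D", seq_len(decoyTerms)))
    trueSizes <- integer(k)
    for (c in seq_len(k)) {
      members <- clusterMembers(truth, c)
      sz <- max(1L, as.integer(round(coverage * length(members))))
      genes[[c]] <- if (sz >= length(members)) members
                    else sample(members, sz)
      trueSizes[c] <- sz
    }
    for (d in seq_len(decoyTerms)) {
      sz <- if (min(trueSizes) == max(trueSizes)) min(trueSizes)
            else sample(seq(min(trueSizes), max(trueSizes)), 1L)
      genes[[k + d]] <- sample(allGenes, sz)
    }
    AnnotationSet(genes,
                  descriptions = c(paste("planted module", seq_len(k)),
                                   if (decoyTerms > 0)
                                     paste("decoy term", seq_len(decoyTerms))),
                  namespace = "synthetic")
  })
}

#' Write a simulated fixture to disk
#'
#' Writes the expression TSV, the GMT annotation file, and the ground-truth
#' clusters table for a planted-module fixture, as consumed by the pipeline
#' and CLI.
#'
#' @param outPrefix Path prefix; writes `<prefix>expr.tsv`,
#'   `<prefix>annotations.gmt`, `<prefix>truth.tsv`.
#' @param ... Passed to [simulateModularExpression()].
#' @param coverage,decoyTerms Passed to [simulateAnnotation()].
#' @param seed Integer seed (shared by both generators).
#' @return Invisibly, named character vector of the three paths.
#' @export
writeFixture <- function(outPrefix, ..., coverage = 1, decoyTerms = 2L,
                         seed = 1L) {
  fx <- simulateModularExpression(..., seed = seed)
  ann <- simulateAnnotation(fx$truth, coverage = coverage,
                            decoyTerms = decoyTerms, seed = seed)
  exprPath <- paste0(outPrefix, "expr.tsv")
  gmtPath <- paste0(outPrefix, "annotations.gmt")
  truthPath <- paste0(outPrefix, "truth.tsv")
  df <- data.frame(gene = rownames(fx$expr), fx$expr, check.names = FALSE)
  utils::write.table(df, exprPath, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE, eol = "\n")
  writeGMT(ann, gmtPath)
  writeClusters(fx$truth, truthPath)
  invisible(c(expr = exprPath, annotations = gmtPath, truth = truthPath))
}
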