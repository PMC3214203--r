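# End-to-end workflow: infer -> topology -> null comparison -> communities ->
# enrichment -> Cytoscape export, with a run log and deterministic outputs.

.pipelineDefaults <- list(
  expr = NULL, annotations = NULL, outdir = NULL,
  tau = 0.9, absolute = TRUE,
  null_model = "rewire", null_reps = 10L,
  cluster_method = "louvain",
  universe = "network", min_cluster = 5L,
  sif_label = "ce", keep_weights = TRUE,
  mcl_inflation = 2.0,
  seed = 42L
)

#' Read a flat key = value run configuration
#'
#' One `key = value` (or `key<TAB>value`) pair per line; `#` starts a
#' comment. Keys mirror [runPipeline()]'s arguments 1:1 and unknown keys are
#' an error so typos cannot silently fall back to defaults.
#'
#' @param path Path to the config file.
#' @return Named list of configuration values (typed).
#' @export
readRunConfig <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  cfg <- list()
  for (ln in lines) {
    kv <- strsplit(sub("=", "\r", ln), "\r", fixed = TRUE)[[1]]
    if (length(kv) != 2L) kv <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    if (length(kv) != 2L) stop("malformed config line: ", ln)
    key <- trimws(kv[1]); val <- trimws(kv[2])
    if (!key %in% names(.pipelineDefaults))
      stop("unknown config key: ", key)
    proto <- .pipelineDefaults[[key]]
    cfg[[key]] <-
      if (is.logical(proto)) toupper(val) %in% c("TRUE", "T", "YES", "1")
      else if (is.integer(proto)) as.integer(val)
      else if (is.numeric(proto)) as.numeric(val)
      else val
  }
  cfg
}

.logLine <- function(con, ...) {
  msg <- paste0(format(Sys.time(), "%Y-%m-%d %H:%M:%S"), " INFO ", ...)
  writeLines(msg, con)
  message(msg)
}

#' Run the full co-expression network workflow
#'
#' Executes: (1) network inference from the expression matrix by Pearson
#' correlation and |r| >= tau thresholding; (2) topology summary;
#' (3) comparison against a random-graph null ensemble; (4) community
#' detection; (5) hypergeometric cluster enrichment (when annotations are
#' given); (6) Cytoscape SIF + node-attribute export. Every output lands in
#' `outdir` and `run.log` records the package version, every effective
#' parameter, and every seed; re-running the same configuration reproduces
#' byte-identical TSV outputs. A failing stage aborts with the stage named,
#' keeping the outputs of completed stages and a `MANIFEST` listing them.
#'
#' @param config A named list (e.g. from [readRunConfig()]); entries override
#'   the defaults: `expr` (expression TSV path, required), `annotations`
#'   (GMT or 2-column file, optional), `outdir` (required), `tau`,
#'   `absolute`, `null_model`, `null_reps`, `cluster_method` (louvain,
#'   greedy, mcl, or spectral), `universe`, `min_cluster`, `sif_label`,
#'   `keep_weights`, `mcl_inflation`, `seed`.
#' @param ... Individual settings overriding `config`.
#' @return Invisibly, the output directory path.
#' @export
runPipeline <- function(config = list(), ...) {
  over <- list(...)
  cfg <- .pipelineDefaults
  for (k in names(config)) {
    if (!k %in% names(cfg)) stop("unknown config key: ", k)
    cfg[[k]] <- config[[k]]
  }
  for (k in names(over)) {
    if (!k %in% names(cfg)) stop("unknown config key: ", k)
    cfg[[k]] <- over[[k]]
  }
  if (is.null(cfg$outdir)) stop("config key 'outdir' is required")
  dir.create(cfg$outdir, showWarnings = FALSE, recursive = TRUE)
  logPath <- file.path(cfg$outdir, "run.log")
  logCon <- file(logPath, open = "wt")
  on.exit(close(logCon), add = TRUE)
  manifest <- character()
  noteOutput <- function(f) {
    manifest <<- c(manifest, f)
    writeLines(manifest, file.path(cfg$outdir, "MANIFEST"))
  }
  stage <- function(name, expr_) {
    tryCatch(expr_, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  .logLine(logCon, "geconet version ",
           as.character(utils::packageVersion("geconet")))
  for (k in names(cfg))
    .logLine(logCon, "param ", k, " = ",
             if (is.null(cfg[[k]])) "<unset>" else as.character(cfg[[k]]))

  # -- infer ---------------------------------------------------------------
  net <- stage("infer", {
    if (is.null(cfg$expr)) stop("config key 'expr' is required")
    if (!file.exists(cfg$expr))
      stop("expression file not found: ", cfg$expr)
    expr <- readExpressionMatrix(cfg$expr)
    sim <- pearsonSimilarity(expr)
    g <- suppressMessages(
      thresholdNetwork(sim, tau = cfg$tau, absolute = cfg$absolute))
    .logLine(logCon, "infer: ", nrow(expr), " genes x ", ncol(expr),
             " samples -> ", numNodes(g), " nodes, ", numEdges(g),
             " edges at tau = ", cfg$tau)
    if (numEdges(g) == 0L) stop("no edges at tau = ", cfg$tau)
    writeEdgeList(g, file.path(cfg$outdir, "net.tsv"),
                  keepWeights = cfg$keep_weights)
    noteOutput("net.tsv")
    g
  })

  # -- topology ------------------------------------------------------------
  topo <- stage("topology", {
    ts <- topologySummary(net)
    utils::write.table(format(ts$global, digits = 10),
                       file.path(cfg$outdir, "topology_summary.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE,
                       eol = "\n")
    noteOutput("topology_summary.tsv")
    .logLine(logCon, "topology: diameter = ", ts$global$diameter,
             ", average degree = ",
             formatC(ts$global$average_degree, digits = 4, format = "g"))
    ts
  })

  # -- null comparison -----------------------------------------------------
  stage("nullcmp", {
    ens <- suppressWarnings(
      nullCompare(net, model = cfg$null_model, nReps = cfg$null_reps,
                  metrics = c("average_clustering", "assortativity",
                              "mean_betweenness"),
                  seed = cfg$seed))
    utils::write.table(format(nullReport(ens), digits = 10),
                       file.path(cfg$outdir, "null_report.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE,
                       eol = "\n")
    noteOutput("null_report.tsv")
    .logLine(logCon, "nullcmp: ", cfg$null_reps, " '", cfg$null_model,
             "' replicates, master seed ", cfg$seed)
  })

  # -- clustering ----------------------------------------------------------
  part <- stage("cluster", {
    res <- switch(cfg$cluster_method,
      louvain = louvainClusters(net, seed = cfg$seed),
      greedy = greedyModularity(net),
      mcl = list(partition = mclClusters(net,
                                         inflation = cfg$mcl_inflation),
                 q = NA_real_),
      spectral = list(partition = spectralBisection(net), q = NA_real_),
      stop("unknown cluster_method: ", cfg$cluster_method))
    p <- res$partition
    if (is.na(res$q) ) res$q <- modularityScore(net, p)
    writeClusters(p, file.path(cfg$outdir, "clusters.tsv"))
    noteOutput("clusters.tsv")
    .logLine(logCon, "cluster: ", cfg$cluster_method, " -> ",
             nClusters(p), " clusters, Q = ",
             formatC(res$q, digits = 4, format = "g"))
    p
  })

  # -- enrichment ----------------------------------------------------------
  if (!is.null(cfg$annotations)) {
    stage("enrich", {
      if (!file.exists(cfg$annotations))
        stop("annotation file not found: ", cfg$annotations)
      ann <- readAnnotations(cfg$annotations)
      res <- enrichClusters(part, ann, universe = cfg$universe,
                            minCluster = cfg$min_cluster)
      out <- res
      out$p_value <- formatC(out$p_value, digits = 10, format = "g")
      out$q_value <- formatC(out$q_value, digits = 10, format = "g")
      utils::write.table(out, file.path(cfg$outdir, "enrichment.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE,
                         eol = "\n")
      noteOutput("enrichment.tsv")
      .logLine(logCon, "enrich: ", nrow(res), " cluster-term tests")
    })
  }

  # -- export --------------------------------------------------------------
  stage("export", {
    writeSIF(net, file.path(cfg$outdir, "network.sif"),
             interactionLabel = cfg$sif_label)
    noteOutput("network.sif")
    attrs <- topo$perNode
    attrs$cluster <- membership(part)[attrs$node]
    writeNodeAttributes(attrs, file.path(cfg$outdir, "node_attributes.tsv"))
    noteOutput("node_attributes.tsv")
    .logLine(logCon, "export: network.sif + node_attributes.tsv written")
  })
  noteOutput("run.log")
  invisible(cfg$outdir)
}
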