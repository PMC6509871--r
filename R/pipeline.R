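#' Read a network from a three-column edge list
#'
#' Inverse of [writeNetworkEdges()]: TSV with header gene_a, gene_b,
#' weight. The gene universe is the set of endpoint ids.
#'
#' @param path edge-list TSV.
#' @return a \linkS4class{GeneNetwork}.
#' @export
readNetworkEdges <- function(path) {
  tab <- utils::read.table(path, sep = "\t", header = TRUE,
                           colClasses = c("character", "character",
                                          "numeric"))
  g <- sort(unique(c(tab[[1]], tab[[2]])), method = "radix")
  W <- matrix(0, length(g), length(g), dimnames = list(g, g))
  i <- match(tab[[1]], g); j <- match(tab[[2]], g)
  W[cbind(i, j)] <- tab[[3]]
  W[cbind(j, i)] <- tab[[3]]
  diag(W) <- 0
  methods::new("GeneNetwork", genes = g, adjacency = W)
}

#' Pipeline configuration
#'
#' Assembles and validates the configuration for [runPipeline()]. Any
#' argument can also arrive via a JSON config file in the command-line
#' interface; see the package scripts.
#'
#' @param input expression input: a matrix, SummarizedExperiment, or a file
#'   path (with \code{format}).
#' @param outDir output directory (created if absent).
#' @param format input file format for path input ("tsv", "csv", "mtx").
#' @param geneFile,sampleFile sidecar id files for mtx input.
#' @param probeMap optional probe-to-gene mapping file; when given, probe
#'   rows are collapsed to gene symbols before preprocessing.
#' @param preprocess one of "microarray", "scrna", "none".
#' @param affinity "lrr" (default) or "pcc" for the correlation baseline;
#'   "precomputed" mines a network read from \code{adjacencyInput} and
#'   skips expression-based stages.
#' @param adjacencyInput edge-list TSV used when
#'   \code{affinity = "precomputed"}.
#' @param lambda LRR noise trade-off (required for affinity "lrr").
#' @param gamma lmQCM seed threshold.
#' @param alpha,t,beta,minSize lmQCM parameters.
#' @param gmt named list/vector of GMT file paths for enrichment (optional).
#' @param enrichMinSize,enrichMaxSize,pCut enrichment gate and cutoff.
#' @param solverOpts LRR solver options, see [lrrOptions()].
#' @param seed integer recorded in the manifest (the core pipeline itself
#'   is deterministic).
#' @return validated config list of class \code{subcoexConfig}.
#' @export
pipelineConfig <- function(input, outDir, format = "tsv", geneFile = NULL,
                           sampleFile = NULL, probeMap = NULL,
                           preprocess = c("none", "microarray", "scrna"),
                           affinity = c("lrr", "pcc", "precomputed"),
                           adjacencyInput = NULL, lambda = NULL,
                           gamma = 0.5, alpha = 1, t = 1, beta = 0.4,
                           minSize = 10L, gmt = NULL,
                           enrichMinSize = 10L, enrichMaxSize = 500L,
                           pCut = 0.01, solverOpts = lrrOptions(),
                           seed = 1L) {
  preprocess <- match.arg(preprocess)
  affinity <- match.arg(affinity)
  if (affinity == "lrr" && (is.null(lambda) || lambda <= 0))
    stop("affinity 'lrr' requires a positive lambda")
  if (affinity == "precomputed" && is.null(adjacencyInput))
    stop("affinity 'precomputed' requires adjacencyInput")
  structure(list(input = input, outDir = outDir, format = format,
                 geneFile = geneFile, sampleFile = sampleFile,
                 probeMap = probeMap, preprocess = preprocess,
                 affinity = affinity, adjacencyInput = adjacencyInput,
                 lambda = lambda, gamma = gamma, alpha = alpha, t = t,
                 beta = beta, minSize = as.integer(minSize), gmt = gmt,
                 enrichMinSize = as.integer(enrichMinSize),
                 enrichMaxSize = as.integer(enrichMaxSize), pCut = pCut,
                 solverOpts = solverOpts, seed = as.integer(seed)),
            class = "subcoexConfig")
}

#' Run the full co-expression module pipeline
#'
#' Executes preprocess, LRR fit on X = t(G), column normalization,
#' adjacency construction, lmQCM mining, per-module CCI, and (optionally)
#' gene-set enrichment, writing every artifact plus a machine-readable
#' manifest to the output directory. With \code{affinity = "pcc"} only the
#' adjacency stage changes (absolute-correlation baseline); with
#' \code{affinity = "precomputed"} the miner runs directly on a stored
#' network. If any stage fails, files created by this run are removed
#' before the error propagates.
#'
#' @param config a config from [pipelineConfig()].
#' @return (invisibly) list with \code{moduleSet}, \code{network},
#'   \code{cci} data.frame, \code{enrichment} (named list of data.frames,
#'   possibly empty), and \code{files} (paths written).
#' @export
runPipeline <- function(config) {
  stopifnot(inherits(config, "subcoexConfig"))
  cfg <- config
  dir.create(cfg$outDir, showWarnings = FALSE, recursive = TRUE)
  written <- character()
  .out <- function(name) {
    p <- file.path(cfg$outDir, name)
    written <<- c(written, p)
    p
  }
  stage <- "setup"
  result <- tryCatch({
    checksums <- NULL
    exprMat <- NULL
    if (cfg$affinity != "precomputed") {
      stage <- "read"
      if (is.character(cfg$input)) {
        checksums <- as.list(tools::md5sum(cfg$input))
        exprMat <- .exprMatrix(readExpressionMatrix(
          cfg$input, format = cfg$format, geneFile = cfg$geneFile,
          sampleFile = cfg$sampleFile))
      } else exprMat <- .exprMatrix(cfg$input)
      if (!is.null(cfg$probeMap)) {
        stage <- "collapse_probesets"
        exprMat <- collapseProbesets(exprMat, readProbeMap(cfg$probeMap))
      }
      stage <- "preprocess"
      exprMat <- switch(cfg$preprocess,
        none = exprMat,
        microarray = preprocessMicroarray(exprMat),
        scrna = preprocessSingleCell(exprMat))
    }
    stage <- "network"
    net <- switch(cfg$affinity,
      lrr = {
        fit <- solveLRR(t(exprMat), lambda = cfg$lambda,
                        opts = cfg$solverOpts)
        representationNetwork(normalizeColumnsInfNorm(lowRank(fit)),
                              genes = rownames(exprMat))
      },
      pcc = correlationNetwork(exprMat),
      precomputed = readNetworkEdges(cfg$adjacencyInput))
    writeNetworkEdges(net, .out("network_edges.tsv"))
    stage <- "mine"
    ms <- lmQCM(net, gamma = cfg$gamma, alpha = cfg$alpha, t = cfg$t,
                beta = cfg$beta, minSize = cfg$minSize)
    writeModules(ms, .out("modules.tsv"))
    stage <- "cci"
    cciDf <- NULL
    if (!is.null(exprMat) && length(ms) > 0) {
      cciDf <- data.frame(
        module_id = seq_len(length(ms)),
        module_size = moduleSizes(ms),
        density = moduleDensities(ms),
        cci = vapply(modules(ms), function(g) cci(exprMat, g), numeric(1)))
      utils::write.table(cciDf, .out("cci.tsv"), sep = "\t", quote = FALSE,
                         row.names = FALSE)
    }
    stage <- "enrichment"
    enr <- list()
    if (!is.null(cfg$gmt) && length(ms) > 0) {
      bg <- if (!is.null(exprMat)) rownames(exprMat) else geneIDs(net)
      for (nm in names(cfg$gmt)) {
        enr[[nm]] <- enrichModules(ms, readGMT(cfg$gmt[[nm]]), bg,
                                   minSize = cfg$enrichMinSize,
                                   maxSize = cfg$enrichMaxSize,
                                   pCut = cfg$pCut)
        utils::write.table(enr[[nm]],
                           .out(paste0("enrichment_", nm, ".tsv")),
                           sep = "\t", quote = FALSE, row.names = FALSE)
      }
    }
    stage <- "manifest"
    manifest <- list(
      package = "subcoex",
      version = as.character(utils::packageVersion("subcoex")),
      parameters = cfg[setdiff(names(cfg), c("input", "solverOpts"))],
      solverOpts = cfg$solverOpts,
      input = if (is.character(cfg$input)) cfg$input else "in-memory",
      input_md5 = checksums,
      n_genes = if (!is.null(exprMat)) nrow(exprMat) else length(geneIDs(net)),
      n_samples = if (!is.null(exprMat)) ncol(exprMat) else NA,
      n_modules = length(ms))
    jsonlite::write_json(manifest, .out("manifest.json"),
                         auto_unbox = TRUE, null = "null", digits = NA,
                         pretty = TRUE)
    list(moduleSet = ms, network = net, cci = cciDf, enrichment = enr,
         files = written)
  }, error = function(e) {
    unlink(written)
    stop("pipeline failed at stage '", stage, "': ", conditionMessage(e),
         call. = FALSE)
  })
  invisible(result)
}
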