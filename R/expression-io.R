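## Internal canonicalization: every user-facing function accepts either a
## plain genes-by-samples numeric matrix with dimnames or a
## SummarizedExperiment (first assay). Invariants checked here once.

.exprMatrix <- function(x, minSamples = 2L) {
  if (methods::is(x, "SummarizedExperiment"))
    x <- SummarizedExperiment::assay(x, 1)
  if (!is.matrix(x) || !is.numeric(x))
    stop("expression input must be a numeric matrix or SummarizedExperiment")
  if (is.null(rownames(x)) || is.null(colnames(x)))
    stop("expression matrix must carry gene row names and sample column names")
  dup <- rownames(x)[duplicated(rownames(x))]
  if (length(dup))
    stop("duplicate gene id(s): ", paste(unique(dup), collapse = ", "))
  dup <- colnames(x)[duplicated(colnames(x))]
  if (length(dup))
    stop("duplicate sample id(s): ", paste(unique(dup), collapse = ", "))
  if (!all(is.finite(x)))
    stop("expression values must all be finite")
  if (nrow(x) < 1L) stop("at least one gene required")
  if (ncol(x) < minSamples)
    stop("at least ", minSamples, " samples required")
  x
}

#' Read a gene expression matrix
#'
#' Reads a genes-by-samples expression matrix from delimited text or a
#' MatrixMarket coordinate triplet. Delimited files must have a header row of
#' sample ids and gene ids in the first column; MatrixMarket input needs
#' sidecar text files with one gene id (rows) and one sample id (columns) per
#' line, and absent entries become 0.
#'
#' @param path file to read.
#' @param format one of \code{"tsv"}, \code{"csv"}, \code{"mtx"}.
#' @param geneFile,sampleFile sidecar id files; required when
#'   \code{format = "mtx"}.
#' @return a [SummarizedExperiment::SummarizedExperiment] with one assay
#'   (\code{exprs}) of expression values.
#' @examples
#' tf <- tempfile(fileext = ".tsv")
#' m <- matrix(1:6, 2, 3, dimnames = list(c("g1", "g2"), c("s1", "s2", "s3")))
#' writeExpressionMatrix(m, tf)
#' se <- readExpressionMatrix(tf)
#' stopifnot(identical(dim(se), c(2L, 3L)))
#' @export
readExpressionMatrix <- function(path, format = c("tsv", "csv", "mtx"),
                                 geneFile = NULL, sampleFile = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "mtx") {
    if (is.null(geneFile) || is.null(sampleFile))
      stop("mtx input requires geneFile and sampleFile sidecars")
    m <- as.matrix(Matrix::readMM(path))
    genes <- readLines(geneFile)
    samples <- readLines(sampleFile)
    if (nrow(m) != length(genes) || ncol(m) != length(samples))
      stop("mtx dimensions (", nrow(m), "x", ncol(m),
           ") do not match sidecar id counts (", length(genes), ", ",
           length(samples), ")")
    dimnames(m) <- list(genes, samples)
    return(.likeInput(.exprMatrix(m), template = .seTemplate()))
  }
  sep <- if (format == "tsv") "\t" else ","
  tab <- tryCatch(
    utils::read.table(path, sep = sep, header = TRUE, check.names = FALSE,
                      colClasses = "character", row.names = NULL,
                      quote = "\"", comment.char = "", fill = FALSE),
    error = function(e) stop("malformed (possibly ragged) table in ", path,
                             ": ", conditionMessage(e)))
  if (ncol(tab) < 2) stop("expected gene id column plus >= 1 sample column")
  genes <- tab[[1]]
  samples <- colnames(tab)[-1]
  vals <- as.matrix(tab[, -1, drop = FALSE])
  num <- suppressWarnings(array(as.numeric(vals), dim = dim(vals)))
  bad <- is.na(num) & !(trimws(vals) %in% c("NA", "NaN"))
  if (any(bad)) {
    w <- which(bad, arr.ind = TRUE)[1, ]
    stop("non-numeric value ", dQuote(vals[w[1], w[2]]), " at gene ",
         dQuote(genes[w[1]]), ", sample ", dQuote(samples[w[2]]))
  }
  dimnames(num) <- list(genes, samples)
  .likeInput(.exprMatrix(num), template = .seTemplate())
}

.seTemplate <- function() {
  ## sentinel making .likeInput produce a SummarizedExperiment
  structure(list(), class = "se_template")
}

## .likeInput dispatch for the sentinel
.likeInput <- function(mat, template) {
  if (inherits(template, "se_template") ||
      methods::is(template, "SummarizedExperiment"))
    SummarizedExperiment::SummarizedExperiment(assays = list(exprs = mat))
  else mat
}

#' Write a gene expression matrix
#'
#' @param x matrix or SummarizedExperiment, genes in rows.
#' @param path output file.
#' @param format \code{"tsv"} or \code{"csv"}.
#' @return \code{path}, invisibly.
#' @export
writeExpressionMatrix <- function(x, path, format = c("tsv", "csv")) {
  format <- match.arg(format)
  m <- .exprMatrix(x, minSamples = 1L)
  sep <- if (format == "tsv") "\t" else ","
  df <- data.frame(gene_id = rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a probe-to-gene mapping
#'
#' Two-column tab-separated file, \code{probe_id<TAB>gene_symbol}, no header.
#' Probes may be unmapped simply by being absent from the file.
#'
#' @param path file to read.
#' @return named character vector: names are probe ids, values gene symbols.
#' @export
readProbeMap <- function(path) {
  tab <- utils::read.table(path, sep = "\t", header = FALSE,
                           colClasses = "character", quote = "",
                           comment.char = "")
  if (ncol(tab) != 2) stop("probe map must have exactly two columns")
  if (anyDuplicated(tab[[1]]))
    stop("duplicate probe id(s): ",
         paste(unique(tab[[1]][duplicated(tab[[1]])]), collapse = ", "))
  stats::setNames(tab[[2]], tab[[1]])
}

#' Collapse probe-level rows to gene symbols
#'
#' Probes without a mapped gene symbol are dropped. When several probes map
#' to the same gene, only the probe with the highest row mean is retained
#' (exact ties resolved toward the lexicographically smallest probe id, for
#' determinism). Surviving rows are re-labelled with gene symbols; the row
#' order follows the original probe order of the retained probes.
#'
#' @param x probe-by-sample matrix or SummarizedExperiment.
#' @param map named character vector (probe id -> gene symbol), e.g. from
#'   [readProbeMap()].
#' @return object of the same container class as \code{x}, keyed by gene
#'   symbol.
#' @export
collapseProbesets <- function(x, map) {
  m <- .exprMatrix(x)
  probes <- rownames(m)
  mapped <- probes[probes %in% names(map)]
  if (!length(mapped))
    stop("no probe id in the expression matrix is present in the map")
  sym <- unname(map[mapped])
  means <- rowMeans(m[mapped, , drop = FALSE])
  ## per gene: highest mean wins; ties -> lexicographically smallest probe id
  ord <- order(sym, -means, .cOrder(mapped))
  keepIdx <- ord[!duplicated(sym[ord])]
  keep <- mapped[sort(keepIdx)]          # restore original row order
  out <- m[keep, , drop = FALSE]
  rownames(out) <- unname(map[keep])
  if (methods::is(x, "SummarizedExperiment")) .likeInput(out, x) else out
}

## Locale-independent (C collation) ordering rank for character vectors.
.cOrder <- function(x) {
  r <- integer(length(x))
  r[order(x, method = "radix")] <- seq_along(x)
  r
}
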