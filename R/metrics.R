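#' Centralized concordance index (CCI) of a module
#'
#' Fraction of the module's correlation-matrix spectrum carried by the top
#' eigenvalue: CCI = lambda_max(R) / K, where R is the K-by-K Pearson
#' correlation matrix of the module's gene profiles. CCI is 1 exactly when
#' every pair of genes is perfectly correlated, and approaches 1/K as the
#' profiles fill more dimensions; low CCI therefore signals higher intrinsic
#' dimensionality of the module.
#'
#' @param x genes-by-samples matrix or SummarizedExperiment.
#' @param moduleGenes character vector of at least two gene ids, all present
#'   in \code{x} with nonzero variance.
#' @return CCI in (0, 1].
#' @export
cci <- function(x, moduleGenes) {
  m <- .exprMatrix(x)
  miss <- setdiff(moduleGenes, rownames(m))
  if (length(miss))
    stop("gene(s) absent from expression matrix: ",
         paste(miss, collapse = ", "))
  if (length(moduleGenes) < 2) stop("a module needs at least 2 genes")
  if (anyDuplicated(moduleGenes)) stop("duplicate gene in module")
  p <- m[moduleGenes, , drop = FALSE]
  v <- .rowVars(p)
  if (any(v == 0))
    stop("zero-variance gene(s): ",
         paste(moduleGenes[v == 0], collapse = ", "))
  R <- stats::cor(t(p))
  ev <- eigen((R + t(R)) / 2, symmetric = TRUE, only.values = TRUE)$values
  max(ev) / length(moduleGenes)
}

#' Two-sample Kolmogorov-Smirnov test
#'
#' D is the supremum of the absolute difference between the two empirical
#' CDFs; the p-value uses the asymptotic two-sided Kolmogorov distribution,
#' appropriate for the module-level CCI comparisons (dozens of values per
#' group).
#'
#' @param a,b numeric samples, each non-empty.
#' @return list with \code{statistic} (D) and \code{p.value}.
#' @export
ksTwoSample <- function(a, b) {
  if (!length(a) || !length(b)) stop("both samples must be non-empty")
  stopifnot(is.numeric(a), is.numeric(b), all(is.finite(a)), all(is.finite(b)))
  kt <- suppressWarnings(stats::ks.test(a, b, exact = FALSE))
  list(statistic = unname(kt$statistic), p.value = unname(kt$p.value))
}

#' Read a protein-protein interaction edge list
#'
#' Two-column tab-separated file of interactor identifiers, no header.
#' An optional two-column mapping file (accession<TAB>gene symbol) is
#' applied first; edges with an unmapped endpoint are dropped. Self-pairs
#' are legitimate (a protein may interact with itself) and duplicate
#' unordered pairs are collapsed.
#'
#' @param path edge-list file.
#' @param mappingPath optional accession-to-symbol mapping file.
#' @return two-column character matrix of unique unordered pairs, each row
#'   sorted.
#' @export
readPPI <- function(path, mappingPath = NULL) {
  tab <- utils::read.table(path, sep = "\t", header = FALSE,
                           colClasses = "character", quote = "",
                           comment.char = "")
  if (ncol(tab) < 2) stop("PPI file must have two columns")
  a <- tab[[1]]; b <- tab[[2]]
  if (!is.null(mappingPath)) {
    mp <- utils::read.table(mappingPath, sep = "\t", header = FALSE,
                            colClasses = "character", quote = "",
                            comment.char = "")
    map <- stats::setNames(mp[[2]], mp[[1]])
    a <- unname(map[a]); b <- unname(map[b])
    ok <- !is.na(a) & !is.na(b)
    a <- a[ok]; b <- b[ok]
  }
  if (any(!nzchar(a)) || any(!nzchar(b))) stop("empty interactor symbol")
  lo <- pmin(a, b); hi <- pmax(a, b)
  keep <- !duplicated(paste(lo, hi, sep = "\r"))
  cbind(lo[keep], hi[keep])
}

#' PPI density of a module
#'
#' With n module genes and n_PPI interactions internal to the module
#' (self-interactions included), density is 2 * n_PPI / (n * (n + 1)) —
#' the denominator counts unordered pairs plus self-pairs, so density 1
#' means every pair and every self-interaction is present.
#'
#' @param moduleGenes character vector of gene symbols (n >= 1).
#' @param ppi two-column character matrix of interactions, e.g. from
#'   [readPPI()]. Genes absent from the PPI simply contribute no edges.
#' @return density in [0, 1].
#' @export
ppiDensity <- function(moduleGenes, ppi) {
  stopifnot(length(moduleGenes) >= 1, is.matrix(ppi), ncol(ppi) == 2)
  if (anyDuplicated(moduleGenes)) stop("duplicate gene in module")
  n <- length(moduleGenes)
  inside <- ppi[, 1] %in% moduleGenes & ppi[, 2] %in% moduleGenes
  2 * sum(inside) / (n * (n + 1))
}
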