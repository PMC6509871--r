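## Low-tail filter. "Bottom frac" = the floor(frac * n) genes with the
## smallest statistic; genes whose statistic equals the smallest retained
## value are kept (ties at the threshold survive), which keeps the rule
## deterministic under ties.
.keepAboveLowTail <- function(stat, frac) {
  n <- length(stat)
  k <- floor(frac * n)
  if (k <= 0) return(rep(TRUE, n))
  if (k >= n) return(rep(FALSE, n))
  thr <- sort(stat)[k + 1]
  stat >= thr
}

.rowVars <- function(m) {
  mu <- rowMeans(m)
  rowSums((m - mu)^2) / (ncol(m) - 1L)
}

#' Microarray preprocessing recipe
#'
#' Three sequential gene filters applied to a (probe-collapsed) expression
#' matrix: (1) drop genes in the bottom \code{meanFrac} by row mean;
#' (2) among survivors, drop genes in the bottom \code{varFrac} by row
#' variance (quantiles recomputed on the survivors); (3) keep at most
#' \code{topN} of the remaining genes, by highest row mean. Original gene
#' order is preserved among survivors.
#'
#' @param x genes-by-samples matrix or SummarizedExperiment.
#' @param meanFrac fraction of lowest-mean genes to remove (default 0.20).
#' @param varFrac fraction of lowest-variance genes to remove (default 0.10).
#' @param topN maximum number of genes retained (default 10000).
#' @return filtered object of the same container class as \code{x}.
#' @export
preprocessMicroarray <- function(x, meanFrac = 0.20, varFrac = 0.10,
                                 topN = 10000L) {
  m <- .exprMatrix(x)
  stopifnot(meanFrac >= 0, meanFrac < 1, varFrac >= 0, varFrac < 1, topN >= 1)
  keep <- which(.keepAboveLowTail(rowMeans(m), meanFrac))
  keep <- keep[.keepAboveLowTail(.rowVars(m[keep, , drop = FALSE]), varFrac)]
  if (length(keep) > topN) {
    mu <- rowMeans(m[keep, , drop = FALSE])
    keep <- sort(keep[order(-mu, keep)[seq_len(topN)]])
  }
  if (length(keep) < 2)
    stop("fewer than 2 genes survive microarray preprocessing")
  if (methods::is(x, "SummarizedExperiment")) x[keep, ] else m[keep, , drop = FALSE]
}

#' Single-cell RNA-seq preprocessing recipe
#'
#' Expression is quantified as log2(TPM/10 + 1). Genes with zero expression
#' in every cell are removed first; then a gene is kept only if it lies in
#' both the top \code{1 - lowFrac} by mean and the top \code{1 - lowFrac} by
#' variance of the transformed values (i.e. genes in the lowest
#' \code{lowFrac} by either statistic are filtered out). The transform
#' dampens the influence of dropout-driven zeros and heavy right tails.
#'
#' @param x genes-by-cells matrix of non-negative TPM values (or a
#'   SummarizedExperiment holding one).
#' @param lowFrac fraction defining the low tail for both filters
#'   (default 0.80).
#' @return filtered, log-transformed object of the same container class as
#'   \code{x}.
#' @export
preprocessSingleCell <- function(x, lowFrac = 0.80) {
  m <- .exprMatrix(x)
  stopifnot(lowFrac >= 0, lowFrac < 1)
  if (any(m < 0)) {
    w <- which(m < 0, arr.ind = TRUE)[1, ]
    stop("negative TPM value at gene ", dQuote(rownames(m)[w[1]]),
         ", cell ", dQuote(colnames(m)[w[2]]))
  }
  m <- m[rowSums(m) > 0, , drop = FALSE]
  if (nrow(m) == 0) stop("all genes have zero expression in every cell")
  lg <- log2(m / 10 + 1)
  keep <- .keepAboveLowTail(rowMeans(lg), lowFrac) &
          .keepAboveLowTail(.rowVars(lg), lowFrac)
  if (!any(keep)) stop("no gene passes both mean and variance filters")
  out <- lg[keep, , drop = FALSE]
  if (methods::is(x, "SummarizedExperiment")) .likeInput(out, x) else out
}
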