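#' Normalize representation columns to unit infinity norm
#'
#' Divides each nonzero column of a representation matrix by its max-abs
#' entry, so that the largest affinity carried by every gene is on the same
#' scale regardless of the gene's expression magnitude. All-zero columns
#' (genes with no representation) are left unchanged.
#'
#' @param Z square representation matrix.
#' @return matrix of the same shape, every nonzero column with max-abs 1.
#' @export
normalizeColumnsInfNorm <- function(Z) {
  stopifnot(is.matrix(Z), all(is.finite(Z)))
  mx <- apply(abs(Z), 2, max)
  scl <- ifelse(mx > 0, 1 / mx, 1)
  Z * rep(scl, each = nrow(Z))
}

#' Gene network from a low-rank representation
#'
#' Builds the weighted, undirected co-expression network with edge weight
#' W_ij = |Z_ij| + |Z_ji| between distinct genes i and j; the diagonal is
#' set to zero. Apply [normalizeColumnsInfNorm()] first so weights are
#' comparable across genes (entries then lie in [0, 2]).
#'
#' @param Z square (typically column-normalized) representation matrix.
#' @param genes character vector of gene ids, one per row/column of
#'   \code{Z}.
#' @return a \linkS4class{GeneNetwork}.
#' @export
representationNetwork <- function(Z, genes = rownames(Z)) {
  stopifnot(is.matrix(Z), nrow(Z) == ncol(Z), all(is.finite(Z)))
  if (is.null(genes)) stop("gene ids required (argument 'genes' or rownames)")
  if (length(genes) != nrow(Z))
    stop("length of gene ids (", length(genes),
         ") does not match representation dimension (", nrow(Z), ")")
  W <- abs(Z) + t(abs(Z))
  diag(W) <- 0
  dimnames(W) <- list(genes, genes)
  methods::new("GeneNetwork", genes = as.character(genes), adjacency = W)
}

#' Gene network from absolute Pearson correlation
#'
#' Baseline adjacency for comparison with the representation-based network:
#' W_ij = |PCC(g_i, g_j)| between gene expression profiles, zero diagonal.
#'
#' @param x genes-by-samples matrix or SummarizedExperiment; every gene must
#'   have nonzero variance.
#' @return a \linkS4class{GeneNetwork}.
#' @export
correlationNetwork <- function(x) {
  m <- .exprMatrix(x)
  v <- .rowVars(m)
  if (any(v == 0))
    stop("zero-variance gene(s): ",
         paste(rownames(m)[v == 0], collapse = ", "))
  W <- abs(stats::cor(t(m)))
  diag(W) <- 0
  W <- (W + t(W)) / 2   # guard symmetry against rounding
  methods::new("GeneNetwork", genes = rownames(m), adjacency = W)
}

#' Export network edges as TSV
#'
#' Writes the upper triangle of the adjacency as three columns
#' (gene_a, gene_b, weight), keeping edges with weight >= \code{minWeight}.
#'
#' @param net a \linkS4class{GeneNetwork}.
#' @param path output file.
#' @param minWeight smallest weight to export (default 0, i.e. all positive
#'   edges plus zero-weight pairs are dropped only when \code{minWeight > 0}
#'   is requested; with the default only strictly positive edges are
#'   written).
#' @return \code{path}, invisibly.
#' @export
writeNetworkEdges <- function(net, path, minWeight = 0) {
  stopifnot(methods::is(net, "GeneNetwork"))
  W <- adjacency(net)
  g <- geneIDs(net)
  ut <- which(upper.tri(W), arr.ind = TRUE)
  w <- W[ut]
  keep <- if (minWeight > 0) w >= minWeight else w > 0
  df <- data.frame(gene_a = g[ut[keep, 1]], gene_b = g[ut[keep, 2]],
                   weight = w[keep], stringsAsFactors = FALSE)
  df <- df[order(-df$weight, .cOrder(df$gene_a), .cOrder(df$gene_b)), ]
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
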