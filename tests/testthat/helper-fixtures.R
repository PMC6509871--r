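# Shared fixture builders; everything generated in code, nothing on disk.

# Symmetric weighted network from an edge list. genes defaults to the union
# of endpoints in sorted (C collation) order.
edgeNetwork <- function(edges, genes = NULL) {
  ep <- unique(c(edges$from, edges$to))
  if (is.null(genes)) genes <- sort(ep, method = "radix")
  W <- matrix(0, length(genes), length(genes),
              dimnames = list(genes, genes))
  for (r in seq_len(nrow(edges))) {
    i <- match(edges$from[r], genes); j <- match(edges$to[r], genes)
    W[i, j] <- W[j, i] <- edges$weight[r]
  }
  methods::new("GeneNetwork", genes = genes, adjacency = W)
}

# Complete graph on n genes with constant weight.
cliqueNetwork <- function(n, weight = 1, prefix = "g") {
  genes <- paste0(prefix, seq_len(n))
  W <- matrix(weight, n, n, dimnames = list(genes, genes))
  diag(W) <- 0
  methods::new("GeneNetwork", genes = genes, adjacency = W)
}

# Random symmetric weight matrix network (dense, positive weights).
randomNetwork <- function(n, seed) {
  set.seed(seed)
  genes <- sprintf("n%02d", seq_len(n))
  W <- matrix(0, n, n, dimnames = list(genes, genes))
  ut <- upper.tri(W)
  W[ut] <- round(runif(sum(ut)), 3)
  W <- W + t(W)
  methods::new("GeneNetwork", genes = genes, adjacency = W)
}

# Small expression matrix with named genes/samples.
exprFixture <- function(K, N, seed = 1, prefix = "g") {
  set.seed(seed)
  matrix(rnorm(K * N), K, N,
         dimnames = list(sprintf("%s%03d", prefix, seq_len(K)),
                         sprintf("s%03d", seq_len(N))))
}

# Independent oracle for module density: explicit pair enumeration.
bruteDensity <- function(net, genes) {
  W <- adjacency(net)
  ix <- match(genes, geneIDs(net))
  tot <- 0
  for (a in seq_along(ix)) for (b in seq_along(ix))
    if (a < b) tot <- tot + W[ix[a], ix[b]]
  2 * tot / (length(ix) * (length(ix) - 1))
}
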