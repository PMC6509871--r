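## Evaluate expr under a temporary RNG state seeded with `seed`, restoring
## the caller's stream afterwards. Keeps simulation and fold assignment
## reproducible without touching global reproducibility of user scripts.
.withSeed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) {
    old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(as.integer(seed))
  expr
}

#' Simulate expression data with planted subspace modules
#'
#' Generates a genes-by-samples matrix in which each planted co-expression
#' module lives in a known low-dimensional subspace: the module's
#' \code{subspaceDims[m]} base profiles are drawn i.i.d. standard normal
#' over samples and every member gene is a random linear combination with
#' all coefficients bounded away from zero (magnitude uniform in
#' [0.5, 1.5] times \code{coeffScale}, random sign). With
#' \code{affineShift = TRUE} each gene additionally receives a nonzero
#' constant offset, so a one-dimensional module spans rank 2 raw but rank 1
#' after row centering — the scale-plus-shift co-expression model.
#' Background genes are independent standard normal profiles; i.i.d.
#' Gaussian noise of sd \code{noiseSD} is added everywhere; a fraction of
#' genes can be replaced wholesale by heavy noise to emulate corrupted
#' (outlier) genes, matching the column-sparse error term of the LRR model.
#'
#' @param moduleSizes integer vector of planted module sizes (each >= 2).
#' @param subspaceDims integer vector, same length: subspace dimension of
#'   each module (each >= 1, less than \code{nSamples}).
#' @param nSamples number of samples (default 100).
#' @param backgroundGenes number of unstructured genes (default 60).
#' @param coeffScale scale of the mixing coefficients (default 1).
#' @param noiseSD standard deviation of the additive noise (default 0.05,
#'   i.e. 5\% of the unit signal scale).
#' @param outlierFraction fraction of all genes replaced by heavy noise
#'   (default 0).
#' @param outlierSD standard deviation of outlier profiles (default 5).
#' @param affineShift add a per-gene constant offset (default FALSE).
#' @param seed integer seed; the generator is fully deterministic given it.
#' @return list with \code{expr} (genes-by-samples matrix, gene ids
#'   \code{g0001...}) and \code{truth}: \code{memberships} (list of gene-id
#'   vectors), \code{bases} (list of dim-by-nSamples matrices),
#'   \code{outliers} (gene ids), \code{config}.
#' @export
simulateSubspaceExpression <- function(moduleSizes = c(40L, 30L, 20L),
                                       subspaceDims = c(1L, 2L, 3L),
                                       nSamples = 100L,
                                       backgroundGenes = 60L,
                                       coeffScale = 1,
                                       noiseSD = 0.05,
                                       outlierFraction = 0,
                                       outlierSD = 5,
                                       affineShift = FALSE,
                                       seed = 1L) {
  stopifnot(length(moduleSizes) == length(subspaceDims),
            all(moduleSizes >= 2), all(subspaceDims >= 1),
            all(subspaceDims < nSamples), nSamples >= 2,
            backgroundGenes >= 0, coeffScale > 0, noiseSD >= 0,
            outlierFraction >= 0, outlierFraction <= 1, outlierSD > 0)
  K <- sum(moduleSizes) + backgroundGenes
  .withSeed(seed, {
    ids <- sprintf("g%04d", seq_len(K))
    expr <- matrix(0, K, nSamples,
                   dimnames = list(ids, sprintf("s%03d", seq_len(nSamples))))
    bases <- vector("list", length(moduleSizes))
    memberships <- vector("list", length(moduleSizes))
    row <- 0L
    for (m in seq_along(moduleSizes)) {
      d <- subspaceDims[m]; sz <- moduleSizes[m]
      B <- matrix(rnorm(d * nSamples), d, nSamples)
      bases[[m]] <- B
      coefs <- matrix(sample(c(-1, 1), sz * d, replace = TRUE) *
                        runif(sz * d, 0.5, 1.5) * coeffScale, sz, d)
      block <- coefs %*% B
      if (affineShift)
        block <- block + sample(c(-1, 1), sz, replace = TRUE) *
          runif(sz, 0.5, 1.5) * coeffScale
      expr[row + seq_len(sz), ] <- block
      memberships[[m]] <- ids[row + seq_len(sz)]
      row <- row + sz
    }
    if (backgroundGenes > 0)
      expr[row + seq_len(backgroundGenes), ] <-
        matrix(rnorm(backgroundGenes * nSamples), backgroundGenes, nSamples)
    if (noiseSD > 0)
      expr <- expr + matrix(rnorm(K * nSamples, sd = noiseSD), K, nSamples)
    outliers <- character()
    nOut <- round(outlierFraction * K)
    if (nOut > 0) {
      oi <- sort(sample.int(K, nOut))
      expr[oi, ] <- matrix(rnorm(nOut * nSamples, sd = outlierSD),
                           nOut, nSamples)
      outliers <- ids[oi]
    }
    list(expr = expr,
         truth = list(memberships = memberships, bases = bases,
                      outliers = outliers,
                      config = list(moduleSizes = moduleSizes,
                                    subspaceDims = subspaceDims,
                                    nSamples = nSamples,
                                    backgroundGenes = backgroundGenes,
                                    coeffScale = coeffScale,
                                    noiseSD = noiseSD,
                                    outlierFraction = outlierFraction,
                                    outlierSD = outlierSD,
                                    affineShift = affineShift,
                                    seed = seed)))
  })
}

#' Score recovered modules against planted truth
#'
#' For each planted module, the best Jaccard index |found int truth| /
#' |found union truth| over all recovered modules.
#'
#' @param found a \linkS4class{GeneModuleSet} or list of gene-id vectors.
#' @param truth the \code{truth} element of
#'   [simulateSubspaceExpression()] output, or a plain list of gene-id
#'   vectors.
#' @return list with \code{scores} (one per planted module) and
#'   \code{mean}.
#' @export
matchModules <- function(found, truth) {
  f <- if (methods::is(found, "GeneModuleSet")) modules(found) else found
  tm <- if (is.list(truth) && !is.null(truth$memberships))
    truth$memberships else truth
  scores <- vapply(tm, function(tg) {
    if (!length(f)) return(0)
    max(vapply(f, function(fg)
      length(intersect(fg, tg)) / length(union(fg, tg)), numeric(1)))
  }, numeric(1))
  list(scores = scores, mean = mean(scores))
}
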