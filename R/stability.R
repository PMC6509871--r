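## One pass of the core pipeline on an expression matrix: LRR fit on
## X = t(G), column normalization, adjacency, lmQCM.
.mineModules <- function(m, lambda, gamma, alpha = 1, t = 1, beta = 0.4,
                         minSize = 10L, opts = lrrOptions()) {
  fit <- solveLRR(t(m), lambda = lambda, opts = opts)
  Zn <- normalizeColumnsInfNorm(lowRank(fit))
  net <- representationNetwork(Zn, genes = rownames(m))
  lmQCM(net, gamma = gamma, alpha = alpha, t = t, beta = beta,
        minSize = minSize)
}

#' Ten-fold stability of a (lambda, gamma) pair
#'
#' Samples are shuffled (seeded) and split round-robin into
#' \code{nFolds} near-equal folds. For each fold, the full pipeline (LRR
#' fit, column normalization, adjacency, lmQCM) is re-run on the remaining
#' folds' samples, giving \code{nFolds} module sets. Writing gAll for the
#' number of genes found in every run's module union and gAny for the
#' number found in at least one run, the stability ratio is gAll / gAny
#' (defined as 0 when no run yields any module). A high ratio means the
#' parameter pair recovers the same genes regardless of which samples are
#' held out.
#'
#' @param x genes-by-samples matrix or SummarizedExperiment with at least
#'   \code{nFolds} samples.
#' @param lambda LRR noise trade-off.
#' @param gamma lmQCM seed threshold.
#' @param alpha,t,beta,minSize lmQCM parameters (see [lmQCM()]).
#' @param nFolds number of folds (default 10).
#' @param seed integer seed for the fold assignment.
#' @param opts LRR solver options.
#' @param fullRun optional precomputed \linkS4class{GeneModuleSet} for the
#'   full data at these parameters; computed when NULL.
#' @return a \linkS4class{StabilityResult}.
#' @export
stabilityRatio <- function(x, lambda, gamma, alpha = 1, t = 1, beta = 0.4,
                           minSize = 10L, nFolds = 10L, seed = 1L,
                           opts = lrrOptions(), fullRun = NULL) {
  m <- .exprMatrix(x)
  N <- ncol(m)
  if (N < nFolds) stop("need at least ", nFolds, " samples, got ", N)
  folds <- .withSeed(seed, {
    shuffled <- sample.int(N)
    split(shuffled, rep(seq_len(nFolds), length.out = N))
  })
  unions <- vector("list", nFolds)
  counts <- integer(nFolds)
  for (f in seq_len(nFolds)) {
    keep <- sort(unlist(folds[-f], use.names = FALSE))
    ms <- .mineModules(m[, keep, drop = FALSE], lambda, gamma,
                       alpha = alpha, t = t, beta = beta,
                       minSize = minSize, opts = opts)
    unions[[f]] <- geneIDs(ms)
    counts[f] <- length(ms)
  }
  gAny <- length(unique(unlist(unions, use.names = FALSE)))
  gAll <- if (gAny == 0) 0L else length(Reduce(intersect, unions))
  if (is.null(fullRun))
    fullRun <- .mineModules(m, lambda, gamma, alpha = alpha, t = t,
                            beta = beta, minSize = minSize, opts = opts)
  methods::new("StabilityResult", lambda = lambda, gamma = gamma,
               gAll = as.integer(gAll), gAny = as.integer(gAny),
               ratio = if (gAny > 0) gAll / gAny else 0,
               modulesFull = length(fullRun),
               perFoldModuleCounts = counts)
}

setMethod("show", "StabilityResult", function(object) {
  cat(sprintf(
    "StabilityResult: lambda = %g, gamma = %g\n  g_all = %d, g_any = %d, ratio = %.4f\n  modules (full data) = %d; per fold: %s\n",
    object@lambda, object@gamma, object@gAll, object@gAny, object@ratio,
    object@modulesFull,
    paste(object@perFoldModuleCounts, collapse = ", ")))
})

#' Joint (lambda, gamma) selection by stability
#'
#' Evaluates [stabilityRatio()] on the Cartesian grid of candidate values.
#' Pairs whose full-data run yields fewer than \code{nMdlThr} modules are
#' inadmissible; among admissible pairs the one with the highest stability
#' ratio wins (ties resolved toward more full-data modules, then smaller
#' lambda, then smaller gamma).
#'
#' @param x genes-by-samples matrix or SummarizedExperiment.
#' @param lambdaGrid,gammaGrid non-empty numeric candidate vectors.
#' @param alpha,t,beta,minSize lmQCM parameters.
#' @param nMdlThr minimum full-data module count for admissibility
#'   (default 10).
#' @param nFolds,seed,opts passed to [stabilityRatio()].
#' @return list with \code{lambda}, \code{gamma}, and \code{table} (one
#'   data.frame row per grid pair: lambda, gamma, g_all, g_any, ratio,
#'   modules_full, admissible).
#' @export
gridSelect <- function(x, lambdaGrid, gammaGrid, alpha = 1, t = 1,
                       beta = 0.4, minSize = 10L, nMdlThr = 10L,
                       nFolds = 10L, seed = 1L, opts = lrrOptions()) {
  stopifnot(length(lambdaGrid) >= 1, length(gammaGrid) >= 1)
  m <- .exprMatrix(x)
  grid <- expand.grid(lambda = lambdaGrid, gamma = gammaGrid,
                      KEEP.OUT.ATTRS = FALSE)
  res <- vector("list", nrow(grid))
  for (i in seq_len(nrow(grid))) {
    ## the LRR fit depends on lambda only; reuse across gamma would need
    ## caching per fold — kept simple and single-process here
    res[[i]] <- stabilityRatio(m, grid$lambda[i], grid$gamma[i],
                               alpha = alpha, t = t, beta = beta,
                               minSize = minSize, nFolds = nFolds,
                               seed = seed, opts = opts)
  }
  tab <- do.call(rbind, lapply(res, function(r)
    data.frame(lambda = r@lambda, gamma = r@gamma, g_all = r@gAll,
               g_any = r@gAny, ratio = r@ratio,
               modules_full = r@modulesFull,
               admissible = r@modulesFull >= nMdlThr)))
  if (!any(tab$admissible))
    stop("no (lambda, gamma) pair yields >= ", nMdlThr,
         " modules on the full data; module counts were: ",
         paste(sprintf("(%g, %g): %d", tab$lambda, tab$gamma,
                       tab$modules_full), collapse = "; "))
  adm <- which(tab$admissible)
  best <- adm[order(-tab$ratio[adm], -tab$modules_full[adm],
                    tab$lambda[adm], tab$gamma[adm])[1]]
  list(lambda = tab$lambda[best], gamma = tab$gamma[best], table = tab)
}
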