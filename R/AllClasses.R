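#' @import methods
#' @importFrom stats cor var sd rnorm runif quantile p.adjust phyper ks.test
#' @importFrom utils read.table write.table head
NULL

#' Low-rank representation fit
#'
#' Container for the solution of the noisy low-rank representation (LRR)
#' problem min ||Z||* + lambda ||E||_{2,1} subject to X = XZ + E, where the
#' columns of X are gene expression profiles (X = t(G) for a genes-by-samples
#' matrix G). \code{Z} is the K-by-K lowest-rank representation whose entries
#' encode subspace affinity between genes; \code{E} captures column-sparse
#' (gene-wise) corruption.
#'
#' @slot Z K-by-K representation matrix.
#' @slot E N-by-K error matrix, same shape as X.
#' @slot lambda positive noise trade-off used in the fit.
#' @slot converged logical; TRUE if both primal residuals fell below the
#'   solver tolerance before the iteration cap.
#' @slot iterations number of inexact-ALM sweeps performed.
#' @slot residuals named numeric of length 2: max-abs of X - XZ - E
#'   (\code{constraint}) and of Z - J (\code{auxiliary}) at exit.
#'
#' @seealso [solveLRR()], [closedFormLRR()]
#' @export
setClass("LRRFit",
  representation(
    Z = "matrix",
    E = "matrix",
    lambda = "numeric",
    converged = "logical",
    iterations = "integer",
    residuals = "numeric"
  )
)

setValidity("LRRFit", function(object) {
  msg <- character()
  if (nrow(object@Z) != ncol(object@Z))
    msg <- c(msg, "Z must be square")
  if (ncol(object@E) != ncol(object@Z))
    msg <- c(msg, "E must have one column per gene (column of Z)")
  if (length(object@residuals) != 2 || !all(is.finite(object@residuals)))
    msg <- c(msg, "residuals must be two finite numbers")
  if (length(object@lambda) != 1 || object@lambda <= 0)
    msg <- c(msg, "lambda must be a single positive number")
  if (length(msg)) msg else TRUE
})

#' Weighted gene co-expression network
#'
#' A symmetric, non-negative weighted adjacency over a fixed gene universe.
#' Self-edges carry no information for module mining, so the diagonal is
#' always zero.
#'
#' @slot genes character vector of unique gene identifiers.
#' @slot adjacency K-by-K symmetric non-negative matrix with zero diagonal.
#'
#' @seealso [representationNetwork()], [correlationNetwork()], [lmQCM()]
#' @export
setClass("GeneNetwork",
  representation(genes = "character", adjacency = "matrix")
)

setValidity("GeneNetwork", function(object) {
  W <- object@adjacency
  g <- object@genes
  msg <- character()
  if (anyDuplicated(g)) msg <- c(msg, "duplicate gene ids")
  if (nrow(W) != length(g) || ncol(W) != length(g))
    msg <- c(msg, "adjacency dimensions must match number of genes")
  if (!all(is.finite(W))) msg <- c(msg, "adjacency must be finite")
  else {
    if (any(W < 0)) msg <- c(msg, "adjacency must be non-negative")
    if (nrow(W) > 0 && any(abs(diag(W)) > 0))
      msg <- c(msg, "adjacency diagonal must be zero")
    if (!isSymmetric(unname(W), tol = 1e-8))
      msg <- c(msg, "adjacency must be symmetric")
  }
  if (length(msg)) msg else TRUE
})

#' Set of mined gene co-expression modules
#'
#' Possibly overlapping gene modules, each an ordered gene list (order of
#' accretion during greedy growth, seed pair first) with its weighted density
#' 2 * sum(internal weights) / (n (n - 1)). Modules are stored in decreasing
#' size order.
#'
#' @slot modules list of character vectors (gene ids, each unique within a
#'   module).
#' @slot densities numeric vector of module densities, parallel to
#'   \code{modules}.
#'
#' @seealso [lmQCM()], [mergeModules()]
#' @export
setClass("GeneModuleSet",
  representation(modules = "list", densities = "numeric")
)

setValidity("GeneModuleSet", function(object) {
  mods <- object@modules
  msg <- character()
  if (length(mods) != length(object@densities))
    msg <- c(msg, "one density per module required")
  if (!all(vapply(mods, is.character, logical(1))))
    msg <- c(msg, "modules must be character vectors")
  else {
    if (any(vapply(mods, anyDuplicated, integer(1)) > 0))
      msg <- c(msg, "duplicate gene within a module")
    sizes <- lengths(mods)
    if (any(sizes < 2)) msg <- c(msg, "modules must have at least 2 genes")
    if (is.unsorted(rev(sizes))) msg <- c(msg, "modules must be sorted by size, descending")
    keys <- vapply(mods, function(m) paste(sort(m), collapse = "\r"), character(1))
    if (anyDuplicated(keys)) msg <- c(msg, "duplicate module gene sets")
  }
  if (length(msg)) msg else TRUE
})

#' Stability of a (lambda, gamma) parameter pair
#'
#' Result of the 10-fold stability assessment: samples are partitioned into
#' folds, the full network-plus-mining pipeline is re-run leaving one fold
#' out at a time, and gene recovery across runs is summarized as the ratio
#' gAll / gAny, where gAll counts genes appearing in every run's module union
#' and gAny counts genes appearing in at least one.
#'
#' @slot lambda LRR noise trade-off evaluated.
#' @slot gamma lmQCM seed-edge threshold evaluated.
#' @slot gAll genes present in all fold runs' module unions.
#' @slot gAny genes present in at least one fold run's module union.
#' @slot ratio gAll / gAny (0 when gAny is 0).
#' @slot modulesFull number of modules mined from the full data.
#' @slot perFoldModuleCounts modules mined in each leave-one-fold-out run.
#'
#' @seealso [stabilityRatio()], [gridSelect()]
#' @export
setClass("StabilityResult",
  representation(
    lambda = "numeric",
    gamma = "numeric",
    gAll = "integer",
    gAny = "integer",
    ratio = "numeric",
    modulesFull = "integer",
    perFoldModuleCounts = "integer"
  )
)

setValidity("StabilityResult", function(object) {
  msg <- character()
  if (object@gAll > object@gAny) msg <- c(msg, "gAll cannot exceed gAny")
  if (object@gAny > 0 && (object@ratio < 0 || object@ratio > 1))
    msg <- c(msg, "ratio must lie in [0, 1]")
  if (length(msg)) msg else TRUE
})
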