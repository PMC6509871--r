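#' @rdname GeneNetwork-class
#' @param x a \linkS4class{GeneNetwork} or \linkS4class{GeneModuleSet}.
#' @export
setGeneric("geneIDs", function(x) standardGeneric("geneIDs"))

#' @rdname GeneNetwork-class
#' @export
setGeneric("adjacency", function(x) standardGeneric("adjacency"))

#' @rdname GeneModuleSet-class
#' @param x a \linkS4class{GeneModuleSet}.
#' @export
setGeneric("modules", function(x) standardGeneric("modules"))

#' @rdname GeneModuleSet-class
#' @export
setGeneric("moduleSizes", function(x) standardGeneric("moduleSizes"))

#' @rdname GeneModuleSet-class
#' @export
setGeneric("moduleDensities", function(x) standardGeneric("moduleDensities"))

#' @rdname LRRFit-class
#' @param x an \linkS4class{LRRFit}.
#' @export
setGeneric("lowRank", function(x) standardGeneric("lowRank"))

#' @rdname LRRFit-class
#' @export
setGeneric("errorMatrix", function(x) standardGeneric("errorMatrix"))

#' @rdname LRRFit-class
#' @export
setGeneric("isConverged", function(x) standardGeneric("isConverged"))

## ---- LRRFit accessors -------------------------------------------------

#' @rdname LRRFit-class
#' @aliases lowRank,LRRFit-method
setMethod("lowRank", "LRRFit", function(x) x@Z)

#' @rdname LRRFit-class
#' @aliases errorMatrix,LRRFit-method
setMethod("errorMatrix", "LRRFit", function(x) x@E)

#' @rdname LRRFit-class
#' @aliases isConverged,LRRFit-method
setMethod("isConverged", "LRRFit", function(x) x@converged)

setMethod("show", "LRRFit", function(object) {
  cat("LRRFit:", ncol(object@Z), "genes,", nrow(object@E), "samples\n")
  cat("  lambda =", object@lambda,
      "| iterations =", object@iterations,
      "| converged =", object@converged, "\n")
  cat(sprintf("  residuals: constraint %.3e, auxiliary %.3e\n",
              object@residuals[1], object@residuals[2]))
})

## ---- GeneNetwork accessors --------------------------------------------

#' @rdname GeneNetwork-class
#' @aliases geneIDs,GeneNetwork-method
setMethod("geneIDs", "GeneNetwork", function(x) x@genes)

#' @rdname GeneNetwork-class
#' @aliases adjacency,GeneNetwork-method
setMethod("adjacency", "GeneNetwork", function(x) x@adjacency)

setMethod("show", "GeneNetwork", function(object) {
  K <- length(object@genes)
  ne <- sum(object@adjacency[upper.tri(object@adjacency)] > 0)
  cat("GeneNetwork:", K, "genes,", ne, "positive-weight edges\n")
  if (ne > 0)
    cat(sprintf("  weight range (positive edges): [%.4g, %.4g]\n",
                min(object@adjacency[object@adjacency > 0]),
                max(object@adjacency)))
})

## ---- GeneModuleSet accessors ------------------------------------------

#' @rdname GeneModuleSet-class
#' @aliases modules,GeneModuleSet-method
setMethod("modules", "GeneModuleSet", function(x) x@modules)

#' @rdname GeneModuleSet-class
#' @aliases moduleSizes,GeneModuleSet-method
setMethod("moduleSizes", "GeneModuleSet", function(x) lengths(x@modules))

#' @rdname GeneModuleSet-class
#' @aliases moduleDensities,GeneModuleSet-method
setMethod("moduleDensities", "GeneModuleSet", function(x) x@densities)

#' @rdname GeneModuleSet-class
#' @aliases geneIDs,GeneModuleSet-method
setMethod("geneIDs", "GeneModuleSet",
          function(x) unique(unlist(x@modules, use.names = FALSE)))

#' @rdname GeneModuleSet-class
#' @aliases length,GeneModuleSet-method
setMethod("length", "GeneModuleSet", function(x) length(x@modules))

#' @rdname GeneModuleSet-class
#' @param i module index.
#' @aliases [[,GeneModuleSet-method
setMethod("[[", "GeneModuleSet", function(x, i) x@modules[[i]])

setMethod("show", "GeneModuleSet", function(object) {
  n <- length(object@modules)
  cat("GeneModuleSet:", n, "modules\n")
  if (n > 0) {
    sizes <- lengths(object@modules)
    cat("  sizes:", paste(head(sizes, 10), collapse = ", "),
        if (n > 10) "...\n" else "\n")
    cat(sprintf("  densities: median %.3f, range [%.3f, %.3f]\n",
                median(object@densities), min(object@densities),
                max(object@densities)))
  }
})

#' @importFrom stats median
NULL
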