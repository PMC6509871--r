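#' Read gene sets in GMT format
#'
#' One gene set per line: \code{term<TAB>description<TAB>gene1<TAB>gene2...}.
#' Duplicate genes within a set are collapsed.
#'
#' @param path GMT file.
#' @return named list of character vectors (gene sets), with a
#'   \code{"description"} attribute carrying the per-set description.
#' @export
readGMT <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(parts) < 3)
  if (length(bad))
    stop("GMT line ", bad[1], " has fewer than 3 fields")
  nm <- vapply(parts, `[[`, character(1), 1)
  if (anyDuplicated(nm))
    stop("duplicate gene-set name(s): ",
         paste(unique(nm[duplicated(nm)]), collapse = ", "))
  sets <- lapply(parts, function(p) unique(p[-(1:2)]))
  names(sets) <- nm
  attr(sets, "description") <-
    stats::setNames(vapply(parts, `[[`, character(1), 2), nm)
  sets
}

#' Hypergeometric upper-tail probability
#'
#' P(X >= k) for X ~ Hypergeometric(background, setSize, draw): the chance
#' of seeing at least \code{k} annotated genes when drawing a module of
#' \code{draw} genes from a \code{background} universe containing
#' \code{setSize} annotated genes. Computed in log space via the stable
#' cumulative routine.
#'
#' @param k observed overlap count.
#' @param setSize annotated genes in the background.
#' @param draw module size (number of draws).
#' @param background universe size.
#' @return probability in [0, 1]; \code{k = 0} gives 1.
#' @export
hypergeomUpperTail <- function(k, setSize, draw, background) {
  stopifnot(k >= 0, draw >= 0, setSize >= 0)
  if (k > draw || draw > background || setSize > background)
    stop("need k <= draw <= background and setSize <= background")
  if (k == 0) return(1)
  exp(stats::phyper(k - 1, setSize, background - setSize, draw,
                    lower.tail = FALSE, log.p = TRUE))
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Standard step-up adjustment with monotonicity enforced by a cumulative
#' minimum from the largest rank; output order matches input order.
#'
#' @param p numeric vector of p-values in [0, 1].
#' @return adjusted values (q-values), same length and order.
#' @export
bhAdjust <- function(p) {
  if (!length(p)) return(numeric())
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Hypergeometric over-representation analysis of modules
#'
#' Tests every (module, gene set) pair. Module and set memberships are first
#' intersected with the background universe; modules whose background-
#' intersected size falls outside \code{[minSize, maxSize]} are not tested.
#' p-values are upper-tail hypergeometric probabilities and q-values are
#' Benjamini-Hochberg adjusted across all tested pairs of the collection.
#'
#' @param ms a \linkS4class{GeneModuleSet} (or plain list of gene-id
#'   vectors).
#' @param sets named list of gene sets, e.g. from [readGMT()].
#' @param background character vector: the gene universe (typically all
#'   genes surviving preprocessing).
#' @param minSize,maxSize module-size gate (defaults 10 and 500).
#' @param pCut significance flag threshold on the raw p-value
#'   (default 0.01).
#' @return data.frame with columns module_id, term, k, set_size,
#'   module_size, background_size, p, q, significant.
#' @export
enrichModules <- function(ms, sets, background, minSize = 10L,
                          maxSize = 500L, pCut = 0.01) {
  mods <- if (methods::is(ms, "GeneModuleSet")) modules(ms) else ms
  if (!length(background)) stop("background gene universe is empty")
  if (anyDuplicated(background)) stop("background gene ids must be unique")
  isets <- lapply(sets, intersect, background)
  rows <- list()
  for (i in seq_along(mods)) {
    mg <- intersect(mods[[i]], background)
    n <- length(mg)
    if (n < minSize || n > maxSize) next
    for (s in seq_along(isets)) {
      k <- length(intersect(mg, isets[[s]]))
      rows[[length(rows) + 1]] <- data.frame(
        module_id = i, term = names(isets)[s], k = k,
        set_size = length(isets[[s]]), module_size = n,
        background_size = length(background),
        p = hypergeomUpperTail(k, length(isets[[s]]), n,
                               length(background)),
        stringsAsFactors = FALSE)
    }
  }
  if (!length(rows))
    return(data.frame(module_id = integer(), term = character(),
                      k = integer(), set_size = integer(),
                      module_size = integer(), background_size = integer(),
                      p = numeric(), q = numeric(),
                      significant = logical()))
  df <- do.call(rbind, rows)
  df$q <- bhAdjust(df$p)
  df$significant <- df$p <= pCut
  df
}
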