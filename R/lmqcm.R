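## lmQCM: local maximal quasi-clique merger.
##
## Seeds are edges that are at least as heavy as every other edge touching
## either endpoint; each seed grows greedily under an adaptive density
## floor, and overlapping modules are merged to a fixed point. Genes may
## belong to several modules or to none.

.moduleDensity <- function(W, idx) {
  n <- length(idx)
  if (n < 2) return(0)
  sum(W[idx, idx]) / (n * (n - 1))   # W symmetric, diag 0: sum == 2*internal
}

#' Locally maximal edges of a weighted network
#'
#' Returns the positive-weight edges whose weight is greater than or equal
#' to that of every other edge incident to either endpoint, sorted by weight
#' (descending) with ties broken by gene id (first the smaller endpoint id,
#' then the smaller second id, C collation). These are the only edges that
#' can seed a module.
#'
#' @param net a \linkS4class{GeneNetwork}.
#' @return data.frame with columns \code{from}, \code{to}, \code{weight}
#'   (possibly zero rows).
#' @export
localMaximalEdges <- function(net) {
  stopifnot(methods::is(net, "GeneNetwork"))
  W <- adjacency(net)
  g <- geneIDs(net)
  K <- length(g)
  empty <- data.frame(from = character(), to = character(),
                      weight = numeric(), stringsAsFactors = FALSE)
  if (K < 2) return(empty)
  rowMax <- apply(W, 1, max)
  ut <- which(upper.tri(W), arr.ind = TRUE)
  w <- W[ut]
  sel <- w > 0 & w >= rowMax[ut[, 1]] & w >= rowMax[ut[, 2]]
  if (!any(sel)) return(empty)
  i <- ut[sel, 1]; j <- ut[sel, 2]; w <- w[sel]
  a <- ifelse(.cOrder(g)[i] < .cOrder(g)[j], g[i], g[j])
  b <- ifelse(.cOrder(g)[i] < .cOrder(g)[j], g[j], g[i])
  ord <- order(-w, .cOrder(a), .cOrder(b))
  data.frame(from = a[ord], to = b[ord], weight = w[ord],
             stringsAsFactors = FALSE)
}

#' Grow one module from a seed edge
#'
#' Starting from the seed pair, repeatedly considers the outside gene v with
#' the largest total connection k(v) = sum of weights to the current module
#' C (ties toward the smaller gene id). v is admitted iff the density of the
#' expanded cluster does not decay too fast:
#' d(C + v) >= alpha_n * d(C), where d is the weighted quasi-clique density
#' and alpha_n = 1 - 1/(2 * alpha * (|C| + t)) is an adaptive factor that
#' lets density degrade gradually as the module grows. Growth stops at the
#' first rejection or when no outside gene has positive connection.
#'
#' @param net a \linkS4class{GeneNetwork}.
#' @param seed length-2 character vector (the seed edge's gene ids); its
#'   weight must be at least \code{gamma}.
#' @param gamma seed-edge admission threshold.
#' @param alpha,t adaptive-floor parameters (defaults 1 and 1).
#' @return list with \code{genes} (in accretion order, seed pair first) and
#'   \code{density}.
#' @export
growModule <- function(net, seed, gamma, alpha = 1, t = 1) {
  stopifnot(methods::is(net, "GeneNetwork"), length(seed) == 2)
  W <- adjacency(net)
  g <- geneIDs(net)
  si <- match(seed, g)
  if (anyNA(si)) stop("seed gene(s) not in network: ",
                      paste(seed[is.na(si)], collapse = ", "))
  if (W[si[1], si[2]] < gamma)
    stop("seed edge weight ", W[si[1], si[2]], " is below gamma = ", gamma)
  cRank <- .cOrder(g)
  inC <- logical(length(g))
  inC[si] <- TRUE
  members <- si
  sumW <- W[si[1], si[2]]                     # sum of internal weights
  kvec <- W[, si[1]] + W[, si[2]]             # connection of every gene to C
  repeat {
    n <- length(members)
    dens <- 2 * sumW / (n * (n - 1))
    cand <- which(!inC & kvec > 0)
    if (!length(cand)) break
    best <- cand[order(-kvec[cand], cRank[cand])[1]]
    alphaN <- 1 - 1 / (2 * alpha * (n + t))
    densNew <- 2 * (sumW + kvec[best]) / ((n + 1) * n)
    if (densNew < alphaN * dens) break
    inC[best] <- TRUE
    members <- c(members, best)
    sumW <- sumW + kvec[best]
    kvec <- kvec + W[, best]
  }
  list(genes = g[members], density = .moduleDensity(W, members))
}

#' Merge overlapping modules
#'
#' Repeatedly merges any pair of modules whose overlap ratio
#' |C1 int C2| / min(|C1|, |C2|) is at least \code{beta} into their union,
#' recomputing density from the network, until no pair qualifies (fixed
#' point). Larger modules are processed first; identical gene sets always
#' merge.
#'
#' @param mods list of modules, each a list with \code{genes} and optionally
#'   \code{density}, or a plain character vector of gene ids.
#' @param beta overlap ratio threshold in (0, 1]; the boundary is inclusive.
#' @param net the \linkS4class{GeneNetwork} densities are computed from.
#' @return a \linkS4class{GeneModuleSet}.
#' @export
mergeModules <- function(mods, beta, net) {
  stopifnot(methods::is(net, "GeneNetwork"), beta > 0, beta <= 1)
  W <- adjacency(net)
  g <- geneIDs(net)
  sets <- lapply(mods, function(m) if (is.character(m)) m else m$genes)
  sets <- sets[lengths(sets) >= 2]
  .sortKey <- function(s) paste(sort(s, method = "radix"), collapse = "\r")
  repeat {
    if (length(sets) <= 1) break
    ord <- order(-lengths(sets),
                 .cOrder(vapply(sets, .sortKey, character(1))))
    sets <- sets[ord]
    merged <- FALSE
    for (i in seq_len(length(sets) - 1)) {
      for (j in seq(i + 1, length(sets))) {
        ov <- length(intersect(sets[[i]], sets[[j]]))
        if (ov / min(length(sets[[i]]), length(sets[[j]])) >= beta) {
          u <- union(sets[[i]], sets[[j]])
          sets <- c(sets[-c(i, j)], list(u))
          merged <- TRUE
          break
        }
      }
      if (merged) break
    }
    if (!merged) break
  }
  ord <- order(-lengths(sets), .cOrder(vapply(sets, .sortKey, character(1))))
  sets <- sets[ord]
  dens <- vapply(sets, function(s) .moduleDensity(W, match(s, g)), numeric(1))
  methods::new("GeneModuleSet", modules = sets, densities = dens)
}

#' Mine gene co-expression modules with lmQCM
#'
#' Full miner: computes locally maximal edges, keeps those with weight at
#' least \code{gamma} as seeds, grows a module from each seed whose two
#' endpoints do not already co-occur in a previously grown module, merges
#' modules with overlap ratio >= \code{beta} to a fixed point, and finally
#' drops modules smaller than \code{minSize}. Deterministic: identical
#' inputs give identical module sets.
#'
#' @param net a \linkS4class{GeneNetwork}.
#' @param gamma weight threshold a locally maximal edge must reach to
#'   initiate a module; the most influential parameter.
#' @param alpha,t adaptive growth-floor parameters (defaults 1, 1).
#' @param beta merge overlap-ratio threshold (default 0.4).
#' @param minSize smallest module size reported (default 10).
#' @return a \linkS4class{GeneModuleSet} (possibly empty).
#' @export
lmQCM <- function(net, gamma, alpha = 1, t = 1, beta = 0.4, minSize = 10L) {
  stopifnot(methods::is(net, "GeneNetwork"), gamma > 0, alpha > 0, t >= 0,
            beta > 0, beta <= 1, minSize >= 2)
  seeds <- localMaximalEdges(net)
  seeds <- seeds[seeds$weight >= gamma, , drop = FALSE]
  grown <- list()
  for (s in seq_len(nrow(seeds))) {
    a <- seeds$from[s]; b <- seeds$to[s]
    dup <- any(vapply(grown, function(m) all(c(a, b) %in% m$genes),
                      logical(1)))
    if (dup) next
    grown[[length(grown) + 1]] <-
      growModule(net, c(a, b), gamma = gamma, alpha = alpha, t = t)
  }
  ms <- mergeModules(grown, beta = beta, net = net)
  keep <- lengths(ms@modules) >= minSize
  methods::new("GeneModuleSet", modules = ms@modules[keep],
               densities = ms@densities[keep])
}

#' Write modules as TSV
#'
#' One row per (module, gene): columns module_id (1-based, modules in
#' decreasing size order), gene_id, module_size, module_density.
#'
#' @param ms a \linkS4class{GeneModuleSet}.
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
writeModules <- function(ms, path) {
  stopifnot(methods::is(ms, "GeneModuleSet"))
  rows <- lapply(seq_along(ms@modules), function(i)
    data.frame(module_id = i, gene_id = ms@modules[[i]],
               module_size = length(ms@modules[[i]]),
               module_density = ms@densities[i], stringsAsFactors = FALSE))
  df <- if (length(rows)) do.call(rbind, rows) else
    data.frame(module_id = integer(), gene_id = character(),
               module_size = integer(), module_density = numeric())
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
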