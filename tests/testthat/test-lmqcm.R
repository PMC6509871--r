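test_that("locally maximal edges on hand-built graphs", {
  # path a-b-c, weights 3 and 1: only (a,b)
  net <- edgeNetwork(data.frame(from = c("a", "b"), to = c("b", "c"),
                                weight = c(3, 1)))
  lm <- localMaximalEdges(net)
  expect_equal(nrow(lm), 1)
  expect_equal(lm$from, "a"); expect_equal(lm$to, "b")
  expect_equal(lm$weight, 3)
  # equal-weight triangle: all three edges (weak inequality)
  tri <- cliqueNetwork(3, weight = 0.7)
  expect_equal(nrow(localMaximalEdges(tri)), 3)
})

test_that("locally maximal edges agree with an exhaustive scan", {
  for (s in 1:50) {
    net <- randomNetwork(8, seed = 1000 + s)
    W <- adjacency(net); g <- geneIDs(net)
    # O(E^2) oracle: compare every edge with every other incident edge
    found <- list()
    for (i in 1:7) for (j in (i + 1):8) {
      if (W[i, j] <= 0) next
      ok <- TRUE
      for (a in 1:8) for (b in 1:8) {
        if (a == b) next
        if ((a %in% c(i, j) || b %in% c(i, j)) && W[a, b] > W[i, j])
          ok <- FALSE
      }
      if (ok) found[[length(found) + 1]] <- c(g[i], g[j], W[i, j])
    }
    lm <- localMaximalEdges(net)
    expect_equal(nrow(lm), length(found))
    oracle <- sort(vapply(found, function(e) paste(e[1], e[2]), character(1)))
    expect_equal(sort(paste(lm$from, lm$to)), oracle)
  }
})

test_that("module growth follows the adaptive density rule", {
  # isolated edge: no candidates, module is the seed pair at density 1
  net <- edgeNetwork(data.frame(from = "a", to = "b", weight = 1))
  gm <- growModule(net, c("a", "b"), gamma = 0.5)
  expect_equal(sort(gm$genes), c("a", "b"))
  expect_equal(gm$density, 1)
  # complete K5 with unit weights grows to all 5 genes at density 1
  k5 <- cliqueNetwork(5)
  gm <- growModule(k5, c("g1", "g2"), gamma = 0.5)
  expect_equal(length(gm$genes), 5)
  expect_equal(gm$density, 1)
  # weakly attached third gene rejected: adding c would drop density
  # to 2*(1+0.4)/6 = 0.467 < alpha_2 * 1 = 5/6
  net4 <- edgeNetwork(data.frame(from = c("a", "c", "c"),
                                 to = c("b", "a", "b"),
                                 weight = c(1, 0.2, 0.2)),
                      genes = c("a", "b", "c", "d"))
  gm <- growModule(net4, c("a", "b"), gamma = 0.5)
  expect_equal(sort(gm$genes), c("a", "b"))
  # seed below gamma is a caller error
  expect_error(growModule(net4, c("c", "a"), gamma = 0.5), "below gamma")
})

test_that("module merging is inclusive at the overlap boundary", {
  net <- cliqueNetwork(13, weight = 0.5)
  A <- paste0("g", 1:10)
  B <- paste0("g", 9:13)
  # overlap 2 / min 5 = 0.4: inclusive boundary merges at beta = 0.4
  ms <- mergeModules(list(A, B), beta = 0.4, net = net)
  expect_equal(length(ms), 1)
  expect_setequal(ms[[1]], paste0("g", 1:13))
  # just above the ratio: no merge
  ms2 <- mergeModules(list(A, B), beta = 0.41, net = net)
  expect_equal(length(ms2), 2)
  # disjoint modules unchanged at any beta
  ms3 <- mergeModules(list(paste0("g", 1:5), paste0("g", 6:10)),
                      beta = 0.1, net = net)
  expect_equal(length(ms3), 2)
  # identical gene sets collapse to one
  ms4 <- mergeModules(list(A, rev(A)), beta = 1, net = net)
  expect_equal(length(ms4), 1)
})

test_that("merged module densities match explicit pair enumeration", {
  net <- randomNetwork(12, seed = 77)
  g <- geneIDs(net)
  ms <- mergeModules(list(g[1:6], g[4:9], g[10:12]), beta = 0.4, net = net)
  for (i in seq_len(length(ms)))
    expect_equal(moduleDensities(ms)[i], bruteDensity(net, ms[[i]]),
                 tolerance = 1e-9)
})

test_that("full miner separates planted cliques and respects gamma", {
  # two 8-cliques (internal 0.9) joined by one weak 0.1 edge
  g <- sprintf("g%02d", 1:16)
  W <- matrix(0, 16, 16, dimnames = list(g, g))
  W[1:8, 1:8] <- 0.9; W[9:16, 9:16] <- 0.9
  W[8, 9] <- W[9, 8] <- 0.1
  diag(W) <- 0
  net <- methods::new("GeneNetwork", genes = g, adjacency = W)
  ms <- lmQCM(net, gamma = 0.5, minSize = 3)
  expect_equal(length(ms), 2)
  expect_setequal(ms[[1]], g[1:8])
  expect_setequal(ms[[2]], g[9:16])
  # all weights below gamma: no seeds, empty result
  expect_equal(length(lmQCM(net, gamma = 0.95, minSize = 3)), 0)
  # defaults alpha = 1, t = 1, beta = 0.4 accepted without override
  expect_equal(length(lmQCM(net, gamma = 0.5, minSize = 3,
                            alpha = 1, t = 1, beta = 0.4)), 2)
})

test_that("miner output densities, overlaps and replay all check out", {
  sim <- simulateSubspaceExpression(moduleSizes = c(25, 20),
                                    subspaceDims = c(1, 2),
                                    nSamples = 60, backgroundGenes = 20,
                                    noiseSD = 0.05, seed = 5)
  fit <- solveLRR(t(sim$expr), 0.5)
  net <- representationNetwork(normalizeColumnsInfNorm(lowRank(fit)),
                               genes = rownames(sim$expr))
  beta <- 0.4
  ms <- lmQCM(net, gamma = 0.3, beta = beta, minSize = 5)
  expect_gt(length(ms), 0)
  W <- adjacency(net); g <- geneIDs(net)
  # recorded densities equal recomputed densities
  for (i in seq_len(length(ms)))
    expect_equal(moduleDensities(ms)[i], bruteDensity(net, ms[[i]]),
                 tolerance = 1e-9)
  # no post-merge pair overlaps at ratio >= beta
  if (length(ms) > 1) {
    for (i in 1:(length(ms) - 1)) for (j in (i + 1):length(ms)) {
      ov <- length(intersect(ms[[i]], ms[[j]])) /
        min(length(ms[[i]]), length(ms[[j]]))
      expect_lt(ov, beta)
    }
  }
  # replay: pre-merge growth traces satisfy the density-decay condition
  seeds <- localMaximalEdges(net)
  seeds <- seeds[seeds$weight >= 0.3, ]
  for (s in seq_len(nrow(seeds))) {
    gm <- growModule(net, c(seeds$from[s], seeds$to[s]), gamma = 0.3)
    ix <- match(gm$genes, g)
    for (step in seq(3, length(ix))) {
      C <- ix[seq_len(step - 1)]
      v <- ix[step]
      n <- length(C)
      dC <- sum(W[C, C]) / (n * (n - 1))
      dNew <- (sum(W[C, C]) + 2 * sum(W[v, C])) / ((n + 1) * n)
      alphaN <- 1 - 1 / (2 * (n + 1))
      expect_gte(dNew, alphaN * dC - 1e-12)
    }
  }
  # determinism: identical inputs give identical module sets
  ms2 <- lmQCM(net, gamma = 0.3, beta = beta, minSize = 5)
  expect_identical(modules(ms), modules(ms2))
  expect_identical(moduleDensities(ms), moduleDensities(ms2))
})

test_that("module TSV export has one row per gene with shared metadata", {
  net <- cliqueNetwork(6, weight = 0.8)
  ms <- lmQCM(net, gamma = 0.5, minSize = 3)
  f <- withr::local_tempfile(fileext = ".tsv")
  writeModules(ms, f)
  tab <- read.delim(f)
  expect_equal(nrow(tab), 6)
  expect_equal(unique(tab$module_id), 1)
  expect_equal(unique(tab$module_size), 6)
  expect_equal(unique(tab$module_density), 0.8)
})
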