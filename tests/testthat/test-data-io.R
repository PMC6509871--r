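test_that("tsv and csv round trips are value-identical", {
  m <- exprFixture(5, 4, seed = 3)
  for (fmt in c("tsv", "csv")) {
    f <- withr::local_tempfile(fileext = paste0(".", fmt))
    writeExpressionMatrix(m, f, format = fmt)
    se <- readExpressionMatrix(f, format = fmt)
    expect_equal(SummarizedExperiment::assay(se), m)
  }
})

test_that("mtx triplet input fills absent entries with zero", {
  f <- withr::local_tempfile(fileext = ".mtx")
  gf <- withr::local_tempfile()
  sf <- withr::local_tempfile()
  writeLines(c("%%MatrixMarket matrix coordinate real general",
               "2 3 3", "1 1 5", "2 2 7", "1 3 2"), f)
  writeLines(c("gA", "gB"), gf)
  writeLines(c("c1", "c2", "c3"), sf)
  se <- readExpressionMatrix(f, format = "mtx", geneFile = gf,
                             sampleFile = sf)
  m <- SummarizedExperiment::assay(se)
  expect_equal(dim(m), c(2L, 3L))
  expect_equal(sum(m != 0), 3)
  expect_equal(sum(m == 0), 3)
  expect_equal(m["gA", "c1"], 5)
  expect_equal(m["gB", "c2"], 7)
})

test_that("malformed delimited input is rejected with location info", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("gene\ts1\ts2", "g1\t1\t2", "g1\t3\t4"), f)
  expect_error(readExpressionMatrix(f), "duplicate gene id.*g1")
  writeLines(c("gene\ts1\ts2", "g1\t1\toops", "g2\t3\t4"), f)
  expect_error(readExpressionMatrix(f), "non-numeric.*oops.*g1.*s2")
  writeLines(c("gene\ts1\ts2", "g1\t1", "g2\t3\t4"), f)
  expect_error(readExpressionMatrix(f), "ragged|malformed")
})

test_that("probe collapse keeps the highest-mean probe per gene", {
  m <- rbind(p1 = c(4, 5, 6),    # mean 5
             p2 = c(6, 7, 8),    # mean 7 -> wins geneA
             p3 = c(9, 9, 9))    # unmapped -> dropped
  colnames(m) <- paste0("s", 1:3)
  map <- c(p1 = "geneA", p2 = "geneA")
  out <- collapseProbesets(m, map)
  expect_equal(rownames(out), "geneA")
  expect_equal(unname(out["geneA", ]), c(6, 7, 8))
  # exact tie -> lexicographically smaller probe id survives
  m2 <- rbind(pB = c(1, 3), pA = c(3, 1), dimnames = NULL)
  rownames(m2) <- c("pB", "pA"); colnames(m2) <- c("s1", "s2")
  out2 <- collapseProbesets(m2, c(pA = "g", pB = "g"))
  expect_equal(unname(out2["g", ]), c(3, 1))  # pA's row
  expect_error(collapseProbesets(m, c(q9 = "x")), "no probe")
})

test_that("microarray filter removes bottom mean then bottom variance", {
  set.seed(9)
  N <- 6
  K <- 100
  # means 1..100; distinct variances via scaled noise
  m <- t(sapply(1:K, function(i) i + scale(rnorm(N))[, 1] * (0.1 + i / 50)))
  dimnames(m) <- list(sprintf("g%03d", 1:K), sprintf("s%d", 1:N))
  out <- preprocessMicroarray(m, meanFrac = 0.20, varFrac = 0, topN = 1e6)
  expect_equal(nrow(out), 80)
  expect_setequal(rownames(out), sprintf("g%03d", 21:100))
  # topN larger than supply keeps everything
  out2 <- preprocessMicroarray(m[1:50, ], meanFrac = 0, varFrac = 0,
                               topN = 1e6)
  expect_equal(nrow(out2), 50)
  # monotone in topN: raising the cap never drops a previously kept gene
  a <- preprocessMicroarray(m, topN = 30)
  b <- preprocessMicroarray(m, topN = 60)
  expect_true(all(rownames(a) %in% rownames(b)))
  # output is always a subset of input genes, original order preserved
  expect_true(all(rownames(a) %in% rownames(m)))
  expect_false(is.unsorted(match(rownames(a), rownames(m))))
})

test_that("microarray filter count matches an independent quantile oracle", {
  set.seed(41)
  K <- 12500
  m <- matrix(rexp(K * 5, rate = 0.2), K, 5,
              dimnames = list(sprintf("g%05d", 1:K), paste0("s", 1:5)))
  out <- preprocessMicroarray(m)
  # oracle: sequential rank-based filtering computed independently
  mu <- rowMeans(m)
  keep1 <- rank(mu, ties.method = "min") > floor(0.20 * K)  # no ties (cont.)
  v <- apply(m[keep1, ], 1, var)
  keep2 <- rank(v, ties.method = "min") > floor(0.10 * sum(keep1))
  expected <- min(10000, sum(keep2))
  expect_equal(nrow(out), expected)
})

test_that("scRNA transform maps TPM 0 to 0 and 10 to 1 and is monotone", {
  tpm <- rbind(a = c(0, 10, 30), b = c(5, 20, 40), c = c(1, 2, 3))
  colnames(tpm) <- paste0("c", 1:3)
  out <- preprocessSingleCell(tpm, lowFrac = 0)
  expect_equal(out["a", 1], 0)
  expect_equal(out["a", 2], 1)
  expect_true(all(diff(out["a", ]) > 0))  # strictly monotone in TPM
  # all-zero gene removed even with no quantile filtering
  tpm2 <- rbind(tpm, z = c(0, 0, 0))
  expect_false("z" %in% rownames(preprocessSingleCell(tpm2, lowFrac = 0)))
  # negative TPM rejected
  tpm3 <- tpm; tpm3[1, 1] <- -1
  expect_error(preprocessSingleCell(tpm3), "negative TPM")
})

test_that("scRNA filter keeps the mean/variance top-set intersection", {
  set.seed(7)
  K <- 100
  tpm <- matrix(rexp(K * 20, rate = 0.1), K, 20,
                dimnames = list(sprintf("g%03d", 1:K), sprintf("c%02d", 1:20)))
  out <- preprocessSingleCell(tpm, lowFrac = 0.80)
  # oracle: independent rank computation on the transformed values
  lg <- log2(tpm / 10 + 1)
  mu <- rowMeans(lg)
  v <- apply(lg, 1, var)
  topMean <- rank(mu, ties.method = "min") > floor(0.8 * K)
  topVar <- rank(v, ties.method = "min") > floor(0.8 * K)
  expect_setequal(rownames(out), rownames(tpm)[topMean & topVar])
})
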