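test_that("singular value thresholding matches the closed form", {
  # diagonal case: singular values are the diagonal entries
  M <- diag(c(3, 1))
  expect_equal(svtOperator(M, 2), diag(c(1, 0)))
  # tau = 0 is the identity
  set.seed(5)
  M <- matrix(rnorm(12), 4, 3)
  expect_equal(svtOperator(M, 0), M, tolerance = 1e-12)
  # brute-force oracle: shrink every singular value explicitly
  for (r in 1:20) {
    M <- matrix(rnorm(12), 4, 3)
    s <- svd(M)
    expected <- s$u %*% diag(pmax(s$d - 0.5, 0)) %*% t(s$v)
    expect_lt(norm(svtOperator(M, 0.5) - expected, "F"), 1e-10)
  }
})

test_that("svt never increases singular values or the nuclear norm", {
  set.seed(6)
  for (r in 1:10) {
    M <- matrix(rnorm(30), 5, 6)
    out <- svtOperator(M, runif(1, 0, 2))
    expect_true(all(svd(out)$d <= svd(M)$d + 1e-12))
    expect_lte(sum(svd(out)$d), sum(svd(M)$d) + 1e-12)
  }
})

test_that("l2,1 shrinkage matches per-column scalar computation", {
  # single column of norm 5 shrunk by 2 -> same direction, norm 3
  v <- matrix(c(3, 4), 2, 1)
  out <- l21Shrinkage(v, 2)
  expect_equal(sqrt(sum(out^2)), 3)
  expect_equal(out / 3, v / 5, tolerance = 1e-12)
  # zero columns stay zero
  expect_equal(l21Shrinkage(matrix(0, 3, 2), 1), matrix(0, 3, 2))
  # per-column oracle on random input
  set.seed(8)
  M <- matrix(rnorm(20), 5, 4)
  out <- l21Shrinkage(M, 1)
  for (j in 1:4) {
    nj <- sqrt(sum(M[, j]^2))
    expected <- max(0, 1 - 1 / nj) * M[, j]
    expect_lt(max(abs(out[, j] - expected)), 1e-12)
    expect_lte(sqrt(sum(out[, j]^2)), nj + 1e-12)  # never grows a column
  }
})

test_that("solveLRR handles degenerate input", {
  X <- matrix(0, 4, 3)
  fit <- solveLRR(X, 1)
  expect_equal(lowRank(fit), matrix(0, 3, 3))
  expect_equal(errorMatrix(fit), matrix(0, 4, 3))
  expect_true(isConverged(fit))
  expect_error(solveLRR(matrix(1, 4, 1), 1), "at least 2 columns")
})

test_that("solveLRR agrees with the closed-form noise-free solution", {
  set.seed(11)
  X <- matrix(rnorm(40 * 3), 40, 3) %*% matrix(rnorm(3 * 30), 3, 30)
  fit <- solveLRR(X, 1e6)
  Zcf <- closedFormLRR(X)
  expect_true(isConverged(fit))
  expect_lt(norm(lowRank(fit) - Zcf, "F") / norm(Zcf, "F"), 1e-3)
  # objective at solver solution does not exceed the closed-form objective
  nuc <- function(M) sum(svd(M)$d)
  l21 <- function(M) sum(sqrt(colSums(M^2)))
  objFit <- nuc(lowRank(fit)) + 1e6 * l21(errorMatrix(fit))
  objCf <- nuc(Zcf)  # E = 0 is feasible for noise-free X
  expect_lte(objFit, objCf * (1 + 1e-3))
})

test_that("independent subspaces give a block-diagonal representation", {
  set.seed(12)
  b1 <- rnorm(20); b2 <- rnorm(20)
  X <- cbind(outer(b1, runif(5, 0.5, 1.5)), outer(b2, runif(5, 0.5, 1.5)))
  fit <- solveLRR(X, 1e6)
  Z <- abs(lowRank(fit))
  offBlock <- sum(Z[1:5, 6:10]) + sum(Z[6:10, 1:5])
  expect_lt(offBlock / sum(Z), 0.01)
})

test_that("column-sparse error concentrates on corrupted genes", {
  sim <- simulateSubspaceExpression(moduleSizes = c(30, 20),
                                    subspaceDims = c(1, 2),
                                    nSamples = 50, backgroundGenes = 0,
                                    noiseSD = 0.01, outlierFraction = 0.06,
                                    outlierSD = 5, seed = 7)
  X <- t(sim$expr)
  fit <- solveLRR(X, 0.02)
  E <- errorMatrix(fit)
  oi <- match(sim$truth$outliers, colnames(X))
  expect_gte(length(oi), 1)
  expect_gte(sum(E[, oi]^2) / sum(E^2), 0.90)
})

test_that("closed-form representation is a projector with rank-sized trace", {
  set.seed(13)
  # rank-1: outer product of the single right singular vector
  x <- rnorm(6)
  X1 <- outer(rnorm(4), x)
  P1 <- closedFormLRR(X1)
  v <- x / sqrt(sum(x^2))
  expect_equal(P1, outer(v, v), tolerance = 1e-10)
  # general: symmetric idempotent, trace = rank, reconstructs X
  X <- matrix(rnorm(6 * 3), 6, 3) %*% matrix(rnorm(3 * 8), 3, 8)
  P <- closedFormLRR(X)
  expect_equal(P, t(P), tolerance = 1e-10)
  expect_lt(norm(P %*% P - P, "F"), 1e-8)
  expect_equal(sum(diag(P)), 3, tolerance = 1e-8)
  expect_equal(sum(svd(P)$d), 3, tolerance = 1e-8)   # nuclear norm = rank
  expect_lt(norm(X %*% P - X, "F"), 1e-8)
  expect_error(closedFormLRR(matrix(0, 2, 2)), "zero")
})
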