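#' Singular value thresholding
#'
#' Proximal operator of the nuclear norm: shrinks every singular value of
#' \code{M} by \code{tau}, flooring at zero, and reconstructs.
#'
#' @param M real matrix.
#' @param tau non-negative shrinkage amount.
#' @return matrix of the same shape as \code{M}.
#' @export
svtOperator <- function(M, tau) {
  stopifnot(is.matrix(M), all(is.finite(M)), length(tau) == 1, tau >= 0)
  s <- svd(M)
  d <- pmax(s$d - tau, 0)
  keep <- d > 0
  if (!any(keep)) return(matrix(0, nrow(M), ncol(M)))
  s$u[, keep, drop = FALSE] %*%
    (d[keep] * t(s$v[, keep, drop = FALSE]))
}

#' Column-wise l2,1 shrinkage
#'
#' Proximal operator of the l2,1 norm (sum of column l2 norms): each column
#' is scaled by max(0, 1 - tau / ||column||); columns with norm at most
#' \code{tau} (including zero columns) become zero. Promotes column-sparse
#' error, matching corruption confined to a few genes.
#'
#' @param M real matrix.
#' @param tau non-negative shrinkage amount.
#' @return matrix of the same shape as \code{M}.
#' @export
l21Shrinkage <- function(M, tau) {
  stopifnot(is.matrix(M), all(is.finite(M)), length(tau) == 1, tau >= 0)
  nrm <- sqrt(colSums(M^2))
  scl <- ifelse(nrm > tau, 1 - tau / nrm, 0)
  scl[nrm == 0] <- 0
  M * rep(scl, each = nrow(M))
}

#' Solver options for the inexact ALM scheme
#'
#' The augmented-Lagrangian penalty starts at \code{mu0} and grows
#' geometrically by \code{rho} per sweep up to \code{muMax}; iteration stops
#' once both primal residuals (constraint X - XZ - E and auxiliary Z - J)
#' fall below \code{tol} in max-abs norm.
#'
#' @param tol convergence tolerance (default 1e-6).
#' @param maxIter iteration cap (default 1000).
#' @param mu0 initial penalty (default 1e-6).
#' @param rho penalty growth factor > 1 (default 1.1).
#' @param muMax penalty ceiling (default 1e10).
#' @return list of validated options.
#' @export
lrrOptions <- function(tol = 1e-6, maxIter = 1000L, mu0 = 1e-6,
                       rho = 1.1, muMax = 1e10) {
  stopifnot(tol > 0, maxIter >= 1, mu0 > 0, rho > 1, muMax > mu0)
  list(tol = tol, maxIter = as.integer(maxIter), mu0 = mu0, rho = rho,
       muMax = muMax)
}

#' Solve the noisy low-rank representation problem
#'
#' Minimizes ||Z||* + lambda ||E||_{2,1} subject to X = XZ + E by inexact
#' augmented Lagrange multipliers, using the data matrix itself as the
#' dictionary. For gene expression, X = t(G): columns of X are gene
#' profiles, so the l2,1 penalty makes E sparse across genes, absorbing
#' wholly corrupted (outlier) genes while Z captures the shared subspace
#' structure.
#'
#' Each sweep solves the three subproblems once: the auxiliary variable J by
#' singular value thresholding of Z + Y2/mu at 1/mu; Z in closed form from a
#' fixed Cholesky factorization of I + X'X; E by l2,1 shrinkage of
#' X - XZ + Y1/mu at lambda/mu. Multipliers Y1, Y2 then take a gradient
#' step and the penalty mu grows. All variables start at zero, so the solve
#' is deterministic.
#'
#' @param X N-by-K real matrix whose columns are the objects to cluster
#'   (gene profiles); K >= 2.
#' @param lambda positive trade-off between low rank and column-sparse
#'   error; large lambda forces E towards 0.
#' @param opts options from [lrrOptions()].
#' @param verbose if TRUE, prints residuals every 50 sweeps.
#' @return an \linkS4class{LRRFit}.
#' @seealso [closedFormLRR()] for the noise-free solution,
#'   [representationNetwork()] to turn Z into a gene network.
#' @export
solveLRR <- function(X, lambda, opts = lrrOptions(), verbose = FALSE) {
  stopifnot(is.matrix(X), all(is.finite(X)), length(lambda) == 1, lambda > 0)
  K <- ncol(X)
  if (K < 2) stop("at least 2 columns (genes) required")
  N <- nrow(X)
  XtX <- crossprod(X)
  R <- chol(diag(K) + XtX)          # fixed factor of (I + X'X)
  Z <- J <- matrix(0, K, K)
  E <- Y1 <- matrix(0, N, K)
  Y2 <- matrix(0, K, K)
  mu <- opts$mu0
  resC <- resA <- Inf
  it <- 0L
  while (it < opts$maxIter) {
    it <- it + 1L
    J <- svtOperator(Z + Y2 / mu, 1 / mu)
    Z <- backsolve(R, forwardsolve(t(R),
           crossprod(X, X - E) + J + (crossprod(X, Y1) - Y2) / mu))
    XZ <- X %*% Z
    E <- l21Shrinkage(X - XZ + Y1 / mu, lambda / mu)
    C1 <- X - XZ - E
    C2 <- Z - J
    if (!all(is.finite(C1)) || !all(is.finite(C2)))
      stop("non-finite intermediate at iteration ", it)
    Y1 <- Y1 + mu * C1
    Y2 <- Y2 + mu * C2
    mu <- min(opts$rho * mu, opts$muMax)
    resC <- max(abs(C1))
    resA <- max(abs(C2))
    if (verbose && it %% 50L == 0L)
      message(sprintf("  ALM sweep %d: constraint %.3e, auxiliary %.3e, mu %.2e",
                      it, resC, resA, mu))
    if (resC < opts$tol && resA < opts$tol) break
  }
  methods::new("LRRFit", Z = Z, E = E, lambda = lambda,
               converged = resC < opts$tol && resA < opts$tol,
               iterations = it,
               residuals = c(constraint = resC, auxiliary = resA))
}

#' Closed-form noise-free low-rank representation
#'
#' The exact minimizer of ||Z||* subject to X = XZ (dictionary = data) is
#' the shape-interaction matrix V V' from the thin SVD of X restricted to
#' strictly positive singular values. Serves as an analytic oracle for the
#' iterative solver on noise-free data, and is block-diagonal when the
#' columns of X come from independent subspaces.
#'
#' @param X real matrix with at least one nonzero entry.
#' @param relTol singular values below \code{relTol * max(singular value)}
#'   are treated as zero (default 1e-10).
#' @return the K-by-K projector V V' (K = ncol(X)).
#' @export
closedFormLRR <- function(X, relTol = 1e-10) {
  stopifnot(is.matrix(X), all(is.finite(X)))
  s <- svd(X)
  if (max(s$d) == 0) stop("X is identically zero")
  keep <- s$d > relTol * max(s$d)
  V <- s$v[, keep, drop = FALSE]
  tcrossprod(V)
}

#' Numerical rank
#'
#' Number of singular values exceeding \code{tol} times the largest singular
#' value.
#'
#' @param M real matrix.
#' @param tol relative tolerance (default 1e-8).
#' @return integer rank.
#' @export
numericalRank <- function(M, tol = 1e-8) {
  d <- svd(M, nu = 0, nv = 0)$d
  if (max(d) == 0) return(0L)
  sum(d > tol * max(d))
}
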