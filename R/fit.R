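# Non-negative regression of one bulk profile on a single-cell library, and
# the bootstrap orchestration over library subsamples.

# Lawson-Hanson active-set NNLS on the normal equations.
# AtA = t(X) %*% X, Atb = t(X) %*% y. Exact at convergence; used as the
# alternative solver and as an in-package reference for the quasi-Newton path.
.nnlsActiveSet <- function(AtA, Atb, tol = NULL, maxIter = NULL) {
  n <- length(Atb)
  if (is.null(tol)) tol <- 1e-10 * max(abs(Atb), 1)
  if (is.null(maxIter)) maxIter <- max(50L, 10L * n)
  x <- numeric(n)
  P <- rep(FALSE, n)
  w <- Atb
  iter <- 0L
  solveP <- function(P) {
    s <- numeric(n)
    sp <- tryCatch(solve(AtA[P, P, drop = FALSE], Atb[P]),
                   error = function(e)
                     qr.coef(qr(AtA[P, P, drop = FALSE]), Atb[P]))
    sp[is.na(sp)] <- 0
    s[P] <- sp
    s
  }
  while (any(!P) && max(w[!P]) > tol && iter < maxIter) {
    iter <- iter + 1L
    free <- which(!P)
    j <- free[which.max(w[free])]
    P[j] <- TRUE
    s <- solveP(P)
    inner <- 0L
    while (any(s[P] <= 0) && inner < maxIter) {
      inner <- inner + 1L
      Q <- P & (s <= 0)
      alpha <- min(x[Q] / (x[Q] - s[Q]))
      x <- x + alpha * (s - x)
      x[x < tol & P] <- 0
      P <- P & (x > 0)
      if (!any(P)) { s <- numeric(n); break }
      s <- solveP(P)
    }
    x <- s
    w <- Atb - AtA %*% x
  }
  pmax(as.numeric(x), 0)
}

# box-constrained quasi-Newton minimisation of 0.5 * ||y - X b||^2 with b >= 0,
# expressed through the precomputed Gram matrix
.lbfgsbNNLS <- function(AtA, Atb, yty, pgtol = 1e-9, maxit = 15000,
                        factr = 1e7) {
  n <- length(Atb)
  fn <- function(b) 0.5 * sum(b * (AtA %*% b)) - sum(b * Atb) + 0.5 * yty
  gr <- function(b) as.numeric(AtA %*% b - Atb)
  res <- stats::optim(par = numeric(n), fn = fn, gr = gr,
                      method = "L-BFGS-B", lower = 0,
                      control = list(maxit = maxit, pgtol = pgtol,
                                     factr = factr))
  pmax(res$par, 0)
}

.thresholdWeights <- function(beta, zeroThreshold) {
  m <- max(beta)
  if (m > 0) beta[beta < zeroThreshold * m] <- 0
  beta
}

.solveSample <- function(AtA, Atb, yty, solver, zeroThreshold,
                         pgtol, maxit, factr) {
  beta <- switch(solver,
    lbfgsb = .lbfgsbNNLS(AtA, Atb, yty, pgtol, maxit, factr),
    nnls = .nnlsActiveSet(AtA, Atb),
    stop(sprintf("unknown solver '%s'", solver), call. = FALSE))
  .thresholdWeights(beta, zeroThreshold)
}

#' Fit non-negative weights for a single bulk profile
#'
#' Solves \eqn{\min_{\beta \ge 0} \|y - X\beta\|} for one bulk expression
#' vector against a library of single-cell profiles. The non-negativity
#' constraint alone yields a sparse weight vector without extra regularisation.
#' The default solver is box-constrained L-BFGS-B; \code{solver = "nnls"}
#' selects an exact Lawson-Hanson active-set solution. Weights below
#' \code{zeroThreshold} times the largest weight are set to exact zero.
#'
#' @param y non-negative bulk expression vector (length = genes).
#' @param X non-negative genes x cells library matrix.
#' @param solver \code{"lbfgsb"} (default) or \code{"nnls"}.
#' @param zeroThreshold relative support threshold, default \code{1e-8}.
#' @param pgtol projected-gradient tolerance for the quasi-Newton solver.
#' @param maxit iteration cap for the quasi-Newton solver.
#' @param factr relative objective-reduction stop (see \code{\link[stats]{optim}}).
#' @return non-negative weight vector, one entry per library cell (named when
#'   \code{X} has column names).
#' @examples
#' X <- diag(2); rownames(X) <- c("g1", "g2"); colnames(X) <- c("c1", "c2")
#' fitWeights(c(3, 5), X)  # (3, 5)
#' @export
fitWeights <- function(y, X, solver = c("lbfgsb", "nnls"),
                       zeroThreshold = 1e-8, pgtol = 1e-9, maxit = 15000,
                       factr = 1e7) {
  solver <- match.arg(solver)
  X <- as.matrix(X)
  y <- as.numeric(y)
  if (length(y) != nrow(X))
    stop("length(y) must equal nrow(X)", call. = FALSE)
  .checkFinite(y, "bulk vector")
  .checkFinite(X, "library matrix")
  .checkNonNegative(y, "bulk vector")
  .checkNonNegative(X, "library matrix")
  if (all(X == 0))
    stop("degenerate library: reference matrix is all zero", call. = FALSE)
  beta <- .solveSample(crossprod(X), as.numeric(crossprod(X, y)), sum(y * y),
                       solver, zeroThreshold, pgtol, maxit, factr)
  names(beta) <- colnames(X)
  beta
}

#' Fit virtual tissues with bootstrap subsampling of the library
#'
#' Reconstructs every bulk sample as a sparse non-negative combination of
#' single-cell profiles. To stabilise the estimates, the library is
#' subsampled \code{nRuns} times (a uniform random fraction
#' \code{cellFraction} of cells, drawn without replacement) and every bulk
#' sample is fitted independently against each subsample. Derived quantities
#' (frequencies, per-label expression, residuals) are later averaged across
#' runs by \code{\link{decomposeTissues}} and \code{\link{qualityReport}}.
#'
#' Inputs are harmonized first (shared gene set, common column scale; see
#' \code{\link{harmonize}}). The whole procedure is deterministic given
#' \code{seed}.
#'
#' @inheritParams harmonize
#' @inheritParams fitWeights
#' @param nRuns number of bootstrap runs (default 50).
#' @param cellFraction fraction of library cells per run, in (0, 1]
#'   (default 0.10).
#' @param seed integer seed controlling the subsample draws.
#' @return a \linkS4class{TissueFit}.
#' @examples
#' set.seed(1)
#' X <- matrix(rexp(60), 20, 3,
#'             dimnames = list(paste0("g", 1:20), paste0("c", 1:3)))
#' Y <- matrix(X %*% c(1, 2, 0), dimnames = list(paste0("g", 1:20), "s1"))
#' fit <- bootstrapFit(Y, X, nRuns = 2, cellFraction = 1, seed = 7)
#' runWeights(fit, 1)
#' @export
bootstrapFit <- function(bulk, library, labels = NULL, donors = NULL,
                         nRuns = 50, cellFraction = 0.1, seed = 1L,
                         solver = c("lbfgsb", "nnls"), zeroThreshold = 1e-8,
                         rescale = TRUE, targetSum = 1e4,
                         pgtol = 1e-9, maxit = 15000, factr = 1e7) {
  solver <- match.arg(solver)
  if (nRuns < 1) stop("nRuns must be >= 1", call. = FALSE)
  if (!(cellFraction > 0 && cellFraction <= 1))
    stop("cellFraction must lie in (0, 1]", call. = FALSE)
  h <- harmonize(bulk, library, labels, donors,
                 rescale = rescale, targetSum = targetSum)
  Y <- h$bulk
  X <- h$library
  nc <- ncol(X)
  subsetSize <- round(cellFraction * nc)
  if (subsetSize < 1)
    stop("cellFraction times the number of cells must round to >= 1",
         call. = FALSE)

  subsets <- .withSeed(seed, lapply(seq_len(nRuns), function(k)
    sort(sample.int(nc, subsetSize))))

  weights <- vector("list", nRuns)
  for (k in seq_len(nRuns)) {
    idx <- subsets[[k]]
    Xk <- X[, idx, drop = FALSE]
    AtA <- crossprod(Xk)
    AtY <- crossprod(Xk, Y)
    W <- matrix(0, subsetSize, ncol(Y),
                dimnames = list(colnames(Xk), colnames(Y)))
    for (s in seq_len(ncol(Y))) {
      W[, s] <- tryCatch(
        .solveSample(AtA, AtY[, s], sum(Y[, s]^2), solver, zeroThreshold,
                     pgtol, maxit, factr),
        error = function(e) stop(sprintf(
          "fit failed in bootstrap run %d, sample '%s': %s",
          k, colnames(Y)[s], conditionMessage(e)), call. = FALSE))
    }
    weights[[k]] <- Matrix::Matrix(W, sparse = TRUE)
  }

  methods::new("TissueFit",
    weights = weights, subsets = subsets, bulk = Y, library = X,
    cellLabels = h$labels, cellDonors = h$donors,
    config = list(nRuns = nRuns, cellFraction = cellFraction,
                  seed = as.integer(seed), zeroThreshold = zeroThreshold,
                  solver = solver, rescale = rescale, targetSum = targetSum))
}
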