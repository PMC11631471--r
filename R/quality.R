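# Relative-residual diagnostics: per-gene and per-sample quality scores and
# bootstrap-variance based stability assessment.

#' Relative residuals of a virtual-tissue fit
#'
#' For every bootstrap run, compares the bulk expression \eqn{Y} with the
#' explained expression \eqn{\tilde Y = X\beta} through the bounded relative
#' residual \eqn{r = |Y - \tilde Y| / (Y + \tilde Y) \in [0, 1]}; 0 indicates a
#' perfect fit, 1 that the reconstruction misses the gene entirely. A gene
#' absent from both bulk and reconstruction (0/0) is assigned residual 0.
#'
#' @param fit a \linkS4class{TissueFit}.
#' @param bulk bulk matrix to compare against; defaults to the harmonized bulk
#'   stored in the fit.
#' @return genes x samples x runs array of residuals in [0, 1].
#' @export
relativeResiduals <- function(fit, bulk = NULL) {
  stopifnot(methods::is(fit, "TissueFit"))
  Y <- if (is.null(bulk)) bulkMatrix(fit) else .unwrapBulk(bulk)
  X <- libraryMatrix(fit)
  if (!identical(dim(Y), dim(bulkMatrix(fit))))
    stop("bulk matrix does not match the fitted samples", call. = FALSE)
  K <- nRuns(fit)
  res <- array(0, c(nrow(Y), ncol(Y), K),
               dimnames = list(rownames(Y), colnames(Y), NULL))
  for (k in seq_len(K)) {
    idx <- runSubset(fit, k)
    Yhat <- as.matrix(X[, idx, drop = FALSE] %*% runWeights(fit, k))
    denom <- Y + Yhat
    r <- abs(Y - Yhat) / denom
    r[denom == 0] <- 0
    res[, , k] <- r
  }
  res
}

#' Per-gene quality score
#'
#' Mean relative residual of each gene over all samples and bootstrap runs:
#' \eqn{g_g = \frac{1}{N_s N_k} \sum_{s,k} r_{g,s}^{(k)}}. Genes poorly
#' represented in the single-cell library (e.g. because the cells expressing
#' them are missing) obtain scores near 1.
#'
#' @param residuals genes x samples x runs residual array from
#'   \code{\link{relativeResiduals}}.
#' @return named per-gene score vector in [0, 1].
#' @export
geneScore <- function(residuals) {
  apply(residuals, 1, mean)
}

#' Per-sample (virtual tissue) quality score
#'
#' Mean relative residual of each sample over all genes and bootstrap runs:
#' \eqn{b_s = \frac{1}{N_g N_k} \sum_{g,k} r_{g,s}^{(k)}}.
#'
#' @inheritParams geneScore
#' @return named per-sample score vector in [0, 1].
#' @export
tissueScore <- function(residuals) {
  apply(residuals, 2, mean)
}

#' Per-gene bootstrap variance of the residuals
#'
#' For each gene, the across-run variance of its residual (n-1 denominator),
#' computed per sample and then averaged over samples:
#' \eqn{v_g = \frac{1}{N_s} \sum_s \mathrm{var}_k(r_{g,s})}. Large values
#' relative to the mean flag genes whose fit depends on a few, possibly
#' outlier, cells.
#'
#' @inheritParams geneScore
#' @return named per-gene variance vector (non-negative).
#' @export
geneVariance <- function(residuals) {
  if (dim(residuals)[3] < 2)
    stop("variance undefined: at least two bootstrap runs required",
         call. = FALSE)
  apply(residuals, 1, function(slice) {
    # slice is samples x runs after dropping the gene dimension
    mean(apply(matrix(slice, nrow = dim(residuals)[2]), 1, stats::var))
  })
}

#' Quality report for a virtual-tissue fit
#'
#' Computes the residual tensor and all three summary scores in one pass.
#' With a single bootstrap run the gene bootstrap variance is undefined and
#' reported as \code{NA} with a warning.
#'
#' @inheritParams relativeResiduals
#' @return a \linkS4class{QualityReport}.
#' @export
qualityReport <- function(fit, bulk = NULL) {
  res <- relativeResiduals(fit, bulk)
  gv <- if (dim(res)[3] >= 2) {
    geneVariance(res)
  } else {
    warning("single bootstrap run: gene bootstrap variances undefined (NA)",
            call. = FALSE)
    stats::setNames(rep(NA_real_, dim(res)[1]), dimnames(res)[[1]])
  }
  methods::new("QualityReport",
    residuals = res,
    geneScores = geneScore(res),
    tissueScores = tissueScore(res),
    geneVariances = gv)
}

#' Filter genes and samples on quality scores
#'
#' Keeps genes with \eqn{g_g \le} \code{geneScoreMax} and bootstrap variance
#' \eqn{v_g \le} \code{varianceMax}, and samples with \eqn{b_s \le}
#' \code{tissueScoreMax}. Only well-reconstructed genes should be interpreted
#' downstream. The default variance cutoff is 10 times the mean gene
#' variance, since meaningful variance cutoffs are relative to the typical
#' bootstrap fluctuation.
#'
#' @param report a \linkS4class{QualityReport}.
#' @param geneScoreMax maximum per-gene score, in [0, 1] (default 0.5).
#' @param varianceMax maximum per-gene bootstrap variance; default
#'   \code{10 * mean(geneVariances)}.
#' @param tissueScoreMax maximum per-sample score, in [0, 1] (default 0.5).
#' @return list with character vectors \code{genes} and \code{samples} of the
#'   retained ids, plus the thresholds applied.
#' @export
applyQualityFilter <- function(report, geneScoreMax = 0.5, varianceMax = NULL,
                               tissueScoreMax = 0.5) {
  stopifnot(methods::is(report, "QualityReport"))
  if (geneScoreMax < 0 || geneScoreMax > 1 ||
      tissueScoreMax < 0 || tissueScoreMax > 1)
    stop("score thresholds must lie in [0, 1]", call. = FALSE)
  g <- geneScores(report)
  v <- geneVariances(report)
  b <- tissueScores(report)
  if (is.null(varianceMax))
    varianceMax <- if (all(is.na(v))) Inf else 10 * mean(v)
  if (varianceMax < 0) stop("varianceMax must be >= 0", call. = FALSE)
  vOK <- if (all(is.na(v))) rep(TRUE, length(g)) else v <= varianceMax
  keepGenes <- names(g)[g <= geneScoreMax & vOK]
  keepSamples <- names(b)[b <= tissueScoreMax]
  if (length(keepGenes) == 0)
    stop(paste("quality filter removed every gene;",
               "revise geneScoreMax / varianceMax thresholds"), call. = FALSE)
  message(sprintf("quality filter: kept %d/%d genes, %d/%d samples",
                  length(keepGenes), length(g), length(keepSamples),
                  length(b)))
  list(genes = keepGenes, samples = keepSamples,
       thresholds = list(geneScoreMax = geneScoreMax,
                         varianceMax = varianceMax,
                         tissueScoreMax = tissueScoreMax))
}
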