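#' @import methods
#' @importFrom Matrix Matrix
NULL

setClassUnion("characterOrNULL", c("character", "NULL"))
setClassUnion("numericOrNULL", c("numeric", "NULL"))

#' Virtual-tissue fit of bulk samples against a single-cell library
#'
#' Holds the result of fitting every bulk sample as a sparse non-negative
#' weighted sum of single-cell profiles, once per bootstrap subsample of the
#' library. Each run stores the drawn cell subset and its weight matrix
#' (cells-in-subset x samples). The harmonized bulk and library matrices are
#' retained so that decomposition and quality diagnostics can be computed
#' without re-supplying the inputs.
#'
#' @slot weights list of \code{nRuns} sparse matrices, one per bootstrap run;
#'   rows are the cells of that run's subset, columns the bulk samples.
#' @slot subsets list of integer vectors indexing the library columns drawn in
#'   each run.
#' @slot bulk harmonized bulk matrix (genes x samples).
#' @slot library harmonized single-cell matrix (genes x cells).
#' @slot cellLabels optional per-cell labels (cell type, cluster, state ...).
#' @slot cellDonors optional per-cell donor/sample-of-origin ids.
#' @slot config list of fitting parameters (nRuns, cellFraction, seed,
#'   zeroThreshold, solver, rescale, targetSum).
#' @export
setClass("TissueFit",
  slots = c(
    weights = "list",
    subsets = "list",
    bulk = "matrix",
    library = "matrix",
    cellLabels = "characterOrNULL",
    cellDonors = "characterOrNULL",
    config = "list"
  )
)

setValidity("TissueFit", function(object) {
  msg <- character()
  k <- length(object@weights)
  if (k != length(object@subsets))
    msg <- c(msg, "weights and subsets must have the same length")
  if (!identical(rownames(object@bulk), rownames(object@library)))
    msg <- c(msg, "bulk and library gene ids must agree (harmonize first)")
  nc <- ncol(object@library)
  for (i in seq_len(k)) {
    w <- object@weights[[i]]
    idx <- object@subsets[[i]]
    if (nrow(w) != length(idx))
      msg <- c(msg, sprintf("run %d: weight rows do not match subset size", i))
    if (ncol(w) != ncol(object@bulk))
      msg <- c(msg, sprintf("run %d: weight columns do not match samples", i))
    if (any(idx < 1 | idx > nc))
      msg <- c(msg, sprintf("run %d: subset index out of range", i))
    if (any(w@x < 0))
      msg <- c(msg, sprintf("run %d: negative weights", i))
  }
  if (!is.null(object@cellLabels) && length(object@cellLabels) != nc)
    msg <- c(msg, "cellLabels must have one entry per library cell")
  if (!is.null(object@cellDonors) && length(object@cellDonors) != nc)
    msg <- c(msg, "cellDonors must have one entry per library cell")
  if (length(msg)) msg else TRUE
})

#' Cell-type decomposition of virtual tissues
#'
#' Bootstrap-aggregated decomposition of a \linkS4class{TissueFit} under a
#' chosen cell labelling: effective per-label frequencies (bootstrap mean and
#' standard deviation), per-label explained expression, and the total
#' explained expression. Per-label expression matrices sum to the total
#' explained expression.
#'
#' @slot frequencies label x sample matrix of bootstrap-mean effective
#'   frequencies; \code{NA} for samples with zero total weight in every run.
#' @slot frequencySd label x sample matrix of bootstrap standard deviations
#'   (n-1 denominator).
#' @slot labelExpression named list, one genes x samples matrix per label
#'   (bootstrap mean of explained expression).
#' @slot totalExplained genes x samples bootstrap-mean explained expression.
#' @slot nRuns number of bootstrap runs aggregated.
#' @export
setClass("TissueDecomposition",
  slots = c(
    frequencies = "matrix",
    frequencySd = "matrix",
    labelExpression = "list",
    totalExplained = "matrix",
    nRuns = "numeric"
  )
)

setValidity("TissueDecomposition", function(object) {
  msg <- character()
  if (!identical(dim(object@frequencies), dim(object@frequencySd)))
    msg <- c(msg, "frequencies and frequencySd must have identical shape")
  if (!identical(sort(rownames(object@frequencies)),
                 sort(names(object@labelExpression))))
    msg <- c(msg, "labelExpression names must match frequency labels")
  f <- object@frequencies
  if (any(f < -1e-12 | f > 1 + 1e-12, na.rm = TRUE))
    msg <- c(msg, "frequencies must lie in [0, 1]")
  if (length(msg)) msg else TRUE
})

#' Fit-quality diagnostics for virtual tissues
#'
#' Relative residuals |Y - Yhat| / (Y + Yhat), bounded in [0, 1], for every
#' gene, sample and bootstrap run, together with the per-gene mean score, the
#' per-sample (virtual-tissue) mean score, and the per-gene mean across-run
#' variance used to judge bootstrap stability.
#'
#' @slot residuals genes x samples x runs array of relative residuals.
#' @slot geneScores per-gene mean residual over samples and runs.
#' @slot tissueScores per-sample mean residual over genes and runs.
#' @slot geneVariances per-gene mean (over samples) of the across-run residual
#'   variance; \code{NA} when fewer than two runs are available.
#' @export
setClass("QualityReport",
  slots = c(
    residuals = "array",
    geneScores = "numeric",
    tissueScores = "numeric",
    geneVariances = "numeric"
  )
)

setValidity("QualityReport", function(object) {
  msg <- character()
  r <- object@residuals
  if (length(dim(r)) != 3)
    msg <- c(msg, "residuals must be a genes x samples x runs array")
  if (any(r < -1e-12 | r > 1 + 1e-12))
    msg <- c(msg, "relative residuals must lie in [0, 1]")
  if (length(object@geneScores) != dim(r)[1])
    msg <- c(msg, "one gene score per gene required")
  if (length(object@tissueScores) != dim(r)[2])
    msg <- c(msg, "one tissue score per sample required")
  if (length(msg)) msg else TRUE
})
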