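#' @rdname TissueFit-class
#' @export
setMethod("bulkMatrix", "TissueFit", function(x) x@bulk)

#' @rdname TissueFit-class
#' @export
setMethod("libraryMatrix", "TissueFit", function(x) x@library)

#' @rdname TissueFit-class
#' @export
setMethod("cellLabels", "TissueFit", function(x) x@cellLabels)

#' @rdname TissueFit-class
#' @export
setMethod("cellDonors", "TissueFit", function(x) x@cellDonors)

#' @rdname TissueFit-class
#' @export
setMethod("fitConfig", "TissueFit", function(x) x@config)

#' @rdname TissueFit-class
#' @export
setMethod("nRuns", "TissueFit", function(x) length(x@weights))

#' @rdname TissueFit-class
#' @export
setMethod("runWeights", "TissueFit", function(x, k) x@weights[[k]])

#' @rdname TissueFit-class
#' @export
setMethod("runSubset", "TissueFit", function(x, k) x@subsets[[k]])

setMethod("show", "TissueFit", function(object) {
  cat("TissueFit:", nrow(object@bulk), "genes,",
      ncol(object@bulk), "bulk samples,",
      ncol(object@library), "library cells\n")
  k <- length(object@weights)
  sz <- if (k) length(object@subsets[[1]]) else 0
  cat("  bootstrap runs:", k, sprintf("(subset size %d, fraction %.3g)", sz,
      object@config$cellFraction), "\n")
  if (k) {
    supp <- vapply(object@weights, function(w) mean(colSums(as.matrix(w) > 0)),
                   numeric(1))
    cat(sprintf("  mean cells per virtual tissue: %.1f\n", mean(supp)))
  }
  cat("  solver:", object@config$solver, " seed:", object@config$seed, "\n")
  if (!is.null(object@cellLabels))
    cat("  labels:", length(unique(object@cellLabels)), "levels\n")
  invisible(NULL)
})

#' @rdname TissueDecomposition-class
#' @export
setMethod("frequencies", "TissueDecomposition", function(x) x@frequencies)

#' @rdname TissueDecomposition-class
#' @export
setMethod("frequencySd", "TissueDecomposition", function(x) x@frequencySd)

#' @rdname TissueDecomposition-class
#' @export
setMethod("labelExpression", "TissueDecomposition", function(x, label = NULL) {
  if (is.null(label)) return(x@labelExpression)
  if (!label %in% names(x@labelExpression))
    stop(sprintf("unknown label '%s'", label), call. = FALSE)
  x@labelExpression[[label]]
})

#' @rdname TissueDecomposition-class
#' @export
setMethod("totalExplained", "TissueDecomposition", function(x) x@totalExplained)

setMethod("show", "TissueDecomposition", function(object) {
  cat("TissueDecomposition:", nrow(object@frequencies), "labels x",
      ncol(object@frequencies), "samples,", object@nRuns, "bootstrap runs\n")
  cat("  mean frequencies:\n")
  print(round(rowMeans(object@frequencies, na.rm = TRUE), 4))
  invisible(NULL)
})

#' @rdname QualityReport-class
#' @export
setMethod("geneScores", "QualityReport", function(x) x@geneScores)

#' @rdname QualityReport-class
#' @export
setMethod("tissueScores", "QualityReport", function(x) x@tissueScores)

#' @rdname QualityReport-class
#' @export
setMethod("geneVariances", "QualityReport", function(x) x@geneVariances)

#' @rdname QualityReport-class
#' @param object a \linkS4class{QualityReport}
#' @param ... ignored
#' @export
setMethod("residuals", "QualityReport", function(object, ...) object@residuals)

setMethod("show", "QualityReport", function(object) {
  d <- dim(object@residuals)
  cat("QualityReport:", d[1], "genes x", d[2], "samples x", d[3], "runs\n")
  cat(sprintf("  gene score   g: median %.3f (range %.3f-%.3f)\n",
              stats::median(object@geneScores), min(object@geneScores),
              max(object@geneScores)))
  cat(sprintf("  tissue score b: median %.3f (range %.3f-%.3f)\n",
              stats::median(object@tissueScores), min(object@tissueScores),
              max(object@tissueScores)))
  if (!all(is.na(object@geneVariances)))
    cat(sprintf("  bootstrap variance v: mean %.4g\n",
                mean(object@geneVariances)))
  invisible(NULL)
})
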