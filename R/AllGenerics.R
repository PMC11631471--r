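#' @rdname TissueFit-class
#' @param x,object a \linkS4class{TissueFit}, \linkS4class{TissueDecomposition}
#'   or \linkS4class{QualityReport}
#' @export
setGeneric("bulkMatrix", function(x) standardGeneric("bulkMatrix"))

#' @rdname TissueFit-class
#' @export
setGeneric("libraryMatrix", function(x) standardGeneric("libraryMatrix"))

#' @rdname TissueFit-class
#' @export
setGeneric("cellLabels", function(x) standardGeneric("cellLabels"))

#' @rdname TissueFit-class
#' @export
setGeneric("cellDonors", function(x) standardGeneric("cellDonors"))

#' @rdname TissueFit-class
#' @export
setGeneric("fitConfig", function(x) standardGeneric("fitConfig"))

#' @rdname TissueFit-class
#' @export
setGeneric("nRuns", function(x) standardGeneric("nRuns"))

#' @rdname TissueFit-class
#' @param k bootstrap run index
#' @export
setGeneric("runWeights", function(x, k) standardGeneric("runWeights"))

#' @rdname TissueFit-class
#' @export
setGeneric("runSubset", function(x, k) standardGeneric("runSubset"))

#' @rdname TissueDecomposition-class
#' @export
setGeneric("frequencies", function(x) standardGeneric("frequencies"))

#' @rdname TissueDecomposition-class
#' @export
setGeneric("frequencySd", function(x) standardGeneric("frequencySd"))

#' @rdname TissueDecomposition-class
#' @param label optional label name; if omitted the full list is returned
#' @export
setGeneric("labelExpression",
           function(x, label = NULL) standardGeneric("labelExpression"))

#' @rdname TissueDecomposition-class
#' @export
setGeneric("totalExplained", function(x) standardGeneric("totalExplained"))

#' @rdname QualityReport-class
#' @export
setGeneric("geneScores", function(x) standardGeneric("geneScores"))

#' @rdname QualityReport-class
#' @export
setGeneric("tissueScores", function(x) standardGeneric("tissueScores"))

#' @rdname QualityReport-class
#' @export
setGeneric("geneVariances", function(x) standardGeneric("geneVariances"))
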