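# Turning fitted weights into effective cell-type frequencies and
# cell-type-specific expression under an arbitrary cell labelling.

.resolveLabels <- function(fit, labels) {
  if (is.null(labels)) labels <- cellLabels(fit)
  if (is.null(labels))
    stop("no cell labels: supply `labels` or fit with a labelled library",
         call. = FALSE)
  cells <- colnames(libraryMatrix(fit))
  if (!is.null(names(labels))) {
    missing <- setdiff(cells, names(labels))
    if (length(missing))
      stop(sprintf("unlabeled cell(s): %s",
                   paste(utils::head(missing, 5), collapse = ", ")),
           call. = FALSE)
    labels <- labels[cells]
  } else if (length(labels) != length(cells)) {
    stop("labels must have one entry per library cell", call. = FALSE)
  }
  labels <- as.character(labels)
  if (anyNA(labels)) {
    bad <- cells[is.na(labels)]
    stop(sprintf("unlabeled cell(s): %s",
                 paste(utils::head(bad, 5), collapse = ", ")), call. = FALSE)
  }
  names(labels) <- cells
  labels
}

#' Effective cell-type frequencies from one weight matrix
#'
#' For one fitted run, a label's effective frequency in a sample is its share
#' of the total fitted weight:
#' \eqn{c_s^a = \sum_{i: l_i = a} \beta_{i,s} / \sum_i \beta_{i,s}}.
#' Samples with zero total weight yield \code{NA} frequencies. Frequencies
#' compare the same label across samples; they are not corrected for per-cell
#' mRNA content, so different labels within one sample are not comparable.
#'
#' @param weights non-negative cells x samples weight matrix (a vector is
#'   treated as a single sample).
#' @param labels one label per row of \code{weights}.
#' @param levels optional label universe fixing the output rows (labels absent
#'   from \code{labels} get frequency 0).
#' @return label x sample matrix of frequencies summing to 1 per sample.
#' @examples
#' effectiveFrequencies(c(1, 1, 2), c("A", "A", "B"))  # A 0.5, B 0.5
#' @export
effectiveFrequencies <- function(weights, labels, levels = NULL) {
  if (is.null(dim(weights))) weights <- matrix(weights, ncol = 1)
  weights <- as.matrix(weights)
  if (length(labels) != nrow(weights))
    stop("one label per weight row required", call. = FALSE)
  if (anyNA(labels)) {
    bad <- rownames(weights)[is.na(labels)]
    if (is.null(bad)) bad <- which(is.na(labels))
    stop(sprintf("unlabeled cell(s): %s",
                 paste(utils::head(bad, 5), collapse = ", ")), call. = FALSE)
  }
  .checkNonNegative(weights, "weights")
  if (is.null(levels)) levels <- sort(unique(as.character(labels)))
  sums <- rowsum(weights, group = as.character(labels))
  out <- matrix(0, length(levels), ncol(weights),
                dimnames = list(levels, colnames(weights)))
  keep <- intersect(rownames(sums), levels)
  out[keep, ] <- sums[keep, , drop = FALSE]
  tot <- colSums(weights)
  freq <- sweep(out, 2, tot, "/")
  freq[, tot == 0] <- NA_real_
  freq
}

#' Explained expression per label from one run
#'
#' Sums the explained expression over all cells carrying each label:
#' \eqn{\tilde Y^a_{\cdot,s} = \sum_{i: l_i = a} X_{\cdot,i} \beta_{i,s}}.
#' Summing the result over labels recovers the total explained expression
#' \eqn{X\beta}.
#'
#' @param X genes x cells matrix for the cells of the run's subset.
#' @param weights cells x samples weight matrix aligned with \code{X}'s
#'   columns.
#' @param labels one label per cell.
#' @param levels optional label universe (absent labels yield zero matrices).
#' @return named list of genes x samples matrices, one per label.
#' @export
cellTypeExpression <- function(X, weights, labels, levels = NULL) {
  X <- as.matrix(X)
  if (is.null(dim(weights))) weights <- matrix(weights, ncol = 1)
  weights <- as.matrix(weights)
  if (ncol(X) != nrow(weights))
    stop("ncol(X) must equal nrow(weights)", call. = FALSE)
  if (length(labels) != ncol(X))
    stop("one label per cell required", call. = FALSE)
  labels <- as.character(labels)
  if (is.null(levels)) levels <- sort(unique(labels))
  out <- lapply(levels, function(a) {
    sel <- which(labels == a)
    if (length(sel) == 0)
      return(matrix(0, nrow(X), ncol(weights),
                    dimnames = list(rownames(X), colnames(weights))))
    X[, sel, drop = FALSE] %*% weights[sel, , drop = FALSE]
  })
  names(out) <- levels
  out
}

#' Decompose a virtual-tissue fit under a cell labelling
#'
#' Aggregates a \linkS4class{TissueFit} over its bootstrap runs into effective
#' per-label frequencies (mean and standard deviation across runs, n-1
#' denominator), per-label explained expression (bootstrap mean), and the
#' total explained expression. Frequencies are normalized within each run,
#' then averaged; labels absent from a run's subset contribute frequency 0 to
#' that run. Because the fitted weights are stored, the same fit can be
#' re-decomposed under any alternative labelling (cell types, clusters,
#' activation states, ...) without refitting: simply call this function again
#' with a different \code{labels} vector.
#'
#' @param fit a \linkS4class{TissueFit}.
#' @param labels per-cell labels; defaults to the labels stored in the fit.
#'   May be named by cell id or given in library column order.
#' @return a \linkS4class{TissueDecomposition}.
#' @export
decomposeTissues <- function(fit, labels = NULL) {
  stopifnot(methods::is(fit, "TissueFit"))
  labels <- .resolveLabels(fit, labels)
  levels <- sort(unique(labels))
  X <- libraryMatrix(fit)
  K <- nRuns(fit)
  S <- ncol(bulkMatrix(fit))
  G <- nrow(X)
  if (K == 1)
    warning("single bootstrap run: standard deviations reported as 0",
            call. = FALSE)

  freqArr <- array(NA_real_, c(length(levels), S, K),
                   dimnames = list(levels, colnames(bulkMatrix(fit)), NULL))
  exprSum <- lapply(levels, function(a)
    matrix(0, G, S, dimnames = list(rownames(X), colnames(bulkMatrix(fit)))))
  names(exprSum) <- levels
  totalSum <- matrix(0, G, S,
                     dimnames = list(rownames(X), colnames(bulkMatrix(fit))))

  for (k in seq_len(K)) {
    idx <- runSubset(fit, k)
    W <- as.matrix(runWeights(fit, k))
    runLabels <- labels[idx]
    freqArr[, , k] <- effectiveFrequencies(W, runLabels, levels = levels)
    ex <- cellTypeExpression(X[, idx, drop = FALSE], W, runLabels,
                             levels = levels)
    for (a in levels) exprSum[[a]] <- exprSum[[a]] + ex[[a]]
    totalSum <- totalSum + X[, idx, drop = FALSE] %*% W
  }

  freqMean <- apply(freqArr, c(1, 2), function(v) {
    if (all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE)
  })
  freqSd <- if (K == 1) {
    m <- freqMean; m[] <- 0; m[is.na(freqMean)] <- NA_real_; m
  } else {
    apply(freqArr, c(1, 2), function(v) {
      v <- v[!is.na(v)]
      if (length(v) < 2) return(if (length(v)) 0 else NA_real_)
      stats::sd(v)
    })
  }

  methods::new("TissueDecomposition",
    frequencies = freqMean, frequencySd = freqSd,
    labelExpression = lapply(exprSum, function(m) m / K),
    totalExplained = totalSum / K, nRuns = K)
}

#' Group-wise mean cell weights and group ratios
#'
#' For a two-group comparison of bulk samples (e.g. two disease subtypes),
#' computes for every library cell its mean fitted weight over the samples of
#' each group, averaged over the bootstrap runs in which the cell was drawn,
#' and per label the ratio of group means (group 1 over group 2). Cells never
#' drawn in any run are reported as missing.
#'
#' @param fit a \linkS4class{TissueFit}.
#' @param sampleGroups factor-like vector with exactly two levels, one entry
#'   per bulk sample (named by sample id or in sample order).
#' @param labels optional per-cell labels; defaults to the fit's labels.
#' @return list with \code{cells} (data.frame: cell_id, label, meanWeight1,
#'   meanWeight2, ratio, nRunsSeen) and \code{labelRatios} (data.frame: label,
#'   meanWeight1, meanWeight2, ratio), plus the group level names.
#' @export
meanCellWeights <- function(fit, sampleGroups, labels = NULL) {
  stopifnot(methods::is(fit, "TissueFit"))
  samples <- colnames(bulkMatrix(fit))
  if (!is.null(names(sampleGroups))) sampleGroups <- sampleGroups[samples]
  if (length(sampleGroups) != length(samples))
    stop("one group per bulk sample required", call. = FALSE)
  g <- factor(as.character(sampleGroups))
  if (nlevels(g) != 2)
    stop("exactly two sample groups required", call. = FALSE)
  if (any(table(g) == 0))
    stop("each group needs at least one sample", call. = FALSE)
  in1 <- g == levels(g)[1]

  nc <- ncol(libraryMatrix(fit))
  sum1 <- sum2 <- numeric(nc)
  seen <- integer(nc)
  for (k in seq_len(nRuns(fit))) {
    idx <- runSubset(fit, k)
    W <- as.matrix(runWeights(fit, k))
    sum1[idx] <- sum1[idx] + rowMeans(W[, in1, drop = FALSE])
    sum2[idx] <- sum2[idx] + rowMeans(W[, !in1, drop = FALSE])
    seen[idx] <- seen[idx] + 1L
  }
  m1 <- ifelse(seen > 0, sum1 / seen, NA_real_)
  m2 <- ifelse(seen > 0, sum2 / seen, NA_real_)

  lab <- if (is.null(labels) && is.null(cellLabels(fit))) {
    rep(NA_character_, nc)
  } else {
    .resolveLabels(fit, labels)
  }
  cells <- data.frame(
    cell_id = colnames(libraryMatrix(fit)), label = unname(lab),
    meanWeight1 = m1, meanWeight2 = m2, ratio = m1 / m2, nRunsSeen = seen,
    stringsAsFactors = FALSE)

  labelRatios <- NULL
  if (!all(is.na(lab))) {
    agg1 <- tapply(m1, lab, mean, na.rm = TRUE)
    agg2 <- tapply(m2, lab, mean, na.rm = TRUE)
    labelRatios <- data.frame(
      label = names(agg1), meanWeight1 = as.numeric(agg1),
      meanWeight2 = as.numeric(agg2),
      ratio = as.numeric(agg1) / as.numeric(agg2),
      stringsAsFactors = FALSE, row.names = NULL)
  }
  list(cells = cells, labelRatios = labelRatios, groups = levels(g))
}
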