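# Cell-type-specific differential ranking between two sample classes and
# ROC/AUC scoring of a known positive gene set.

# vectorised Welch t statistics per gene (rows); returns signed t
.rowWelchT <- function(A, B) {
  n1 <- ncol(A)
  n2 <- ncol(B)
  m1 <- rowMeans(A)
  m2 <- rowMeans(B)
  v1 <- .rowVar(A)
  v2 <- .rowVar(B)
  se2 <- v1 / n1 + v2 / n2
  t <- (m1 - m2) / sqrt(se2)
  zeroVar <- se2 == 0
  t[zeroVar & m1 == m2] <- 0
  t[zeroVar & m1 != m2] <- sign(m1 - m2)[zeroVar & m1 != m2] * Inf
  t
}

.differentialStatistic <- function(exprMat, classes, statistic) {
  g <- factor(as.character(classes))
  if (nlevels(g) != 2)
    stop("exactly two sample classes required", call. = FALSE)
  if (any(table(g) < 2))
    stop("each class needs at least two samples", call. = FALSE)
  A <- exprMat[, g == levels(g)[1], drop = FALSE]
  B <- exprMat[, g == levels(g)[2], drop = FALSE]
  st <- switch(statistic,
    welch = abs(.rowWelchT(log2(1 + A), log2(1 + B))),
    welch_signed = .rowWelchT(log2(1 + A), log2(1 + B)),
    lfc = abs(log2(1 + rowMeans(A)) - log2(1 + rowMeans(B))),
    lfc_signed = log2(1 + rowMeans(A)) - log2(1 + rowMeans(B)),
    stop(sprintf("unknown statistic '%s'", statistic), call. = FALSE))
  stats::setNames(st, rownames(exprMat))
}

#' Rank genes by cell-type-specific differential expression
#'
#' For each label's genes x samples expression matrix, computes a per-gene
#' differential statistic between two sample classes and ranks genes by
#' decreasing statistic (ties broken by gene id). The default statistic is
#' the absolute Welch t statistic on log2(1 + x); the log transform is used
#' for ranking only. Genes with zero variance in both classes and equal means
#' receive statistic 0.
#'
#' @param exprByLabel named list of genes x samples matrices (e.g. from
#'   \code{\link{labelExpression}}), or a single matrix.
#' @param classes two-level class assignment, one entry per sample; each
#'   class needs at least two samples.
#' @param statistic \code{"welch"} (absolute Welch t, default),
#'   \code{"welch_signed"}, \code{"lfc"} (absolute log fold change) or
#'   \code{"lfc_signed"}.
#' @return data.frame with columns \code{label}, \code{gene},
#'   \code{statistic}, \code{rank} (1 = most differential, a permutation of
#'   1..n per label).
#' @export
rankDifferential <- function(exprByLabel, classes,
                             statistic = c("welch", "welch_signed", "lfc",
                                           "lfc_signed")) {
  statistic <- match.arg(statistic)
  if (is.matrix(exprByLabel)) exprByLabel <- list(all = exprByLabel)
  out <- lapply(names(exprByLabel), function(lab) {
    st <- .differentialStatistic(exprByLabel[[lab]], classes, statistic)
    ord <- order(-st, names(st))
    r <- integer(length(st))
    r[ord] <- seq_along(st)
    data.frame(label = lab, gene = names(st), statistic = unname(st),
               rank = r, stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' ROC curve and AUC for a known positive gene set
#'
#' Scores how well a ranked statistic separates a set of positive genes from
#' the rest. The AUC is the pair-counting probability
#' \eqn{P(s_{pos} > s_{neg}) + \frac{1}{2} P(s_{pos} = s_{neg})} over all
#' positive/negative pairs (equivalently the Mann-Whitney statistic), and ROC
#' points are emitted at every score threshold.
#'
#' @param scores named numeric vector of per-gene statistics (larger = more
#'   differential).
#' @param positives character vector of positive gene ids; must be a
#'   non-empty proper subset of \code{names(scores)}.
#' @return list with \code{auc} (numeric in [0, 1]) and \code{roc}
#'   (data.frame: threshold, fpr, tpr).
#' @examples
#' s <- c(a = 5, b = 4, c = 3, d = 2, e = 1)
#' rocAuc(s, c("a", "b"))$auc  # 1: positives occupy the top ranks
#' @export
rocAuc <- function(scores, positives) {
  if (is.null(names(scores)))
    stop("scores must be named by gene id", call. = FALSE)
  pos <- names(scores) %in% positives
  if (!any(pos) || all(pos))
    stop("positives must be a non-empty proper subset of the scored genes",
         call. = FALSE)
  if (!all(positives %in% names(scores)))
    stop("unknown gene id(s) in positives", call. = FALSE)
  n1 <- sum(pos)
  n2 <- sum(!pos)
  r <- rank(scores)  # midranks handle ties as half-credit
  auc <- (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n2)

  ord <- order(-scores, names(scores))
  sOrd <- scores[ord]
  pOrd <- pos[ord]
  grp <- cumsum(!duplicated(sOrd))  # tie groups share one threshold
  tp <- cumsum(pOrd)
  fp <- cumsum(!pOrd)
  last <- !duplicated(grp, fromLast = TRUE)
  roc <- data.frame(threshold = sOrd[last],
                    fpr = fp[last] / n2, tpr = tp[last] / n1)
  roc <- rbind(data.frame(threshold = Inf, fpr = 0, tpr = 0), roc)
  rownames(roc) <- NULL
  list(auc = auc, roc = roc)
}
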