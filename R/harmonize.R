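#' Harmonize a bulk matrix and a single-cell library onto a shared gene set
#'
#' Restricts both matrices to the intersection of their gene ids, in a
#' deterministic (lexicographic) gene order, and optionally rescales every
#' column of both matrices to a common total, so that bulk samples and
#' single-cell profiles live on the same linear (CPM/TPM-like) scale.
#' Library cells that become all-zero after the gene restriction are dropped
#' with a warning, since they cannot contribute to any fit.
#'
#' @param bulk genes x samples matrix (or SummarizedExperiment), linear scale,
#'   non-negative, with gene ids as rownames.
#' @param library genes x cells matrix (or SingleCellExperiment /
#'   SummarizedExperiment) of single-cell profiles.
#' @param labels optional per-cell label vector (taken from the library's
#'   colData when available).
#' @param donors optional per-cell donor id vector.
#' @param rescale if \code{TRUE} (default) every column of both matrices is
#'   scaled to sum to \code{targetSum}.
#' @param targetSum common column total used when \code{rescale = TRUE};
#'   default \code{1e4}.
#' @return list with elements \code{bulk} (matrix), \code{library} (matrix),
#'   \code{labels}, \code{donors} (possibly \code{NULL}).
#' @examples
#' bulk <- matrix(c(2, 2), 2, 1, dimnames = list(c("g1", "g2"), "s1"))
#' lib <- matrix(1:6, 2, 3, dimnames = list(c("g1", "g2"), paste0("c", 1:3)))
#' h <- harmonize(bulk, lib, targetSum = 100)
#' colSums(h$bulk)  # 100
#' @export
harmonize <- function(bulk, library, labels = NULL, donors = NULL,
                      rescale = TRUE, targetSum = 1e4) {
  Y <- .unwrapBulk(bulk)
  lib <- .unwrapLibrary(library, labels, donors)
  X <- lib$values
  .checkUnique(rownames(Y), "bulk gene ids")
  .checkUnique(colnames(Y), "bulk sample ids")
  .checkUnique(rownames(X), "library gene ids")
  .checkUnique(colnames(X), "library cell ids")
  .checkFinite(Y, "bulk matrix")
  .checkFinite(X, "library matrix")
  .checkNonNegative(Y, "bulk matrix")
  .checkNonNegative(X, "library matrix")
  if (nrow(Y) == 0 || ncol(Y) == 0 || nrow(X) == 0 || ncol(X) == 0)
    stop("empty input matrix", call. = FALSE)

  shared <- sort(intersect(rownames(Y), rownames(X)))
  if (length(shared) == 0)
    stop(sprintf(
      "no shared genes between bulk (%d gene ids) and library (%d gene ids)",
      nrow(Y), nrow(X)), call. = FALSE)
  Y <- Y[shared, , drop = FALSE]
  X <- X[shared, , drop = FALSE]

  zero <- colSums(X) == 0
  if (any(zero)) {
    warning(sprintf(
      "dropping %d library cell(s) with all-zero profiles on the shared gene set",
      sum(zero)), call. = FALSE)
    X <- X[, !zero, drop = FALSE]
    if (ncol(X) == 0)
      stop("degenerate library: no cells left after gene restriction",
           call. = FALSE)
    if (!is.null(lib$labels)) lib$labels <- lib$labels[!zero]
    if (!is.null(lib$donors)) lib$donors <- lib$donors[!zero]
  }

  if (rescale) {
    scaleCols <- function(m) {
      cs <- colSums(m)
      bad <- cs == 0
      if (any(bad)) cs[bad] <- 1  # all-zero bulk columns stay all-zero
      sweep(m, 2, cs / targetSum, "/")
    }
    Y <- scaleCols(Y)
    X <- scaleCols(X)
  }
  list(bulk = Y, library = X, labels = lib$labels, donors = lib$donors)
}
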