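# Readers and writers for the plain-text interchange formats: dense TSV
# expression matrices, Matrix-Market sparse libraries with gene/cell side
# tables, long-format weight tables with JSON sidecars.

.readLines2 <- function(path) {
  if (!file.exists(path))
    stop(sprintf("file not found: %s", path), call. = FALSE)
  readLines(path)
}

#' Read a dense genes x samples expression TSV
#'
#' Expects a header row of sample ids and a first column of gene ids.
#' Validates rectangularity, id uniqueness and non-negativity; errors name
#' the offending line.
#'
#' @param path TSV file path.
#' @return numeric matrix with gene rownames and sample colnames.
#' @export
readExpressionMatrix <- function(path) {
  lines <- .readLines2(path)
  if (length(lines) < 2)
    stop(sprintf("%s: need a header and at least one gene row", path),
         call. = FALSE)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nCol <- length(fields[[1]])
  bad <- which(vapply(fields, length, integer(1)) != nCol)
  if (length(bad))
    stop(sprintf("%s: ragged row at line %d (expected %d fields)",
                 path, bad[1], nCol), call. = FALSE)
  header <- fields[[1]]
  samples <- header[-1]
  geneRows <- fields[-1]
  genes <- vapply(geneRows, `[[`, character(1), 1)
  dup <- which(duplicated(genes))
  if (length(dup))
    stop(sprintf("%s: duplicate gene id '%s' at line %d",
                 path, genes[dup[1]], dup[1] + 1), call. = FALSE)
  .checkUnique(samples, sprintf("sample ids in %s", path))
  vals <- vapply(geneRows, function(f) as.numeric(f[-1]),
                 numeric(length(samples)))
  m <- if (length(samples) == 1) matrix(vals, ncol = 1) else t(vals)
  if (anyNA(m)) {
    badLine <- which(rowSums(is.na(m)) > 0)[1]
    stop(sprintf("%s: non-numeric value at line %d", path, badLine + 1),
         call. = FALSE)
  }
  dimnames(m) <- list(genes, samples)
  if (any(m < 0))
    stop(sprintf("%s: negative expression values", path), call. = FALSE)
  m
}

#' Write a dense genes x samples expression TSV
#'
#' @param mat genes x samples matrix.
#' @param path output TSV path.
#' @export
writeExpressionMatrix <- function(mat, path) {
  df <- data.frame(gene_id = rownames(mat), mat, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a single-cell library
#'
#' Accepts either a directory (or file triple) in Matrix-Market layout --
#' \code{matrix.mtx} (genes x cells), \code{genes.tsv} (one gene id per
#' line), \code{cells.tsv} (header: \code{cell_id}, optional \code{label},
#' optional \code{donor_id}) -- or a single dense TSV in the
#' \code{\link{readExpressionMatrix}} layout, optionally with a separate
#' cell metadata TSV.
#'
#' @param path directory containing the Matrix-Market triple, or a dense TSV.
#' @param cellsPath optional cell metadata TSV when \code{path} is dense.
#' @return a \link[SingleCellExperiment]{SingleCellExperiment} with assay
#'   \code{"expression"} and colData columns \code{label} / \code{donor}
#'   when present.
#' @export
readCellLibrary <- function(path, cellsPath = NULL) {
  if (dir.exists(path)) {
    mtx <- file.path(path, "matrix.mtx")
    genesF <- file.path(path, "genes.tsv")
    cellsF <- file.path(path, "cells.tsv")
    for (f in c(mtx, genesF, cellsF))
      if (!file.exists(f))
        stop(sprintf("missing library component: %s", f), call. = FALSE)
    m <- as.matrix(Matrix::readMM(mtx))
    genes <- readLines(genesF)
    meta <- utils::read.delim(cellsF, stringsAsFactors = FALSE)
    if (!"cell_id" %in% colnames(meta))
      stop(sprintf("%s: missing required column 'cell_id'", cellsF),
           call. = FALSE)
    if (nrow(m) != length(genes))
      stop(sprintf("%s: %d rows but %d gene ids", mtx, nrow(m),
                   length(genes)), call. = FALSE)
    if (ncol(m) != nrow(meta))
      stop(sprintf("%s: %d columns but %d cell rows", mtx, ncol(m),
                   nrow(meta)), call. = FALSE)
    .checkUnique(genes, sprintf("gene ids in %s", genesF))
    .checkUnique(meta$cell_id, sprintf("cell ids in %s", cellsF))
    .checkNonNegative(m, mtx)
    dimnames(m) <- list(genes, meta$cell_id)
  } else {
    m <- readExpressionMatrix(path)
    meta <- if (!is.null(cellsPath)) {
      utils::read.delim(cellsPath, stringsAsFactors = FALSE)
    } else {
      data.frame(cell_id = colnames(m), stringsAsFactors = FALSE)
    }
    if (!"cell_id" %in% colnames(meta))
      stop("cell metadata: missing required column 'cell_id'", call. = FALSE)
    if (!setequal(meta$cell_id, colnames(m)))
      stop("cell metadata ids do not match library columns", call. = FALSE)
    meta <- meta[match(colnames(m), meta$cell_id), , drop = FALSE]
  }
  cd <- S4Vectors::DataFrame(cell_id = colnames(m), row.names = colnames(m))
  if ("label" %in% colnames(meta)) cd$label <- meta$label
  if ("donor_id" %in% colnames(meta)) cd$donor <- meta$donor_id
  SingleCellExperiment::SingleCellExperiment(
    assays = list(expression = m), colData = cd)
}

#' Write a single-cell library in Matrix-Market layout
#'
#' @param library SingleCellExperiment or genes x cells matrix.
#' @param dir output directory (created if needed); writes
#'   \code{matrix.mtx}, \code{genes.tsv}, \code{cells.tsv}.
#' @export
writeCellLibrary <- function(library, dir) {
  lib <- .unwrapLibrary(library)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  Matrix::writeMM(Matrix::Matrix(lib$values, sparse = TRUE),
                  file.path(dir, "matrix.mtx"))
  writeLines(rownames(lib$values), file.path(dir, "genes.tsv"))
  meta <- data.frame(cell_id = colnames(lib$values),
                     stringsAsFactors = FALSE)
  if (!is.null(lib$labels)) meta$label <- unname(lib$labels)
  if (!is.null(lib$donors)) meta$donor_id <- unname(lib$donors)
  utils::write.table(meta, file.path(dir, "cells.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' Write fitted weights as a long-format TSV with a JSON sidecar
#'
#' Emits one row per (run, cell, sample) with weight above the support
#' threshold (zeros are omitted), plus \code{<stem>.json} holding the fit
#' configuration, seed and the bootstrap subsets needed to reconstruct the
#' fit.
#'
#' @param fit a \linkS4class{TissueFit}.
#' @param path output TSV path; the sidecar replaces the extension with
#'   \code{.json}.
#' @export
writeWeights <- function(fit, path) {
  stopifnot(methods::is(fit, "TissueFit"))
  rows <- lapply(seq_len(nRuns(fit)), function(k) {
    W <- as.matrix(runWeights(fit, k))
    nz <- which(W > 0, arr.ind = TRUE)
    if (nrow(nz) == 0) return(NULL)
    data.frame(run = k, cell_id = rownames(W)[nz[, 1]],
               sample_id = colnames(W)[nz[, 2]],
               weight = W[nz], stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  sidecar <- sub("\\.[^.]*$", ".json", path)
  jsonlite::write_json(
    list(config = fitConfig(fit),
         subsets = lapply(fit@subsets, function(i)
           colnames(libraryMatrix(fit))[i]),
         samples = colnames(bulkMatrix(fit)),
         genes = rownames(bulkMatrix(fit))),
    sidecar, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Reconstruct a TissueFit from a weight TSV and its inputs
#'
#' Re-reads a long-format weight table written by \code{\link{writeWeights}}
#' together with its JSON sidecar and the original bulk/library inputs, and
#' rebuilds the \linkS4class{TissueFit} (re-harmonizing with the recorded
#' configuration) so decomposition and quality reports can be produced
#' without refitting.
#'
#' @param path weight TSV path (sidecar expected next to it).
#' @param bulk,library the original inputs (paths or matrices).
#' @param labels,donors optional per-cell annotations.
#' @return a \linkS4class{TissueFit}.
#' @export
readWeights <- function(path, bulk, library, labels = NULL, donors = NULL) {
  sidecar <- sub("\\.[^.]*$", ".json", path)
  if (!file.exists(sidecar))
    stop(sprintf("missing sidecar: %s", sidecar), call. = FALSE)
  meta <- jsonlite::read_json(sidecar, simplifyVector = FALSE)
  meta$subsets <- lapply(meta$subsets, function(ids)
    unlist(ids, use.names = FALSE))
  if (is.character(bulk)) bulk <- readExpressionMatrix(bulk)
  if (is.character(library)) library <- readCellLibrary(library)
  h <- harmonize(bulk, library, labels, donors,
                 rescale = isTRUE(meta$config$rescale),
                 targetSum = meta$config$targetSum)
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  cells <- colnames(h$library)
  subsets <- lapply(meta$subsets, function(ids) {
    idx <- match(ids, cells)
    if (anyNA(idx))
      stop("sidecar subsets reference cells absent from the library",
           call. = FALSE)
    idx
  })
  weights <- lapply(seq_along(subsets), function(k) {
    idx <- subsets[[k]]
    W <- matrix(0, length(idx), ncol(h$bulk),
                dimnames = list(cells[idx], colnames(h$bulk)))
    sub <- tab[tab$run == k, , drop = FALSE]
    W[cbind(match(sub$cell_id, rownames(W)),
            match(sub$sample_id, colnames(W)))] <- sub$weight
    Matrix::Matrix(W, sparse = TRUE)
  })
  methods::new("TissueFit", weights = weights, subsets = subsets,
               bulk = h$bulk, library = h$library,
               cellLabels = h$labels, cellDonors = h$donors,
               config = meta$config)
}

#' Write a decomposition to TSV files
#'
#' Writes \code{frequencies.tsv}, \code{frequencies_sd.tsv} (label x sample)
#' and \code{expression_long.tsv} (gene, sample, label, value).
#'
#' @param decomposition a \linkS4class{TissueDecomposition}.
#' @param dir output directory.
#' @export
writeDecomposition <- function(decomposition, dir) {
  stopifnot(methods::is(decomposition, "TissueDecomposition"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  wr <- function(m, f) utils::write.table(
    data.frame(label = rownames(m), m, check.names = FALSE),
    file.path(dir, f), sep = "\t", quote = FALSE, row.names = FALSE)
  wr(frequencies(decomposition), "frequencies.tsv")
  wr(frequencySd(decomposition), "frequencies_sd.tsv")
  ex <- labelExpression(decomposition)
  long <- do.call(rbind, lapply(names(ex), function(a) {
    m <- ex[[a]]
    data.frame(gene = rep(rownames(m), ncol(m)),
               sample = rep(colnames(m), each = nrow(m)),
               label = a, value = as.vector(m), stringsAsFactors = FALSE)
  }))
  utils::write.table(long, file.path(dir, "expression_long.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' Write a quality report to TSV files
#'
#' Writes \code{quality_genes.tsv} (gene, g, v, pass) and
#' \code{quality_samples.tsv} (sample, b, pass) under the given thresholds.
#'
#' @param report a \linkS4class{QualityReport}.
#' @param dir output directory.
#' @inheritParams applyQualityFilter
#' @export
writeQualityReport <- function(report, dir, geneScoreMax = 0.5,
                               varianceMax = NULL, tissueScoreMax = 0.5) {
  stopifnot(methods::is(report, "QualityReport"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  kept <- tryCatch(
    applyQualityFilter(report, geneScoreMax, varianceMax, tissueScoreMax),
    error = function(e) list(genes = character(), samples = character()))
  g <- geneScores(report)
  utils::write.table(
    data.frame(gene = names(g), g = unname(g),
               v = unname(geneVariances(report)),
               pass = names(g) %in% kept$genes),
    file.path(dir, "quality_genes.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE)
  b <- tissueScores(report)
  utils::write.table(
    data.frame(sample = names(b), b = unname(b),
               pass = names(b) %in% kept$samples),
    file.path(dir, "quality_samples.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE)
  invisible(dir)
}

#' Select the most variable genes across bulk and library
#'
#' Ranks genes by the variance of log2(1 + x), computed separately across
#' bulk samples and across library cells, and scores each gene by the better
#' (smaller) of its two variance ranks, so a gene highly variable in either
#' dataset is eligible. The top \code{n} genes are returned with
#' deterministic gene-id tie-breaking. Inputs must already share an
#' identical gene set (see \code{\link{harmonize}}).
#'
#' @param bulk genes x samples matrix (or SummarizedExperiment).
#' @param library genes x cells matrix (or SingleCellExperiment).
#' @param n number of genes to select (default 1000).
#' @return character vector of selected gene ids (in gene-id order).
#' @export
selectVariableGenes <- function(bulk, library, n = 1000) {
  Y <- .unwrapBulk(bulk)
  X <- .unwrapLibrary(library)$values
  if (!identical(rownames(Y), rownames(X)))
    stop("bulk and library must share an identical gene set; harmonize first",
         call. = FALSE)
  if (n < 1) stop("n must be >= 1", call. = FALSE)
  genes <- rownames(Y)
  if (n >= length(genes)) {
    if (n > length(genes))
      warning(sprintf("requested %d genes but only %d available", n,
                      length(genes)), call. = FALSE)
    return(genes)
  }
  varB <- .rowVar(log2(1 + Y))
  varL <- .rowVar(log2(1 + X))
  rk <- function(v) {
    r <- integer(length(v))
    r[order(-v, genes)] <- seq_along(v)
    r
  }
  score <- pmin(rk(varB), rk(varL))
  sel <- order(score, genes)[seq_len(n)]
  sort(genes[sel])
}
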