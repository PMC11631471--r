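# Synthetic single-cell libraries and pseudo-bulk benchmark: discrete cell
# types with shared baseline expression plus type-specific marker blocks,
# donor structure, negative-binomial counts, and controlled within-type gene
# modifications that define a two-class pseudo-bulk benchmark.

#' Configuration for the synthetic benchmark
#'
#' Bundles and validates the parameters of the synthetic single-cell
#' generator and the pseudo-bulk benchmark built on top of it. Defaults
#' mirror the benchmark design: 8 donors split half into the fitting library
#' and half into the pseudo-bulk pool, 38 modified genes, half of one cell
#' type's cells modified, 100 pseudo-bulks of 500 summed cells split into two
#' classes.
#'
#' @param nGenes number of genes (default 500).
#' @param cellTypes named integer vector of cells per type (>= 2 types).
#' @param nDonors number of donors; the first half provide the fitting
#'   library, the second half the pseudo-bulk pool (default 8).
#' @param modifiedType name of the cell type carrying the modification.
#' @param modifiedCellFraction fraction of that type's cells modified, in
#'   (0, 1] (default 0.5).
#' @param nModifiedGenes number of randomly chosen modified genes
#'   (default 38).
#' @param log2FoldChange log2 fold change applied to the modified genes in
#'   the modified cells (benchmark grid spans 0.5 to 2; default 2).
#' @param nBulks number of pseudo-bulks, split equally into class I
#'   (modified) and class II (unmodified); must be even (default 100).
#' @param cellsPerBulk cells summed per pseudo-bulk (default 500).
#' @param seed integer seed (default 1).
#' @param markerFraction fraction of genes reserved as type-specific marker
#'   blocks; the remainder is shared across types so that modified genes are
#'   typically not exclusive to one type (default 0.4).
#' @param markerStrength multiplicative elevation of a type's markers over
#'   the shared baseline (default 8).
#' @param donorSd log-normal sd of per-donor, per-gene expression factors
#'   (default 0.1).
#' @param cellSizeSd log-normal sd of per-cell library-size factors
#'   (default 0.25).
#' @param nbSize negative-binomial size (dispersion) parameter of the count
#'   noise; \code{Inf} gives the deterministic zero-noise limit (default 4).
#' @param targetSum per-cell column total after linear (CPM-like) scaling
#'   (default 1e4).
#' @return validated list of class \code{scMosaicSimConfig}.
#' @export
simulationConfig <- function(nGenes = 500,
                             cellTypes = c(T_CD8 = 1200, T_CD4 = 1200,
                                           B = 800, Myeloid = 800),
                             nDonors = 8, modifiedType = "T_CD8",
                             modifiedCellFraction = 0.5, nModifiedGenes = 38,
                             log2FoldChange = 2, nBulks = 100,
                             cellsPerBulk = 500, seed = 1L,
                             markerFraction = 0.4, markerStrength = 8,
                             donorSd = 0.1, cellSizeSd = 0.25, nbSize = 4,
                             targetSum = 1e4) {
  if (length(cellTypes) < 2)
    stop("at least 2 cell types required (spill-over targets needed)",
         call. = FALSE)
  if (is.null(names(cellTypes)) || anyNA(names(cellTypes)))
    stop("cellTypes must be a named vector of cell counts", call. = FALSE)
  if (!modifiedType %in% names(cellTypes))
    stop(sprintf("modifiedType '%s' is not among the cell types",
                 modifiedType), call. = FALSE)
  if (!(modifiedCellFraction > 0 && modifiedCellFraction <= 1))
    stop("modifiedCellFraction must lie in (0, 1]", call. = FALSE)
  if (any(nModifiedGenes > nGenes))
    stop("nModifiedGenes must not exceed nGenes", call. = FALSE)
  if (any(nBulks %% 2 != 0))
    stop("nBulks must be even (half per class)", call. = FALSE)
  if (nDonors < 2)
    stop("at least 2 donors required for the library/bulk split",
         call. = FALSE)
  if (markerFraction < 0 || markerFraction >= 1)
    stop("markerFraction must lie in [0, 1)", call. = FALSE)
  structure(list(
    nGenes = as.integer(nGenes), cellTypes = cellTypes,
    nDonors = as.integer(nDonors), modifiedType = modifiedType,
    modifiedCellFraction = modifiedCellFraction,
    nModifiedGenes = as.integer(nModifiedGenes),
    log2FoldChange = log2FoldChange, nBulks = as.integer(nBulks),
    cellsPerBulk = as.integer(cellsPerBulk), seed = as.integer(seed),
    markerFraction = markerFraction, markerStrength = markerStrength,
    donorSd = donorSd, cellSizeSd = cellSizeSd, nbSize = nbSize,
    targetSum = targetSum), class = "scMosaicSimConfig")
}

#' Generate a synthetic single-cell population
#'
#' Draws single-cell profiles for every configured cell type around
#' type-specific archetypes: a shared baseline expression level per gene,
#' elevated by \code{markerStrength} on each type's disjoint marker block, a
#' per-donor log-normal gene factor, a per-cell library-size factor, and
#' negative-binomial count noise. Columns are scaled to a common linear
#' (CPM-like) total. Cells of donors in the first half are flagged as the
#' fitting library, the rest as the pseudo-bulk pool.
#'
#' @param config a \code{\link{simulationConfig}}.
#' @return a \link[SingleCellExperiment]{SingleCellExperiment} with assay
#'   \code{"expression"}, colData columns \code{cell_type}, \code{donor},
#'   \code{pool} ("library" or "bulk"), and rowData column
#'   \code{marker_type} naming the type whose marker block a gene belongs to
#'   (\code{NA} for shared baseline genes).
#' @export
simulateCells <- function(config) {
  stopifnot(inherits(config, "scMosaicSimConfig"))
  .withSeed(config$seed, {
    nGenes <- config$nGenes
    types <- names(config$cellTypes)
    nTypes <- length(types)
    genes <- sprintf("gene_%04d", seq_len(nGenes))

    baseMean <- stats::rgamma(nGenes, shape = 0.6, rate = 0.6 / 10) + 0.05
    nMarkPer <- floor(nGenes * config$markerFraction / nTypes)
    markerIdx <- if (nMarkPer > 0) {
      split(sample.int(nGenes, nMarkPer * nTypes),
            rep(seq_len(nTypes), each = nMarkPer))
    } else {
      rep(list(integer(0)), nTypes)
    }
    archetypes <- matrix(baseMean, nGenes, nTypes,
                         dimnames = list(genes, types))
    for (t in seq_len(nTypes))
      archetypes[markerIdx[[t]], t] <-
        archetypes[markerIdx[[t]], t] * config$markerStrength

    donorFactor <- matrix(
      stats::rlnorm(nGenes * config$nDonors, 0, config$donorSd),
      nGenes, config$nDonors)

    cellType <- rep(types, config$cellTypes)
    nCells <- length(cellType)
    donor <- unlist(lapply(config$cellTypes, function(n)
      sample(rep_len(seq_len(config$nDonors), n))), use.names = FALSE)
    sizeFactor <- if (config$cellSizeSd > 0)
      stats::rlnorm(nCells, 0, config$cellSizeSd) else rep(1, nCells)

    typeIdx <- match(cellType, types)
    mu <- archetypes[, typeIdx, drop = FALSE] *
      donorFactor[, donor, drop = FALSE]
    mu <- sweep(mu, 2, sizeFactor, "*")
    counts <- if (is.finite(config$nbSize)) {
      matrix(stats::rnbinom(length(mu), mu = as.vector(mu),
                            size = config$nbSize), nGenes, nCells)
    } else {
      mu
    }
    cs <- colSums(counts)
    cs[cs == 0] <- 1
    expr <- sweep(counts, 2, cs / config$targetSum, "/")
    dimnames(expr) <- list(genes, sprintf("cell_%05d", seq_len(nCells)))

    markerType <- rep(NA_character_, nGenes)
    for (t in seq_len(nTypes)) markerType[markerIdx[[t]]] <- types[t]

    libDonors <- seq_len(floor(config$nDonors / 2))
    SingleCellExperiment::SingleCellExperiment(
      assays = list(expression = expr),
      rowData = S4Vectors::DataFrame(gene_id = genes,
                                     marker_type = markerType,
                                     row.names = genes),
      colData = S4Vectors::DataFrame(
        cell_id = colnames(expr), cell_type = cellType,
        donor = sprintf("donor_%02d", donor),
        pool = ifelse(donor %in% libDonors, "library", "bulk"),
        row.names = colnames(expr)))
  })
}

#' Introduce a within-cell-type expression modification
#'
#' Multiplies the expression of the selected genes by \code{2^log2fc} in a
#' uniformly random fraction of the target type's cells, leaving every other
#' cell untouched. This creates a sub-state within one cell type whose
#' recovery the benchmark evaluates.
#'
#' @param cells a SingleCellExperiment (from \code{\link{simulateCells}}) or
#'   a genes x cells matrix plus \code{cellTypes}.
#' @param type target cell-type name.
#' @param fraction fraction of the type's cells to modify, in (0, 1].
#' @param geneIds modified gene ids (subset of rownames).
#' @param log2fc log2 fold change; 0 leaves the data unchanged.
#' @param seed integer seed for the cell draw.
#' @param cellTypes per-cell type vector when \code{cells} is a bare matrix.
#' @return list with \code{cells} (same container type as the input, with
#'   colData column \code{modified} when a SingleCellExperiment),
#'   \code{modifiedCells} and \code{modifiedGenes} (character ids).
#' @export
applyModification <- function(cells, type, fraction, geneIds, log2fc, seed,
                              cellTypes = NULL) {
  isSCE <- methods::is(cells, "SummarizedExperiment")
  if (isSCE) {
    cellTypes <- as.character(SummarizedExperiment::colData(cells)$cell_type)
    expr <- SummarizedExperiment::assay(cells, 1)
  } else {
    expr <- as.matrix(cells)
    if (is.null(cellTypes) || length(cellTypes) != ncol(expr))
      stop("cellTypes must be given, one per cell", call. = FALSE)
  }
  if (!all(geneIds %in% rownames(expr)))
    stop("modified gene ids must be a subset of the gene set", call. = FALSE)
  candidates <- which(cellTypes == type)
  if (length(candidates) == 0)
    stop(sprintf("no cells of type '%s'", type), call. = FALSE)
  nSel <- round(fraction * length(candidates))
  if (nSel < 1)
    stop("fraction times the type's cell count rounds to < 1", call. = FALSE)
  sel <- .withSeed(seed, sort(sample(candidates, nSel)))
  expr[geneIds, sel] <- expr[geneIds, sel] * 2^log2fc
  if (isSCE) {
    SummarizedExperiment::assay(cells, 1) <- expr
    SummarizedExperiment::colData(cells)$modified <-
      seq_len(ncol(expr)) %in% sel
  } else {
    cells <- expr
  }
  list(cells = cells, modifiedCells = colnames(expr)[sel],
       modifiedGenes = geneIds)
}

.poolMatrix <- function(x) {
  if (methods::is(x, "SummarizedExperiment"))
    as.matrix(SummarizedExperiment::assay(x, 1))
  else as.matrix(x)
}

#' Build two-class pseudo-bulk profiles
#'
#' Creates artificial bulk profiles by summing randomly drawn single-cell
#' profiles (without replacement within one bulk, with replacement across
#' bulks). Class-I bulks draw from the pool in which the target type's
#' modified sub-state is present; class-II bulks draw from the matched
#' unmodified pool, so the classes differ only through the modification.
#'
#' @param poolI genes x cells pool (matrix or SingleCellExperiment)
#'   containing the modified cells.
#' @param poolII matched unmodified pool.
#' @param nBulks total number of bulks, half per class (must be even).
#' @param cellsPerBulk cells summed into each bulk.
#' @param seed integer seed for the draws.
#' @return list with \code{bulk}
#'   (a \link[SummarizedExperiment]{SummarizedExperiment}, assay
#'   \code{"expression"}, colData column \code{class} in \{"I", "II"\}) and
#'   \code{cellsUsed} (list of drawn cell ids per bulk).
#' @export
buildPseudobulks <- function(poolI, poolII, nBulks, cellsPerBulk, seed) {
  XI <- .poolMatrix(poolI)
  XII <- .poolMatrix(poolII)
  if (!identical(rownames(XI), rownames(XII)))
    stop("pools must share the same gene set", call. = FALSE)
  if (nBulks %% 2 != 0) stop("nBulks must be even", call. = FALSE)
  if (cellsPerBulk > ncol(XI) || cellsPerBulk > ncol(XII))
    stop("cellsPerBulk exceeds the pool size", call. = FALSE)
  half <- nBulks / 2
  .withSeed(seed, {
    draws <- lapply(seq_len(nBulks), function(b) {
      pool <- if (b <= half) XI else XII
      sample.int(ncol(pool), cellsPerBulk)
    })
    mat <- vapply(seq_len(nBulks), function(b) {
      pool <- if (b <= half) XI else XII
      rowSums(pool[, draws[[b]], drop = FALSE])
    }, numeric(nrow(XI)))
    dimnames(mat) <- list(rownames(XI), sprintf("bulk_%03d", seq_len(nBulks)))
    cls <- rep(c("I", "II"), each = half)
    cellsUsed <- lapply(seq_len(nBulks), function(b) {
      pool <- if (b <= half) XI else XII
      colnames(pool)[draws[[b]]]
    })
    names(cellsUsed) <- colnames(mat)
    list(bulk = SummarizedExperiment::SummarizedExperiment(
           assays = list(expression = mat),
           colData = S4Vectors::DataFrame(class = cls,
                                          row.names = colnames(mat))),
         cellsUsed = cellsUsed)
  })
}

#' Run the pseudo-bulk attribution benchmark
#'
#' Full pipeline: simulate a multi-donor single-cell population, modify a
#' random gene set in half of one cell type's cells (in both the library
#' donors and the bulk donors, so the library contains the modified
#' sub-state), build class-I/class-II pseudo-bulks from the bulk donors only,
#' fit virtual tissues against the library donors, decompose per cell type,
#' rank genes by cell-type-specific differential expression between the two
#' classes, and compute per-type ROC/AUC with the modified genes as
#' positives. High AUC is expected only for the modified type; unmodified
#' types should stay near 0.5 (no spill-over). Grids of
#' \code{log2FoldChange} and \code{nModifiedGenes} values are evaluated in
#' all combinations.
#'
#' @param config a \code{\link{simulationConfig}}; its \code{log2FoldChange}
#'   and \code{nModifiedGenes} entries may be vectors (grid).
#' @param nRuns bootstrap runs for the fit (default 10).
#' @param cellFraction library fraction per bootstrap run (default 0.1).
#' @param statistic differential statistic passed to
#'   \code{\link{rankDifferential}}.
#' @param nPerm label permutations for the AUC null band (default 200).
#' @param solver passed to \code{\link{bootstrapFit}}.
#' @return list with \code{auc} (data.frame: label, log2fc, nModifiedGenes,
#'   auc, pPermutation, nullLow, nullHigh, modifiedType), \code{truth},
#'   and, for the last grid point, \code{fit}, \code{decomposition},
#'   \code{differential}.
#' @export
runBenchmark <- function(config, nRuns = 10, cellFraction = 0.1,
                         statistic = "welch", nPerm = 200,
                         solver = "lbfgsb") {
  stopifnot(inherits(config, "scMosaicSimConfig"))
  cells <- simulateCells(config)
  pool <- SummarizedExperiment::colData(cells)$pool
  libCells <- cells[, pool == "library"]
  bulkCells <- cells[, pool == "bulk"]

  rows <- list()
  lastFit <- lastDec <- lastDiff <- NULL
  truth <- list()
  gridId <- 0L
  for (nm in config$nModifiedGenes) {
    for (fc in config$log2FoldChange) {
      gridId <- gridId + 1L
      gmod <- .withSeed(config$seed + 11L + gridId,
                        sort(sample(rownames(cells), nm)))
      modLib <- applyModification(libCells, config$modifiedType,
                                  config$modifiedCellFraction, gmod, fc,
                                  seed = config$seed + 101L + gridId)
      modPool <- applyModification(bulkCells, config$modifiedType,
                                   config$modifiedCellFraction, gmod, fc,
                                   seed = config$seed + 201L + gridId)
      pb <- buildPseudobulks(modPool$cells, bulkCells, config$nBulks,
                             config$cellsPerBulk,
                             seed = config$seed + 301L + gridId)
      classes <- SummarizedExperiment::colData(pb$bulk)$class
      fit <- bootstrapFit(pb$bulk, modLib$cells,
                          nRuns = nRuns, cellFraction = cellFraction,
                          seed = config$seed + 401L + gridId, solver = solver)
      dec <- decomposeTissues(fit)
      diff <- rankDifferential(labelExpression(dec), classes,
                               statistic = statistic)
      for (lab in sort(names(labelExpression(dec)))) {
        dl <- diff[diff$label == lab, ]
        scores <- stats::setNames(dl$statistic, dl$gene)
        auc <- rocAuc(scores, gmod)$auc
        perm <- .permutationAUC(labelExpression(dec)[[lab]], classes, gmod,
                                nPerm = nPerm, statistic = statistic,
                                seed = config$seed + 501L + gridId)
        rows[[length(rows) + 1L]] <- data.frame(
          label = lab, log2fc = fc, nModifiedGenes = nm, auc = auc,
          pPermutation = mean(c(perm, auc) >= auc),
          nullLow = stats::quantile(perm, 0.025, names = FALSE),
          nullHigh = stats::quantile(perm, 0.975, names = FALSE),
          modifiedType = lab == config$modifiedType,
          stringsAsFactors = FALSE)
      }
      truth[[gridId]] <- list(log2fc = fc, nModifiedGenes = nm,
                              modifiedGenes = gmod,
                              modifiedLibraryCells = modLib$modifiedCells,
                              modifiedPoolCells = modPool$modifiedCells,
                              classes = stats::setNames(
                                classes,
                                colnames(SummarizedExperiment::assay(pb$bulk))))
      lastFit <- fit; lastDec <- dec; lastDiff <- diff
    }
  }
  list(auc = do.call(rbind, rows), truth = truth, fit = lastFit,
       decomposition = lastDec, differential = lastDiff)
}

# AUC null distribution under random class-label permutations, holding the
# decomposition fixed (the decomposition does not depend on the class labels)
.permutationAUC <- function(exprMat, classes, positives, nPerm, statistic,
                            seed) {
  .withSeed(seed, {
    vapply(seq_len(nPerm), function(i) {
      perm <- sample(classes)
      st <- .differentialStatistic(exprMat, perm, statistic)
      rocAuc(st, positives)$auc
    }, numeric(1))
  })
}
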