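tinyConfig <- function(...) {
  simulationConfig(nGenes = 50,
                   cellTypes = c(tA = 10, tB = 10),
                   nDonors = 2, modifiedType = "tA",
                   nModifiedGenes = 5, nBulks = 4, cellsPerBulk = 3,
                   seed = 7, ...)
}

test_that("the generator honours the configured shapes and labels", {
  cells <- simulateCells(tinyConfig())
  m <- SummarizedExperiment::assay(cells)
  expect_identical(dim(m), c(50L, 20L))
  expect_equal(unname(table(SummarizedExperiment::colData(cells)$cell_type)),
               c(10L, 10L), ignore_attr = TRUE)
  expect_true(all(m >= 0))
  # both donor pools populated
  expect_setequal(unique(SummarizedExperiment::colData(cells)$pool),
                  c("library", "bulk"))
})

test_that("the zero-noise limit collapses cells onto their type archetypes", {
  cfg <- tinyConfig(nbSize = Inf, cellSizeSd = 0, donorSd = 0)
  cells <- simulateCells(cfg)
  m <- SummarizedExperiment::assay(cells)
  ct <- SummarizedExperiment::colData(cells)$cell_type
  for (tp in unique(ct)) {
    cols <- m[, ct == tp, drop = FALSE]
    expect_equal(max(abs(cols - cols[, 1])), 0, tolerance = 1e-9)
  }
})

test_that("type archetypes are pairwise distinguishable", {
  cells <- simulateCells(simulationConfig(seed = 3))
  m <- SummarizedExperiment::assay(cells)
  ct <- SummarizedExperiment::colData(cells)$cell_type
  means <- sapply(unique(ct), function(tp) rowMeans(m[, ct == tp]))
  cosine <- function(a, b) sum(a * b) / sqrt(sum(a^2) * sum(b^2))
  pairs <- utils::combn(ncol(means), 2)
  cs <- apply(pairs, 2, function(p) cosine(means[, p[1]], means[, p[2]]))
  expect_true(all(cs < 0.95))
})

test_that("the generator is deterministic under its seed", {
  c1 <- SummarizedExperiment::assay(simulateCells(tinyConfig()))
  c2 <- SummarizedExperiment::assay(simulateCells(tinyConfig()))
  expect_identical(c1, c2)
})

test_that("modification multiplies exactly the selected entries", {
  cells <- simulateCells(tinyConfig())
  genes <- rownames(cells)[c(3, 7, 9)]
  m0 <- SummarizedExperiment::assay(cells)
  # log2fc = 0 leaves everything untouched
  mod0 <- applyModification(cells, "tA", 0.5, genes, 0, seed = 5)
  expect_equal(SummarizedExperiment::assay(mod0$cells), m0)
  # single cell, one gene, log2fc = 2 -> entry times 4
  one <- applyModification(cells, "tA", fraction = 1 / 10, genes[1],
                           log2fc = 2, seed = 5)
  cell <- one$modifiedCells
  expect_length(cell, 1)
  m1 <- SummarizedExperiment::assay(one$cells)
  expect_equal(m1[genes[1], cell], 4 * m0[genes[1], cell])
  diff <- m1 != m0
  expect_equal(sum(diff), sum(m0[genes[1], cell] != 0))
  # fraction too small for a single cell
  expect_error(applyModification(cells, "tA", 0.01, genes, 1, seed = 5),
               "rounds to < 1")
})

test_that("modified cells show the configured fold change on modified genes", {
  cfg <- simulationConfig(nGenes = 200, cellTypes = c(tA = 60, tB = 40),
                          nDonors = 2, modifiedType = "tA",
                          nBulks = 4, cellsPerBulk = 5, seed = 13,
                          nModifiedGenes = 20)
  cells <- simulateCells(cfg)
  genes <- sample(rownames(cells), 20)
  mod <- applyModification(cells, "tA", 0.5, genes, log2fc = 1.5, seed = 14)
  m <- SummarizedExperiment::assay(mod$cells)
  ct <- SummarizedExperiment::colData(cells)$cell_type
  isMod <- colnames(cells) %in% mod$modifiedCells
  ratio <- mean(m[genes, isMod]) / mean(m[genes, ct == "tA" & !isMod])
  expect_equal(ratio, 2^1.5, tolerance = 0.25)
})

test_that("pseudo-bulks are sums of drawn cells with the expected totals", {
  cells <- simulateCells(tinyConfig())
  m <- SummarizedExperiment::assay(cells)
  # cellsPerBulk = 1 reduces to single cell profiles
  pb1 <- buildPseudobulks(cells, cells, nBulks = 4, cellsPerBulk = 1,
                          seed = 3)
  b1 <- SummarizedExperiment::assay(pb1$bulk)
  expect_true(all(apply(b1, 2, function(col)
    any(apply(m, 2, function(cell) isTRUE(all.equal(col, cell,
                                                    check.attributes = FALSE)))))))
  # constant pool: every bulk is cellsPerBulk times the profile
  const <- matrix(rep(c(1, 2, 4), 4), 3, 4,
                  dimnames = list(paste0("g", 1:3), paste0("c", 1:4)))
  pbc <- buildPseudobulks(const, const, nBulks = 2, cellsPerBulk = 3,
                          seed = 4)
  expect_true(all(SummarizedExperiment::assay(pbc$bulk) == c(3, 6, 12)))
  # column totals concentrate around cellsPerBulk x mean cell total
  pb <- buildPseudobulks(m, m, nBulks = 10, cellsPerBulk = 5, seed = 5)
  tot <- colSums(SummarizedExperiment::assay(pb$bulk))
  expected <- 5 * mean(colSums(m))
  sdTot <- 5 * stats::sd(colSums(m))
  expect_true(all(abs(tot - expected) <= 3 * sdTot))
  expect_error(buildPseudobulks(m, m, 2, cellsPerBulk = 1000, seed = 1),
               "exceeds the pool")
})

test_that("bulk draws are reproducible and class II never contains modified cells", {
  cfg <- simulationConfig(nGenes = 100, cellTypes = c(tA = 40, tB = 40),
                          nDonors = 4, modifiedType = "tA", nBulks = 6,
                          cellsPerBulk = 10, nModifiedGenes = 10, seed = 21)
  cells <- simulateCells(cfg)
  pool <- SummarizedExperiment::colData(cells)$pool
  bulkCells <- cells[, pool == "bulk"]
  genes <- rownames(cells)[1:10]
  mod <- applyModification(bulkCells, "tA", 0.5, genes, 2, seed = 22)
  pb1 <- buildPseudobulks(mod$cells, bulkCells, 6, 10, seed = 23)
  pb2 <- buildPseudobulks(mod$cells, bulkCells, 6, 10, seed = 23)
  expect_identical(SummarizedExperiment::assay(pb1$bulk),
                   SummarizedExperiment::assay(pb2$bulk))
  cls <- SummarizedExperiment::colData(pb1$bulk)$class
  expect_equal(sum(cls == "I"), 3)
  # class-II bulks are built from the untouched pool, so none of their drawn
  # cells carries the modification
  classII <- names(pb1$cellsUsed)[cls == "II"]
  m0 <- SummarizedExperiment::assay(bulkCells)
  for (b in classII) {
    drawn <- pb1$cellsUsed[[b]]
    expect_equal(SummarizedExperiment::assay(pb1$bulk)[, b],
                 rowSums(m0[, drawn]))
  }
})

test_that("no cell contributes to both the fitting library and a pseudo-bulk", {
  cfg <- simulationConfig(nGenes = 100, cellTypes = c(tA = 40, tB = 40),
                          nDonors = 4, modifiedType = "tA", nBulks = 4,
                          cellsPerBulk = 10, nModifiedGenes = 5, seed = 31)
  cells <- simulateCells(cfg)
  cd <- SummarizedExperiment::colData(cells)
  libIds <- cd$cell_id[cd$pool == "library"]
  bulkCells <- cells[, cd$pool == "bulk"]
  pb <- buildPseudobulks(bulkCells, bulkCells, 4, 10, seed = 32)
  used <- unique(unlist(pb$cellsUsed))
  expect_length(intersect(used, libIds), 0)
  # and donors are split, not shared
  expect_length(intersect(cd$donor[cd$pool == "library"],
                          cd$donor[cd$pool == "bulk"]), 0)
})

test_that("configuration validation rejects inconsistent designs", {
  expect_error(simulationConfig(cellTypes = c(only = 5)), "at least 2")
  expect_error(simulationConfig(nModifiedGenes = 1000, nGenes = 10),
               "exceed")
  expect_error(simulationConfig(nBulks = 7), "even")
  expect_error(simulationConfig(modifiedType = "nope"), "not among")
})
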