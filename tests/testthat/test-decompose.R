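test_that("effective frequencies follow the weight-share definition", {
  expect_equal(effectiveFrequencies(c(1, 1, 2), c("A", "A", "B"))[, 1],
               c(A = 0.5, B = 0.5))
  expect_equal(effectiveFrequencies(c(0.2, 0.3, 0.5), c("A", "B", "B"))[, 1],
               c(A = 0.2, B = 0.8))
  expect_equal(effectiveFrequencies(c(0, 0, 3), c("A", "A", "B"))[, 1],
               c(A = 0, B = 1))
})

test_that("zero-total-weight samples yield missing frequencies", {
  W <- cbind(s1 = c(1, 1), s2 = c(0, 0))
  f <- effectiveFrequencies(W, c("A", "B"))
  expect_equal(unname(f[, "s1"]), c(0.5, 0.5))
  expect_true(all(is.na(f[, "s2"])))
})

test_that("unlabeled cells are reported by id", {
  W <- matrix(c(1, 2), 2, 1, dimnames = list(c("cellA", "cellB"), "s1"))
  expect_error(effectiveFrequencies(W, c("A", NA)), "cellB")
})

test_that("per-run frequencies are normalized and bounded in every run", {
  sf <- smallFit(nRuns = 4)
  labels <- sf$lib$labels
  names(labels) <- colnames(libraryMatrix(sf$fit))
  for (k in seq_len(nRuns(sf$fit))) {
    f <- effectiveFrequencies(as.matrix(runWeights(sf$fit, k)),
                              labels[runSubset(sf$fit, k)])
    ok <- colSums(!is.na(f)) > 0
    expect_equal(unname(colSums(f[, ok, drop = FALSE])),
                 rep(1, sum(ok)), tolerance = 1e-9)
    expect_true(all(f >= -1e-12 & f <= 1 + 1e-12, na.rm = TRUE))
  }
})

test_that("bootstrap sd follows the n-1 convention", {
  # two runs with frequencies 0.4 and 0.6 -> mean 0.5, sd sqrt(0.02)
  X <- diag(2)
  dimnames(X) <- list(c("g1", "g2"), c("c1", "c2"))
  fitLike <- function(freqA) {
    Matrix::Matrix(matrix(c(freqA, 1 - freqA), 2, 1,
                          dimnames = list(c("c1", "c2"), "s1")),
                   sparse = TRUE)
  }
  fit <- methods::new("TissueFit",
    weights = list(fitLike(0.4), fitLike(0.6)),
    subsets = list(1:2, 1:2),
    bulk = matrix(1, 2, 1, dimnames = list(c("g1", "g2"), "s1")),
    library = X, cellLabels = c(c1 = "A", c2 = "B"), cellDonors = NULL,
    config = list(nRuns = 2, cellFraction = 1, seed = 1L,
                  zeroThreshold = 0, solver = "nnls", rescale = FALSE,
                  targetSum = 1e4))
  dec <- decomposeTissues(fit)
  expect_equal(frequencies(dec)["A", 1], 0.5)
  expect_equal(frequencySd(dec)["A", 1], sqrt(0.02), tolerance = 1e-12)
})

test_that("constant frequencies across runs give sd 0 and one run warns", {
  sf <- smallFit(nRuns = 1)
  expect_warning(dec <- decomposeTissues(sf$fit), "single bootstrap run")
  expect_true(all(frequencySd(dec) == 0, na.rm = TRUE))
})

test_that("single-label decomposition reduces to the total explained expression", {
  sf <- smallFit(nRuns = 2)
  dec <- decomposeTissues(sf$fit,
                          rep("all", ncol(libraryMatrix(sf$fit))))
  expect_equal(labelExpression(dec, "all"), totalExplained(dec),
               tolerance = 1e-12)
  expect_true(all(abs(frequencies(dec) - 1) < 1e-12, na.rm = TRUE))
})

test_that("per-label expression follows the explained-sum definition", {
  X <- diag(2)
  dimnames(X) <- list(c("g1", "g2"), c("c1", "c2"))
  ex <- cellTypeExpression(X, c(1, 2), c("A", "B"))
  expect_equal(unname(ex$A[, 1]), c(1, 0))
  expect_equal(unname(ex$B[, 1]), c(0, 2))
})

test_that("label expressions sum to X beta in every run (conservation)", {
  sf <- smallFit(nRuns = 3)
  labels <- sf$lib$labels
  names(labels) <- colnames(libraryMatrix(sf$fit))
  X <- libraryMatrix(sf$fit)
  for (k in seq_len(nRuns(sf$fit))) {
    idx <- runSubset(sf$fit, k)
    W <- as.matrix(runWeights(sf$fit, k))
    ex <- cellTypeExpression(X[, idx], W, labels[idx])
    expect_equal(Reduce(`+`, ex), X[, idx] %*% W, tolerance = 1e-9)
  }
  dec <- decomposeTissues(sf$fit)
  expect_equal(Reduce(`+`, labelExpression(dec)), totalExplained(dec),
               tolerance = 1e-9)
})

test_that("relabeling is refit-free: identity, merges and splits behave additively", {
  sf <- smallFit(nRuns = 3)
  labels <- sf$lib$labels
  dec <- decomposeTissues(sf$fit, labels)
  # identity
  expect_equal(frequencies(decomposeTissues(sf$fit, labels)),
               frequencies(dec))
  # merge alpha and beta
  merged <- ifelse(labels %in% c("alpha", "beta"), "ab", labels)
  decM <- decomposeTissues(sf$fit, merged)
  expect_equal(frequencies(decM)["ab", ],
               frequencies(dec)["alpha", ] + frequencies(dec)["beta", ],
               tolerance = 1e-9)
  expect_equal(labelExpression(decM, "ab"),
               labelExpression(dec, "alpha") + labelExpression(dec, "beta"),
               tolerance = 1e-9)
  # split alpha by cell parity
  idx <- seq_along(labels)
  splitLab <- ifelse(labels == "alpha",
                     ifelse(idx %% 2 == 0, "alpha_even", "alpha_odd"),
                     labels)
  decS <- decomposeTissues(sf$fit, splitLab)
  expect_equal(decS@frequencies["alpha_even", ] + decS@frequencies["alpha_odd", ],
               frequencies(dec)["alpha", ], tolerance = 1e-9)
})

test_that("group-wise mean cell weights behave symmetrically and arithmetically", {
  X <- diag(2)
  dimnames(X) <- list(c("g1", "g2"), c("c1", "c2"))
  W <- matrix(c(2, 1, 2, 1, 1, 3, 1, 3), 2, 4,
              dimnames = list(c("c1", "c2"), paste0("s", 1:4)))
  fit <- methods::new("TissueFit",
    weights = list(Matrix::Matrix(W, sparse = TRUE)), subsets = list(1:2),
    bulk = matrix(1, 2, 4, dimnames = list(c("g1", "g2"), paste0("s", 1:4))),
    library = X, cellLabels = c(c1 = "A", c2 = "B"), cellDonors = NULL,
    config = list(nRuns = 1, cellFraction = 1, seed = 1L, zeroThreshold = 0,
                  solver = "nnls", rescale = FALSE, targetSum = 1e4))
  # identical weights in both groups -> ratio 1
  mw <- meanCellWeights(fit, c("g1", "g2", "g1", "g2"))
  expect_equal(mw$cells$ratio, c(1, 1))
  # c1 weights (2,2) in group 1, (1,1) in group 2 -> ratio 2
  mw2 <- meanCellWeights(fit, c("x", "x", "y", "y"))
  expect_equal(mw2$cells$ratio[1], 2)
  expect_equal(mw2$cells$ratio[2], 1 / 3)
  expect_error(meanCellWeights(fit, rep("x", 4)), "two sample groups")
})

test_that("sub-state enrichment shows up as a weight ratio above one", {
  # group-1 bulks built only from sub-state-1 alpha cells, group 2 only from
  # sub-state-2 alpha cells; beta/gamma shared
  lib <- makeTypedLibrary(nGenes = 80, cellsPerType = 30, seed = 71,
                          noiseSd = 0.05)
  sub <- ifelse(lib$labels == "alpha",
                ifelse(seq_along(lib$labels) %% 2 == 0, "alpha_s2",
                       "alpha_s1"), lib$labels)
  # make the two sub-states distinguishable: boost 10 genes in sub-state 1
  cells <- lib$cells
  boost <- rownames(cells)[61:70]
  cells[boost, sub == "alpha_s1"] <- cells[boost, sub == "alpha_s1"] * 6
  mkBulk <- function(subState, seed) {
    set.seed(seed)
    sapply(1:4, function(b) {
      picked <- c(sample(which(sub == subState), 15),
                  sample(which(lib$labels == "beta"), 10),
                  sample(which(lib$labels == "gamma"), 5))
      rowSums(cells[, picked])
    })
  }
  bulk <- cbind(mkBulk("alpha_s1", 72), mkBulk("alpha_s2", 73))
  dimnames(bulk) <- list(rownames(cells), paste0("s", 1:8))
  fit <- bootstrapFit(bulk, cells, labels = sub, nRuns = 6,
                      cellFraction = 0.6, seed = 74)
  mw <- meanCellWeights(fit, rep(c("grp1", "grp2"), each = 4))
  lr <- mw$labelRatios
  expect_gt(lr$ratio[lr$label == "alpha_s1"], 1)
  expect_lt(lr$ratio[lr$label == "alpha_s2"], 1)
  # direct per-group NNLS fits agree on the direction
  d1 <- fitWeights(rowMeans(bulkMatrix(fit)[, 1:4]), libraryMatrix(fit),
                   solver = "nnls")
  d2 <- fitWeights(rowMeans(bulkMatrix(fit)[, 5:8]), libraryMatrix(fit),
                   solver = "nnls")
  expect_gt(sum(d1[sub == "alpha_s1"]), sum(d1[sub == "alpha_s2"]))
  expect_gt(sum(d2[sub == "alpha_s2"]), sum(d2[sub == "alpha_s1"]))
})
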