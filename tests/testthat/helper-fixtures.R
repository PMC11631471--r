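# in-code fixtures shared across test files

# small random non-negative regression instance
randomInstance <- function(nGenes, nCells, seed) {
  set.seed(seed)
  X <- matrix(rexp(nGenes * nCells), nGenes, nCells,
              dimnames = list(sprintf("g%03d", seq_len(nGenes)),
                              sprintf("c%03d", seq_len(nCells))))
  y <- rexp(nGenes)
  names(y) <- rownames(X)
  list(X = X, y = y)
}

objectiveNorm <- function(y, X, beta) sqrt(sum((y - X %*% beta)^2))

# well-separated 3-type library: shared baseline plus strong disjoint marker
# blocks; every cell scaled to a common total so that mixture proportions of
# summed cells translate directly into weight shares
makeTypedLibrary <- function(nGenes = 90, cellsPerType = 40, seed = 5,
                             noiseSd = 0.1, targetSum = 1e4) {
  set.seed(seed)
  types <- c("alpha", "beta", "gamma")
  genes <- sprintf("g%03d", seq_len(nGenes))
  base <- rexp(nGenes, 1 / 5) + 0.5
  bs <- floor(nGenes / 4)
  block <- split(seq_len(3 * bs), rep(1:3, each = bs))
  arch <- sapply(1:3, function(t) {
    a <- base
    a[block[[t]]] <- a[block[[t]]] * 10
    a
  })
  dimnames(arch) <- list(genes, types)
  cells <- do.call(cbind, lapply(types, function(tp) {
    m <- arch[, tp] * matrix(rlnorm(nGenes * cellsPerType, 0, noiseSd),
                             nGenes, cellsPerType)
    m
  }))
  dimnames(cells) <- list(genes, sprintf("cell_%03d", seq_len(ncol(cells))))
  cells <- sweep(cells, 2, colSums(cells) / targetSum, "/")
  list(cells = cells,
       labels = rep(types, each = cellsPerType),
       types = types,
       markerGenes = lapply(block, function(ix) genes[ix]),
       archetypes = arch)
}

# bulks as exact cell mixtures with known per-type proportions; the bulk size
# defaults to the smallest type pool so every draw fits without replacement
makeMixtureBulk <- function(lib, proportions, cellsPerBulk = NULL, seed = 9) {
  set.seed(seed)
  if (is.null(cellsPerBulk)) cellsPerBulk <- min(table(lib$labels))
  stopifnot(is.matrix(proportions))  # bulks x types
  mats <- sapply(seq_len(nrow(proportions)), function(b) {
    counts <- round(proportions[b, ] * cellsPerBulk)
    picked <- unlist(lapply(seq_along(lib$types), function(t) {
      sample(which(lib$labels == lib$types[t]), counts[t])
    }))
    rowSums(lib$cells[, picked, drop = FALSE])
  })
  dimnames(mats) <- list(rownames(lib$cells),
                         sprintf("mix_%02d", seq_len(nrow(proportions))))
  mats
}

# tiny deterministic fit used by decomposition/quality tests
smallFit <- function(nRuns = 4, seed = 21, nBulks = 5, solver = "lbfgsb") {
  lib <- makeTypedLibrary(seed = seed)
  props <- matrix(c(0.5, 0.3, 0.2,
                    0.2, 0.2, 0.6,
                    1/3, 1/3, 1/3,
                    0.7, 0.2, 0.1,
                    0.1, 0.6, 0.3), ncol = 3, byrow = TRUE)[seq_len(nBulks), ,
                                                            drop = FALSE]
  bulk <- makeMixtureBulk(lib, props, seed = seed + 1)
  fit <- bootstrapFit(bulk, lib$cells, labels = lib$labels,
                      nRuns = nRuns, cellFraction = 0.5, seed = seed + 2,
                      solver = solver)
  list(fit = fit, lib = lib, bulk = bulk, props = props)
}
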