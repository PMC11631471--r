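# internal input checking and unwrapping helpers

.checkFinite <- function(x, what) {
  if (!all(is.finite(x)))
    stop(sprintf("non-finite entries in %s", what), call. = FALSE)
  invisible(TRUE)
}

.checkNonNegative <- function(x, what) {
  if (any(x < 0))
    stop(sprintf("negative entries in %s (found %d)", what, sum(x < 0)),
         call. = FALSE)
  invisible(TRUE)
}

.checkUnique <- function(ids, what) {
  d <- unique(ids[duplicated(ids)])
  if (length(d))
    stop(sprintf("duplicate %s: %s", what,
                 paste(utils::head(d, 5), collapse = ", ")), call. = FALSE)
  invisible(TRUE)
}

# accept a matrix-like or SummarizedExperiment as bulk input
.unwrapBulk <- function(x) {
  if (methods::is(x, "SummarizedExperiment"))
    x <- SummarizedExperiment::assay(x, 1)
  x <- as.matrix(x)
  if (is.null(rownames(x)))
    stop("bulk matrix must carry gene ids as rownames", call. = FALSE)
  if (is.null(colnames(x)))
    colnames(x) <- paste0("sample_", seq_len(ncol(x)))
  storage.mode(x) <- "double"
  x
}

# accept matrix / SingleCellExperiment / SummarizedExperiment as library input;
# returns list(values, labels, donors)
.unwrapLibrary <- function(x, labels = NULL, donors = NULL) {
  if (methods::is(x, "SummarizedExperiment")) {
    cd <- SummarizedExperiment::colData(x)
    pick <- function(given, candidates) {
      if (!is.null(given)) return(given)
      hit <- intersect(candidates, colnames(cd))
      if (length(hit)) as.character(cd[[hit[1]]]) else NULL
    }
    labels <- pick(labels, c("label", "cell_type", "celltype"))
    donors <- pick(donors, c("donor", "donor_id", "sample_origin"))
    x <- SummarizedExperiment::assay(x, 1)
  }
  x <- as.matrix(x)
  if (is.null(rownames(x)))
    stop("library matrix must carry gene ids as rownames", call. = FALSE)
  if (is.null(colnames(x)))
    colnames(x) <- paste0("cell_", seq_len(ncol(x)))
  storage.mode(x) <- "double"
  if (!is.null(labels)) {
    labels <- as.character(labels)
    if (length(labels) != ncol(x))
      stop("labels must have one entry per cell", call. = FALSE)
    names(labels) <- colnames(x)
  }
  if (!is.null(donors)) {
    donors <- as.character(donors)
    if (length(donors) != ncol(x))
      stop("donors must have one entry per cell", call. = FALSE)
    names(donors) <- colnames(x)
  }
  list(values = x, labels = labels, donors = donors)
}

# evaluate expr with a temporary RNG state seeded by `seed`, restoring the
# caller's stream afterwards
.withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(expr)
}

.rowVar <- function(m) {
  n <- ncol(m)
  if (n < 2) return(rep(NA_real_, nrow(m)))
  mu <- rowMeans(m)
  rowSums((m - mu)^2) / (n - 1)
}
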