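#' @importFrom methods as is
#' @importFrom stats as.dist cor cutree dist hclust kmeans p.adjust pnorm
#'   prcomp quantile rbinom rlnorm rnbinom runif sd setNames var wilcox.test
#' @importFrom utils head read.delim write.csv write.table
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

.assert <- function(ok, msg, field = NULL) {
  if (!isTRUE(ok)) {
    if (!is.null(field)) msg <- sprintf("[%s] %s", field, msg)
    stop(msg, call. = FALSE)
  }
  invisible(TRUE)
}

# Coerce any matrix-like input to a sparse dgCMatrix, cells in rows.
.as_sparse <- function(x) {
  if (is(x, "dgCMatrix")) return(x)
  if (is.matrix(x)) x <- Matrix::Matrix(x, sparse = TRUE)
  as(as(as(x, "dMatrix"), "generalMatrix"), "CsparseMatrix")
}

.check_counts <- function(counts) {
  .assert(!is.null(rownames(counts)), "count matrix must have cell barcodes as rownames")
  .assert(!is.null(colnames(counts)), "count matrix must have gene ids as colnames")
  .assert(!anyDuplicated(rownames(counts)), "cell barcodes must be unique")
  invisible(TRUE)
}

# Exact PCA via an eigendecomposition of the gene-gene covariance; fully
# deterministic (no randomized solver), so clustering is reproducible and
# invariant to gene order up to component sign flips, which distances ignore.
.pca_scores <- function(x, n_pcs, scale. = TRUE) {
  x <- as.matrix(x)
  mu <- colMeans(x)
  xc <- sweep(x, 2L, mu, "-")
  if (scale.) {
    sds <- apply(xc, 2L, sd)
    keep <- sds > 1e-12
    xc <- sweep(xc[, keep, drop = FALSE], 2L, sds[keep], "/")
  }
  n_pcs <- min(n_pcs, nrow(xc) - 1L, ncol(xc))
  cv <- crossprod(xc) / max(1L, nrow(xc) - 1L)
  ev <- eigen(cv, symmetric = TRUE)
  xc %*% ev$vectors[, seq_len(n_pcs), drop = FALSE]
}

# Row-wise running mean along columns with symmetric truncation at the ends:
# position i averages over [i-h, i+h] with h = min(half, i-1, n-i).
.running_mean <- function(x, window) {
  n <- ncol(x)
  half <- (window - 1L) %/% 2L
  cs <- cbind(0, t(apply(x, 1L, cumsum)))
  out <- x
  for (i in seq_len(n)) {
    h <- min(half, i - 1L, n - i)
    out[, i] <- (cs[, i + h + 1L] - cs[, i - h]) / (2L * h + 1L)
  }
  out
}
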