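#' Quality-control thresholds
#'
#' Defaults follow common 10x practice for tumor cohorts: drop cells with
#' fewer than 200 detected genes, the top 2% of cells by detected genes and
#' by total UMIs (a doublet surrogate, computed per sample), and cells with
#' more than 50% mitochondrial content.
#'
#' @param min_genes minimum detected genes per cell.
#' @param top_gene_fraction,top_umi_fraction fraction of cells removed from
#'   the top of the per-sample gene-count / UMI-count distributions.
#' @param max_mito_fraction maximum mitochondrial fraction.
#' @param min_cells_per_gene_for_cnv minimum expressing cells per gene used
#'   later by [infer_cnv()].
#' @return list of class `qc_thresholds`.
#' @export
qc_thresholds <- function(min_genes = 200, top_gene_fraction = 0.02,
                          top_umi_fraction = 0.02, max_mito_fraction = 0.5,
                          min_cells_per_gene_for_cnv = 20) {
  .assert(top_gene_fraction > 0 && top_gene_fraction < 1, "fraction in (0,1)",
          "top_gene_fraction")
  .assert(top_umi_fraction > 0 && top_umi_fraction < 1, "fraction in (0,1)",
          "top_umi_fraction")
  .assert(max_mito_fraction > 0 && max_mito_fraction < 1, "fraction in (0,1)",
          "max_mito_fraction")
  .assert(min_genes >= 0, "must be >= 0", "min_genes")
  structure(list(min_genes = min_genes,
                 top_gene_fraction = top_gene_fraction,
                 top_umi_fraction = top_umi_fraction,
                 max_mito_fraction = max_mito_fraction,
                 min_cells_per_gene_for_cnv = min_cells_per_gene_for_cnv),
            class = "qc_thresholds")
}

# Per-sample ceiling for "remove the top `frac` of cells by x": with
# k = floor(frac * n) the ceiling is the (n-k)-th order statistic; cells
# strictly above it are removed (ties at the ceiling survive), so at most k
# cells are dropped and the rule is deterministic.
.top_ceiling <- function(x, frac) {
  n <- length(x)
  k <- floor(frac * n)
  if (k == 0L) return(Inf)
  sort(x)[n - k]
}

#' Filter cells by quality-control rules
#'
#' A cell is removed when any rule fires: fewer than `min_genes` detected
#' genes; in the top `top_gene_fraction` of its sample by detected genes; in
#' the top `top_umi_fraction` by total UMIs; or mitochondrial fraction above
#' `max_mito_fraction`. Top-fraction ceilings are computed per sample on the
#' matrix passed in; pass `ceilings` from a previous run to re-apply the
#' original thresholds (which makes the filter idempotent).
#'
#' @param counts sparse cells x genes count matrix.
#' @param sample_of_cell optional sample label per cell; a single pooled
#'   sample when `NULL`.
#' @param thresholds a [qc_thresholds()].
#' @param mito_prefix gene-symbol prefix identifying mitochondrial genes.
#' @param ceilings optional list of per-sample `gene` and `umi` ceilings, as
#'   found in the `ceilings` element of a previous result.
#' @return list with `counts` (retained cells), `annotation` (one row per
#'   input cell: n_genes, n_umis, mito_fraction, per-rule flags, qc_pass),
#'   and `ceilings`.
#' @export
qc_filter <- function(counts, sample_of_cell = NULL,
                      thresholds = qc_thresholds(), mito_prefix = "MT-",
                      ceilings = NULL) {
  counts <- .as_sparse(counts)
  if (nrow(counts) == 0L) {
    warning("empty count matrix; nothing to filter")
    return(list(counts = counts,
                annotation = data.frame(barcode = character()),
                ceilings = list()))
  }
  .check_counts(counts)
  sample_of_cell <- sample_of_cell %||% rep("all", nrow(counts))
  .assert(length(sample_of_cell) == nrow(counts),
          "sample_of_cell must match the number of cells")
  n_genes <- Matrix::rowSums(counts > 0)
  n_umis <- Matrix::rowSums(counts)
  mito <- startsWith(colnames(counts), mito_prefix)
  if (!any(mito)) {
    warning(sprintf("no gene matches mito prefix '%s'; mito_fraction set to 0",
                    mito_prefix))
    mito_frac <- rep(0, nrow(counts))
  } else {
    mito_frac <- Matrix::rowSums(counts[, mito, drop = FALSE]) / pmax(n_umis, 1)
  }
  if (is.null(ceilings)) {
    ceilings <- list(gene = tapply(n_genes, sample_of_cell, .top_ceiling,
                                   frac = thresholds$top_gene_fraction),
                     umi = tapply(n_umis, sample_of_cell, .top_ceiling,
                                  frac = thresholds$top_umi_fraction))
  }
  fail_low_genes <- as.vector(n_genes < thresholds$min_genes)
  fail_top_genes <- as.vector(n_genes > unlist(ceilings$gene)[sample_of_cell])
  fail_top_umis <- as.vector(n_umis > unlist(ceilings$umi)[sample_of_cell])
  fail_mito <- as.vector(mito_frac > thresholds$max_mito_fraction)
  qc_pass <- !(fail_low_genes | fail_top_genes | fail_top_umis | fail_mito)
  annotation <- data.frame(barcode = rownames(counts),
                           sample = sample_of_cell,
                           n_genes = as.numeric(n_genes),
                           n_umis = as.numeric(n_umis),
                           mito_fraction = as.numeric(mito_frac),
                           fail_low_genes = fail_low_genes,
                           fail_top_genes = fail_top_genes,
                           fail_top_umis = fail_top_umis,
                           fail_mito = fail_mito,
                           qc_pass = qc_pass,
                           row.names = NULL, stringsAsFactors = FALSE)
  list(counts = counts[qc_pass, , drop = FALSE], annotation = annotation,
       ceilings = ceilings)
}

#' Library-size normalization with log transform
#'
#' Scales each cell to `target_sum` total counts, then applies `log(1 + x)`.
#' All-zero cells are left as zeros with a warning.
#'
#' @param counts sparse cells x genes count matrix.
#' @param target_sum per-cell target total (default 10,000).
#' @return sparse cells x genes matrix of log-normalized expression.
#' @export
normalize_log <- function(counts, target_sum = 1e4) {
  counts <- .as_sparse(counts)
  tot <- Matrix::rowSums(counts)
  if (any(tot == 0)) warning(sum(tot == 0), " cell(s) with zero total count left as zeros")
  sf <- ifelse(tot > 0, target_sum / tot, 0)
  x <- Matrix::Diagonal(x = sf) %*% counts
  x@x <- log1p(x@x)
  dimnames(x) <- dimnames(counts)
  .as_sparse(x)
}

#' Graph-based clustering of cells
#'
#' PCA (exact, deterministic) on scaled log-normalized expression, a shared
#' nearest-neighbor graph with Jaccard weights in PC space, and Louvain
#' modularity community detection at the given resolution.
#'
#' @param norm cells x genes log-normalized matrix.
#' @param resolution modularity resolution (default 1.2).
#' @param n_pcs number of principal components.
#' @param k_neighbors neighbors per cell for the SNN graph; reduced with a
#'   warning when there are too few cells.
#' @param seed RNG seed for the community detection.
#' @return factor of cluster labels named by barcode.
#' @export
cluster_cells <- function(norm, resolution = 1.2, n_pcs = 30,
                          k_neighbors = 20, seed = 0) {
  n <- nrow(norm)
  .assert(n >= 2, "need at least 2 cells to cluster")
  if (n <= k_neighbors) {
    k_neighbors <- max(1L, n - 1L)
    warning("fewer cells than k_neighbors + 1; using k = ", k_neighbors)
  }
  scores <- .pca_scores(norm, n_pcs)
  d <- as.matrix(dist(scores))
  nn <- apply(d, 1L, function(r) order(r)[2:(k_neighbors + 1L)])
  adj <- Matrix::sparseMatrix(i = rep(seq_len(n), each = k_neighbors),
                              j = as.vector(nn), x = 1, dims = c(n, n))
  shared <- Matrix::tcrossprod(adj)          # shared neighbors
  jac <- shared
  jac@x <- jac@x / (2 * k_neighbors - jac@x) # Jaccard of neighbor sets
  both <- (adj + Matrix::t(adj)) > 0
  jac <- jac * both
  Matrix::diag(jac) <- 0
  g <- igraph::graph_from_adjacency_matrix(jac, mode = "undirected",
                                           weighted = TRUE)
  set.seed(seed)
  cl <- igraph::cluster_louvain(g, resolution = resolution)
  labels <- factor(igraph::membership(cl))
  names(labels) <- rownames(norm)
  labels
}

# Vectorized one-vs-rest Wilcoxon rank-sum tests: ranks and tie corrections
# are computed once per gene over all cells; the U statistic per cluster
# follows from in-group rank sums. The normal approximation with tie and
# continuity correction matches stats::wilcox.test(exact = FALSE).
.rank_prep <- function(xd) {
  n <- nrow(xd)
  ranks <- matrix(0, n, ncol(xd), dimnames = dimnames(xd))
  tiecor <- numeric(ncol(xd))
  for (j in seq_len(ncol(xd))) {
    ranks[, j] <- rank(xd[, j])
    ties <- tabulate(match(xd[, j], unique(xd[, j])))
    tiecor[j] <- sum(ties^3 - ties) / (n * (n - 1))
  }
  list(ranks = ranks, tiecor = tiecor, n = n)
}

.ranksum_p <- function(prep, in_group) {
  n <- prep$n; n1 <- sum(in_group); n2 <- n - n1
  u <- colSums(prep$ranks[in_group, , drop = FALSE]) - n1 * (n1 + 1) / 2
  sigma2 <- (n1 * n2 / 12) * ((n + 1) - prep$tiecor)
  z <- u - n1 * n2 / 2
  z <- (z - sign(z) * 0.5) / sqrt(pmax(sigma2, .Machine$double.eps))
  p <- 2 * pnorm(-abs(z))
  p[sigma2 <= 0] <- 1
  unname(p)
}

#' Cluster marker genes by one-vs-rest rank-sum test
#'
#' For every cluster, each gene is tested against all remaining cells with a
#' Wilcoxon rank-sum test (normal approximation with tie correction). Rows
#' are kept when the gene is detected in more than `min_pct` of the cluster's
#' cells and its natural-log fold change exceeds `min_logfc`; p-values are
#' Benjamini-Hochberg adjusted per cluster over all genes tested.
#'
#' @param norm cells x genes log-normalized matrix.
#' @param labels cluster labels per cell.
#' @param min_pct minimum detected fraction inside the cluster (default 0.10,
#'   strict `>`).
#' @param min_logfc minimum natural-log fold change (default 0.25, strict `>`).
#' @param pseudocount added to both means in the fold change.
#' @return data.frame (cluster, gene, log_fold_change, pct_in_cluster,
#'   pct_outside, p_value, adjusted_p), sorted by log fold change within
#'   cluster.
#' @export
find_markers <- function(norm, labels, min_pct = 0.10, min_logfc = 0.25,
                         pseudocount = 1e-9) {
  labels <- as.factor(labels)
  .assert(nlevels(droplevels(labels)) >= 2, "need at least 2 clusters")
  xd <- as.matrix(norm)
  prep <- .rank_prep(xd)
  out <- list()
  for (cl in levels(droplevels(labels))) {
    in_group <- labels == cl
    if (sum(in_group) < 2L) {
      warning("cluster ", cl, " has fewer than 2 cells; skipped")
      next
    }
    m_in <- colMeans(expm1(xd[in_group, , drop = FALSE]))
    m_out <- colMeans(expm1(xd[!in_group, , drop = FALSE]))
    lfc <- log((m_in + pseudocount) / (m_out + pseudocount))
    pct_in <- colMeans(xd[in_group, , drop = FALSE] > 0)
    pct_out <- colMeans(xd[!in_group, , drop = FALSE] > 0)
    p <- .ranksum_p(prep, in_group)
    adj <- p.adjust(p, method = "BH")
    keep <- pct_in > min_pct & lfc > min_logfc
    if (!any(keep)) next
    tab <- data.frame(cluster = cl, gene = colnames(xd)[keep],
                      log_fold_change = lfc[keep], pct_in_cluster = pct_in[keep],
                      pct_outside = pct_out[keep], p_value = p[keep],
                      adjusted_p = adj[keep], row.names = NULL,
                      stringsAsFactors = FALSE)
    out[[cl]] <- tab[order(-tab$log_fold_change), ]
  }
  if (!length(out))
    return(data.frame(cluster = character(), gene = character(),
                      log_fold_change = numeric(), pct_in_cluster = numeric(),
                      pct_outside = numeric(), p_value = numeric(),
                      adjusted_p = numeric(), stringsAsFactors = FALSE))
  do.call(rbind, c(out, make.row.names = FALSE))
}

#' Annotate clusters with cell types from canonical markers
#'
#' Each cluster is assigned the type whose marker list has the highest mean
#' z-scaled expression over the cluster's cells; exact ties go to the
#' lexicographically first type and are flagged. Clusters with no positive
#' marker signal are labeled `"unassigned"`.
#'
#' @param norm cells x genes log-normalized matrix.
#' @param labels cluster labels per cell.
#' @param marker_db named list: type -> character vector of marker genes.
#' @param markers optional [find_markers()] table, recorded alongside the
#'   assignment for reporting.
#' @return list with `cell_type` (per-cell character vector), and
#'   `cluster_table` (cluster, cell_type, score, tie flag).
#' @export
annotate_clusters <- function(norm, labels, marker_db, markers = NULL) {
  .assert(length(marker_db) > 0, "marker_db must be nonempty")
  labels <- as.factor(labels)
  xd <- as.matrix(norm)
  sds <- apply(xd, 2L, sd)
  z <- sweep(xd, 2L, colMeans(xd), "-")
  z[, sds > 0] <- sweep(z[, sds > 0, drop = FALSE], 2L, sds[sds > 0], "/")
  types <- sort(names(marker_db))
  rows <- lapply(levels(labels), function(cl) {
    cells <- labels == cl
    raw_any <- FALSE
    score <- vapply(types, function(ty) {
      gg <- intersect(marker_db[[ty]], colnames(xd))
      if (!length(gg)) return(-Inf)
      if (sum(xd[cells, gg, drop = FALSE]) > 0) raw_any <<- TRUE
      mean(z[cells, gg, drop = FALSE])
    }, 0)
    if (!raw_any || all(!is.finite(score)))
      return(data.frame(cluster = cl, cell_type = "unassigned", score = NA_real_,
                        tie = FALSE, stringsAsFactors = FALSE))
    best <- max(score)
    winners <- types[score == best]
    data.frame(cluster = cl, cell_type = winners[1L], score = best,
               tie = length(winners) > 1L, stringsAsFactors = FALSE)
  })
  cluster_table <- do.call(rbind, rows)
  cell_type <- cluster_table$cell_type[match(labels, cluster_table$cluster)]
  names(cell_type) <- rownames(norm)
  list(cell_type = cell_type, cluster_table = cluster_table, markers = markers)
}
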