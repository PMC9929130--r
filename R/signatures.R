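#' Gene-set module score with bin-matched control genes
#'
#' The score of a cell is the mean log-normalized expression of the set's
#' genes minus the mean over control genes drawn from the same
#' expression-magnitude bins: genes are binned by their average expression
#' across cells into `n_bins` equal-size bins and `n_ctrl` controls are
#' sampled (with replacement) from the bin of each set gene. A random gene
#' set therefore scores 0 in expectation.
#'
#' @param norm cells x genes log-normalized matrix.
#' @param genes character vector of set genes (those absent from the matrix
#'   are dropped; fewer than 3 remaining triggers a warning).
#' @param n_bins number of expression bins (default 25).
#' @param n_ctrl control genes sampled per set gene (default 100).
#' @param seed RNG seed for control sampling.
#' @param control_genes optional explicit control set, bypassing bin
#'   sampling (a set used as its own control scores exactly 0).
#' @return named numeric vector of per-cell scores.
#' @export
module_score <- function(norm, genes, n_bins = 25, n_ctrl = 100, seed = 0,
                         control_genes = NULL) {
  genes <- intersect(genes, colnames(norm))
  .assert(length(genes) > 0, "no set gene present in the matrix")
  if (length(genes) < 3) warning("gene set has fewer than 3 genes in the matrix")
  .assert(ncol(norm) >= n_bins, "need at least n_bins genes in the matrix")
  set_mean <- Matrix::rowMeans(norm[, genes, drop = FALSE])
  if (is.null(control_genes)) {
    avg <- Matrix::colMeans(norm)
    bins <- ceiling(rank(avg, ties.method = "first") / (length(avg) / n_bins))
    set.seed(seed)
    control_genes <- unlist(lapply(genes, function(g) {
      pool <- colnames(norm)[bins == bins[[match(g, colnames(norm))]]]
      sample(pool, n_ctrl, replace = TRUE)
    }))
  }
  ctrl_mean <- Matrix::rowMeans(norm[, control_genes, drop = FALSE])
  out <- set_mean - ctrl_mean
  names(out) <- rownames(norm)
  out
}

#' Assign cell-cycle phase from S and G2M scores
#'
#' Cells whose S and G2M module scores are both non-positive are G1
#' (noncycling); otherwise the larger score decides the phase. An exact
#' positive tie is called S and flagged. S and G2M are cycling states.
#'
#' @param s_score,g2m_score per-cell module scores of the S-phase and G2M
#'   gene sets.
#' @return data.frame (barcode, s_score, g2m_score, phase, cycling, tie).
#' @export
assign_phase <- function(s_score, g2m_score) {
  .assert(length(s_score) == length(g2m_score),
          "score vectors must have equal length")
  phase <- ifelse(pmax(s_score, g2m_score) <= 0, "G1",
                  ifelse(s_score >= g2m_score, "S", "G2M"))
  tie <- s_score == g2m_score & s_score > 0
  data.frame(barcode = names(s_score) %||% as.character(seq_along(s_score)),
             s_score = as.numeric(s_score), g2m_score = as.numeric(g2m_score),
             phase = phase, cycling = phase != "G1", tie = tie,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Per-cell expression entropy with bootstrap uncertainty
#'
#' Shannon entropy of each cell's expression profile after excluding
#' ribosomal and spike-in genes: with p_g the cell's expression fraction of
#' gene g, entropy is -sum(p_g log p_g) over expressed genes, in nats. High
#' entropy (a flat profile) is read as transcriptional promiscuity, a
#' stemness surrogate; the bootstrap resamples genes to attach a standard
#' deviation.
#'
#' @param norm cells x genes log-normalized matrix.
#' @param exclude_prefixes gene-symbol prefixes to drop before scoring.
#' @param n_boot bootstrap replicates over genes (0 disables).
#' @param seed RNG seed for the bootstrap.
#' @return data.frame (barcode, entropy, entropy_sd, zero_total flag).
#' @export
expression_entropy <- function(norm, exclude_prefixes = c("RPL", "RPS", "ERCC"),
                               n_boot = 100, seed = 0) {
  drop <- Reduce(`|`, lapply(exclude_prefixes, startsWith, x = colnames(norm)))
  x <- as.matrix(norm[, !drop, drop = FALSE])
  .assert(ncol(x) >= 2, "need at least 2 genes after exclusion")
  ent_of <- function(m) {
    tot <- rowSums(m)
    p <- m / ifelse(tot > 0, tot, 1)
    lp <- ifelse(p > 0, log(p), 0)
    -rowSums(p * lp)
  }
  entropy <- ent_of(x)
  entropy_sd <- rep(NA_real_, nrow(x))
  if (n_boot > 0) {
    set.seed(seed)
    boots <- matrix(0, nrow(x), n_boot)
    for (b in seq_len(n_boot))
      boots[, b] <- ent_of(x[, sample(ncol(x), replace = TRUE), drop = FALSE])
    entropy_sd <- apply(boots, 1L, sd)
  }
  data.frame(barcode = rownames(x), entropy = as.numeric(entropy),
             entropy_sd = entropy_sd, zero_total = rowSums(x) == 0,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Dot-plot statistics per cluster and gene
#'
#' For every cluster and gene: the fraction of cells with expression above
#' zero and the cluster mean expression, plus the mean z-scaled across
#' clusters per gene (the usual dot-plot color). A per-cluster ranking of
#' the requested genes by mean expression is included so statements like
#' "gene A exceeds gene B in cluster X" are machine-checkable.
#'
#' @param norm cells x genes log-normalized matrix.
#' @param labels cluster labels per cell.
#' @param genes genes to tabulate; missing genes yield NA rows with a warning.
#' @return list with `stats` (cluster, gene, mean_expression, scaled_mean,
#'   fraction_expressing) and `ranking` (cluster, rank, gene).
#' @export
dotplot_stats <- function(norm, labels, genes) {
  labels <- as.factor(labels)
  missing <- setdiff(genes, colnames(norm))
  if (length(missing))
    warning("genes absent from the matrix: ", paste(missing, collapse = ", "))
  present <- intersect(genes, colnames(norm))
  rows <- list()
  mean_mat <- matrix(NA_real_, nlevels(labels), length(genes),
                     dimnames = list(levels(labels), genes))
  for (cl in levels(labels)) {
    cells <- labels == cl
    for (g in genes) {
      if (g %in% present) {
        v <- norm[cells, g]
        mean_mat[cl, g] <- mean(v)
        frac <- mean(v > 0)
      } else frac <- NA_real_
      rows[[length(rows) + 1L]] <- data.frame(
        cluster = cl, gene = g, mean_expression = mean_mat[cl, g],
        fraction_expressing = frac, stringsAsFactors = FALSE)
    }
  }
  stats <- do.call(rbind, rows)
  scaled <- scale(mean_mat)  # z per gene across clusters
  stats$scaled_mean <- mapply(function(cl, g) scaled[cl, g],
                              stats$cluster, stats$gene)
  ranking <- do.call(rbind, lapply(levels(labels), function(cl) {
    m <- mean_mat[cl, present]
    ord <- order(-m)
    data.frame(cluster = cl, rank = seq_along(ord), gene = present[ord],
               mean_expression = as.numeric(m[ord]), stringsAsFactors = FALSE)
  }))
  list(stats = stats[, c("cluster", "gene", "mean_expression", "scaled_mean",
                         "fraction_expressing")],
       ranking = ranking)
}
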