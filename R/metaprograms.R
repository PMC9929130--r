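#' Extract per-sample expression modules from malignant cells
#'
#' Within each sample, malignant cells are subclustered with the same graph
#' engine used for the global clustering; every subcluster becomes an
#' expression module whose signature is its top 100 genes by log fold change
#' from [find_markers()] (for a sample collapsing to a single subcluster,
#' the top 100 genes by mean expression). Each module's score over all
#' malignant cells of the cohort is its signature's bin-matched
#' [module_score()], which downstream meta-clustering correlates.
#'
#' @param norm cells x genes log-normalized matrix (whole cohort).
#' @param sample_of_cell named sample label per cell.
#' @param malignant named logical per cell (e.g. from [call_malignant()]).
#' @param resolution subclustering resolution.
#' @param modules_per_sample optional fixed subcluster count per sample;
#'   when given, k-means on PC scores replaces graph clustering.
#' @param min_cells samples with fewer malignant cells are skipped.
#' @param top_n signature size (default 100).
#' @param n_pcs,k_neighbors passed to [cluster_cells()].
#' @param seed RNG seed.
#' @return list of modules, each with `module_id`, `sample`,
#'   `signature_genes`, and `score` (named vector over all malignant cells).
#' @export
extract_modules <- function(norm, sample_of_cell, malignant, resolution = 1.2,
                            modules_per_sample = NULL, min_cells = 50,
                            top_n = 100, n_pcs = 20, k_neighbors = 15,
                            seed = 0) {
  samples <- unique(sample_of_cell)
  .assert(length(samples) >= 2, "need at least 2 samples")
  cancer <- rownames(norm)[malignant[rownames(norm)]]
  norm_cancer <- norm[cancer, , drop = FALSE]
  modules <- list()
  for (si in seq_along(samples)) {
    s <- samples[si]
    cells <- cancer[sample_of_cell[cancer] == s]
    if (length(cells) < min_cells) {
      warning("sample ", s, " has ", length(cells),
              " malignant cells (< ", min_cells, "); skipped")
      next
    }
    sub <- norm[cells, , drop = FALSE]
    if (is.null(modules_per_sample)) {
      labels <- cluster_cells(sub, resolution = resolution, n_pcs = n_pcs,
                              k_neighbors = k_neighbors, seed = seed + si)
    } else {
      set.seed(seed + si)
      km <- kmeans(.pca_scores(sub, n_pcs), centers = modules_per_sample,
                   nstart = 10)
      labels <- factor(km$cluster)
      names(labels) <- cells
    }
    sigs <- list()
    if (nlevels(droplevels(labels)) >= 2) {
      mk <- find_markers(sub, labels)
      for (cl in unique(mk$cluster))
        sigs[[cl]] <- head(mk$gene[mk$cluster == cl], top_n)
    } else {
      sigs[["1"]] <- names(sort(Matrix::colMeans(sub), decreasing = TRUE))[seq_len(top_n)]
    }
    for (k in seq_along(sigs)) {
      if (!length(sigs[[k]])) next
      mid <- sprintf("%s_m%d", s, k)
      modules[[mid]] <- list(
        module_id = mid, sample = s, signature_genes = sigs[[k]],
        score = module_score(norm_cancer, sigs[[k]], seed = seed + 1000L + si))
    }
  }
  modules
}

#' Aggregate modules into recurrent meta-programs
#'
#' Pairwise Pearson correlation of module score vectors over all malignant
#' cells, average-linkage hierarchical clustering of 1 - r, and a cut at
#' `correlation_cut` define the meta-programs. A program's consensus genes
#' are the genes present in more than half of its member modules'
#' signatures, padded to at least `min_consensus` genes by membership
#' frequency; programs whose members span at least two samples are flagged
#' recurrent.
#'
#' @param modules result of [extract_modules()].
#' @param correlation_cut correlation at which the dendrogram is cut
#'   (default r = 0.3; modules merging below it stay separate).
#' @param min_consensus minimum consensus-gene count (default 10).
#' @return list of meta-programs, each with `program_id`, `member_modules`,
#'   `samples`, `recurrent`, `consensus_genes`.
#' @export
aggregate_modules <- function(modules, correlation_cut = 0.3,
                              min_consensus = 10) {
  .assert(length(modules) >= 2, "need at least 2 modules")
  scores <- do.call(cbind, lapply(modules, `[[`, "score"))
  r <- cor(scores)
  if (all(r[upper.tri(r)] < correlation_cut))
    warning("no module pair correlated above the cut; every module its own program")
  hc <- hclust(as.dist(1 - r), method = "average")
  grp <- cutree(hc, h = 1 - correlation_cut)
  lapply(seq_len(max(grp)), function(g) {
    members <- modules[grp == g]
    sigs <- lapply(members, `[[`, "signature_genes")
    freq <- table(unlist(sigs))
    consensus <- names(freq)[freq > length(members) / 2]
    if (length(consensus) < min_consensus) {
      ord <- names(freq)[order(-as.numeric(freq), names(freq))]
      consensus <- head(ord, min_consensus)
    }
    samples <- unique(vapply(members, `[[`, "", "sample"))
    list(program_id = sprintf("MP%d", g),
         member_modules = vapply(members, `[[`, "", "module_id"),
         samples = samples,
         recurrent = length(samples) >= 2,
         consensus_genes = sort(consensus))
  })
}

#' Assign program cells by the 70% expression rule
#'
#' A gene counts as expressed in a cell when its log-normalized value is
#' above zero; a cell is a program cell when it expresses strictly more than
#' `threshold` (default 0.70) of the program's consensus genes present in
#' the matrix. The per-sample program score is the exact proportion of
#' program cells.
#'
#' @param norm cells x genes log-normalized matrix (typically malignant
#'   cells only).
#' @param programs result of [aggregate_modules()] (or any list with
#'   `program_id` and `consensus_genes`).
#' @param sample_of_cell named sample label per cell.
#' @param threshold expressed-gene fraction that must be exceeded.
#' @return list with `assignment` (logical cells x programs matrix) and
#'   `program_score` (data.frame sample, program, n_cells, n_program_cells,
#'   program_score).
#' @export
assign_program_cells <- function(norm, programs, sample_of_cell,
                                 threshold = 0.70) {
  ids <- vapply(programs, `[[`, "", "program_id")
  assignment <- matrix(FALSE, nrow(norm), length(programs),
                       dimnames = list(rownames(norm), ids))
  for (p in programs) {
    genes <- intersect(p$consensus_genes, colnames(norm))
    .assert(length(genes) > 0,
            sprintf("program %s has no consensus gene in the matrix",
                    p$program_id))
    frac <- Matrix::rowMeans(norm[, genes, drop = FALSE] > 0)
    assignment[, p$program_id] <- frac > threshold
  }
  samples <- sort(unique(sample_of_cell[rownames(norm)]))
  rows <- list()
  for (s in samples) {
    cells <- rownames(norm)[sample_of_cell[rownames(norm)] == s]
    for (p in ids) {
      k <- sum(assignment[cells, p])
      rows[[length(rows) + 1L]] <- data.frame(
        sample = s, program = p, n_cells = length(cells),
        n_program_cells = k, program_score = k / length(cells),
        stringsAsFactors = FALSE)
    }
  }
  list(assignment = assignment, program_score = do.call(rbind, rows))
}

#' Pairwise program dependency log-odds
#'
#' For every program pair the 2x2 table of joint program-cell membership is
#' formed over all cells, 0.5 is added to each cell (Haldane-Anscombe), and
#' the natural-log odds ratio ln((a+.5)(d+.5)/((b+.5)(c+.5))) is reported.
#' Pairs above `cut` are classified co-occurring, below `-cut` exclusive,
#' otherwise neither.
#'
#' @param assignment logical cells x programs matrix from
#'   [assign_program_cells()].
#' @param cut classification threshold on the log-odds scale (default 0.1).
#' @return list with `log_odds` (symmetric matrix, NA diagonal),
#'   `classification` (character matrix), and `low_information` (programs
#'   assigned to no or all cells).
#' @export
dependency_log_odds <- function(assignment, cut = 0.1) {
  .assert(ncol(assignment) >= 2, "need at least 2 programs")
  ids <- colnames(assignment)
  lo <- matrix(NA_real_, length(ids), length(ids), dimnames = list(ids, ids))
  for (i in seq_along(ids)) for (j in seq_along(ids)) {
    if (j <= i) next
    p <- assignment[, i]; q <- assignment[, j]
    a <- sum(p & q); b <- sum(p & !q); c <- sum(!p & q); d <- sum(!p & !q)
    v <- log(((a + 0.5) * (d + 0.5)) / ((b + 0.5) * (c + 0.5)))
    lo[i, j] <- v; lo[j, i] <- v
  }
  classification <- ifelse(lo > cut, "cooccurring",
                           ifelse(lo < -cut, "exclusive", "neither"))
  marg <- colSums(assignment)
  low_info <- ids[marg == 0 | marg == nrow(assignment)]
  if (length(low_info))
    warning("program(s) with no or all cells assigned: ",
            paste(low_info, collapse = ", "))
  list(log_odds = lo, classification = classification,
       low_information = low_info)
}

#' Contrast program cells against nonprogram cells on gene sets
#'
#' For each program and gene set: the difference in mean [module_score()]
#' between program and nonprogram cells, a rank-sum p-value, and a BH
#' adjustment over the whole table. A column-wise z-scaled copy of the
#' effect matrix is returned for display.
#'
#' @param norm cells x genes log-normalized matrix.
#' @param assignment logical cells x programs matrix.
#' @param gene_sets named list of gene sets (e.g. hallmark-style).
#' @param seed seed for the control-gene sampling of the set scores.
#' @return list with `table` (program, gene_set, effect, p_value,
#'   adjusted_p) and `z_effect` (programs x sets matrix, z per column).
#' @export
contrast_program_cells <- function(norm, assignment, gene_sets, seed = 0) {
  set_scores <- list()
  for (nm in names(gene_sets)) {
    genes <- intersect(gene_sets[[nm]], colnames(norm))
    if (!length(genes)) {
      warning("gene set ", nm, " has no gene in the matrix; skipped")
      next
    }
    set_scores[[nm]] <- module_score(norm, genes, seed = seed)
  }
  rows <- list()
  for (p in colnames(assignment)) {
    inp <- assignment[, p]
    for (nm in names(set_scores)) {
      sc <- set_scores[[nm]]
      if (!any(inp) || all(inp)) {
        rows[[length(rows) + 1L]] <- data.frame(
          program = p, gene_set = nm, effect = NA_real_, p_value = NA_real_,
          stringsAsFactors = FALSE)
        next
      }
      eff <- mean(sc[inp]) - mean(sc[!inp])
      pv <- stats::wilcox.test(sc[inp], sc[!inp], exact = FALSE)$p.value
      rows[[length(rows) + 1L]] <- data.frame(
        program = p, gene_set = nm, effect = eff, p_value = pv,
        stringsAsFactors = FALSE)
    }
  }
  tab <- do.call(rbind, rows)
  tab$adjusted_p <- p.adjust(tab$p_value, method = "BH")
  z <- NULL
  if (!is.null(tab)) {
    em <- matrix(NA_real_, ncol(assignment), length(set_scores),
                 dimnames = list(colnames(assignment), names(set_scores)))
    for (r in seq_len(nrow(tab)))
      em[tab$program[r], tab$gene_set[r]] <- tab$effect[r]
    z <- scale(em)
  }
  list(table = tab, z_effect = z)
}
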