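#' Permutation test for ligand-receptor interactions between cell types
#'
#' For every ligand-receptor pair and every ordered (sender, receiver) type
#' pair, the observed statistic is the average of the ligand's mean
#' log-normalized expression in the sender type and the receptor's mean in
#' the receiver type. The null distribution is built by permuting the
#' type-of-cell labels `n_perm` times and recomputing the statistic; the
#' p-value uses the permutation-inclusive estimator
#' p = (1 + #\{null >= observed\}) / (n_perm + 1), so p >= 1/(n_perm + 1)
#' and zero p-values cannot occur. A result is significant when the
#' statistic exceeds `expr_cut` and p < `alpha`.
#'
#' A (pair, sender, receiver) combination is only tested when the ligand is
#' detected in more than `min_expr_frac` of sender cells and the receptor in
#' more than `min_expr_frac` of receiver cells; untested combinations are
#' reported with `tested = FALSE`. Types with fewer than `min_cells` cells
#' are reported as NA. Pairs whose genes are absent are skipped with a
#' warning.
#'
#' @param norm cells x genes log-normalized matrix.
#' @param type_of_cell named cell-type label per cell.
#' @param db data.frame with columns `pair_id`, `ligand`, `receptor`.
#' @param n_perm number of label permutations (default 1000).
#' @param seed RNG seed.
#' @param min_cells minimum cells per type (default 10).
#' @param min_expr_frac detection fraction required in sender/receiver.
#' @param expr_cut,alpha significance rule: mean statistic > `expr_cut`
#'   (default 0.1) and p < `alpha` (default 0.05).
#' @param stat `"mean"` (default) or `"min"` of the two type means.
#' @param include_self whether to test sender == receiver combinations.
#' @return data.frame with one row per (pair, sender, receiver): `mean_stat`,
#'   `p_value`, `tested`, `significant`.
#' @export
interaction_test <- function(norm, type_of_cell, db, n_perm = 1000, seed = 0,
                             min_cells = 10, min_expr_frac = 0.10,
                             expr_cut = 0.1, alpha = 0.05,
                             stat = c("mean", "min"), include_self = FALSE) {
  stat <- match.arg(stat)
  .assert(n_perm >= 1, "n_perm must be at least 1")
  type_of_cell <- type_of_cell[rownames(norm)]
  types <- sort(unique(as.character(type_of_cell)))
  .assert(length(types) >= 2, "need at least 2 cell types")
  missing <- !(db$ligand %in% colnames(norm)) | !(db$receptor %in% colnames(norm))
  if (any(missing)) {
    warning("skipping pair(s) with absent genes: ",
            paste(db$pair_id[missing], collapse = ", "))
    db <- db[!missing, , drop = FALSE]
  }
  genes <- unique(c(db$ligand, db$receptor))
  x <- as.matrix(norm[, genes, drop = FALSE])
  n_type <- table(type_of_cell)[types]
  type_ok <- n_type >= min_cells

  type_means <- function(labels) {
    rowsum(x, labels)[types, , drop = FALSE] / as.vector(n_type)
  }
  detect_frac <- rowsum((x > 0) * 1, type_of_cell)[types, , drop = FALSE] /
    as.vector(n_type)
  obs_means <- type_means(type_of_cell)

  combos <- expand.grid(sender = types, receiver = types,
                        stringsAsFactors = FALSE)
  if (!include_self) combos <- combos[combos$sender != combos$receiver, ]
  res <- merge(db, combos, by = NULL)
  pair_stat <- function(tm) {
    lig <- tm[cbind(res$sender, res$ligand)]
    rec <- tm[cbind(res$receiver, res$receptor)]
    if (stat == "mean") (lig + rec) / 2 else pmin(lig, rec)
  }
  res$mean_stat <- pair_stat(obs_means)
  res$tested <- detect_frac[cbind(res$sender, res$ligand)] > min_expr_frac &
    detect_frac[cbind(res$receiver, res$receptor)] > min_expr_frac

  set.seed(seed)
  exceed <- numeric(nrow(res))
  labels <- as.character(type_of_cell)
  for (b in seq_len(n_perm)) {
    perm <- sample(labels)
    exceed <- exceed + (pair_stat(type_means(perm)) >= res$mean_stat)
  }
  res$p_value <- (1 + exceed) / (n_perm + 1)

  na_combo <- !type_ok[res$sender] | !type_ok[res$receiver]
  res$mean_stat[na_combo] <- NA_real_
  res$p_value[na_combo] <- NA_real_
  res$tested[na_combo] <- FALSE
  res$significant <- res$tested & !is.na(res$p_value) &
    res$mean_stat > expr_cut & res$p_value < alpha
  rownames(res) <- NULL
  res[, c("pair_id", "ligand", "receptor", "sender", "receiver",
          "mean_stat", "p_value", "tested", "significant")]
}

#' Count significant interactions between type pairs
#'
#' @param results an [interaction_test()] table.
#' @param symmetrize when `TRUE`, return the symmetrized matrix
#'   counts(s, r) + counts(r, s).
#' @return types x types integer matrix of significant-pair counts.
#' @export
interaction_counts <- function(results, symmetrize = FALSE) {
  types <- sort(unique(c(results$sender, results$receiver)))
  m <- matrix(0L, length(types), length(types), dimnames = list(types, types))
  sig <- results[results$significant, , drop = FALSE]
  for (r in seq_len(nrow(sig)))
    m[sig$sender[r], sig$receiver[r]] <- m[sig$sender[r], sig$receiver[r]] + 1L
  if (symmetrize) m <- m + t(m)
  m
}
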