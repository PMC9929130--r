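# Independent oracles and fixture builders shared across tests. These
# deliberately re-derive results with naive, loop-based code so the package
# implementation is checked against a second route, not against itself.

# Adjusted Rand index between two partitions (direct pair-counting formula).
ari <- function(a, b) {
  tab <- table(a, b)
  n <- sum(tab)
  sum_ij <- sum(choose(tab, 2))
  sum_i <- sum(choose(rowSums(tab), 2))
  sum_j <- sum(choose(colSums(tab), 2))
  expected <- sum_i * sum_j / choose(n, 2)
  max_idx <- (sum_i + sum_j) / 2
  if (max_idx == expected) return(1)
  (sum_ij - expected) / (max_idx - expected)
}

# Naive copy-number smoothing pipeline: explicit loops over genes and window
# positions, no cumulative sums, mirroring the documented contract of
# infer_cnv step by step.
naive_cnv <- function(norm, gene_positions, reference_cells, window = 101,
                      clip_sd = 1.5, min_cells = 20) {
  x_all <- as.matrix(norm)
  n_expr <- colSums(x_all > 0)
  keep <- colnames(x_all)[n_expr > min_cells]
  keep <- keep[keep %in% gene_positions$gene]
  gp <- gene_positions[match(keep, gene_positions$gene), ]
  gp <- gp[order(match(gp$chrom, unique(gene_positions$chrom)), gp$start), ]
  x <- x_all[, gp$gene, drop = FALSE]
  for (j in seq_len(ncol(x))) {
    x[, j] <- x[, j] - mean(x[, j])
    bound <- clip_sd * sd(x[, j])
    x[, j] <- pmin(pmax(x[, j], -bound), bound)
  }
  out <- x
  for (ch in unique(gp$chrom)) {
    cols <- which(gp$chrom == ch)
    n <- length(cols)
    w <- if (n < window) n - (1 - n %% 2) else window
    half <- (w - 1) %/% 2
    for (k in seq_len(n)) {
      h <- min(half, k - 1, n - k)
      span <- cols[(k - h):(k + h)]
      out[, cols[k]] <- rowMeans(x[, span, drop = FALSE])
    }
  }
  ref <- colMeans(out[reference_cells, , drop = FALSE])
  sweep(out, 2, ref, "-")
}

# Hand application of the four QC rules on raw per-cell summaries, written
# as the literal prose of the rules (sort, take the top floor(frac*n), etc.).
enumerate_qc <- function(n_genes, n_umis, mito_frac, sample_of_cell,
                         min_genes = 200, top_frac = 0.02, max_mito = 0.5) {
  removed <- n_genes < min_genes
  for (s in unique(sample_of_cell)) {
    idx <- which(sample_of_cell == s)
    k <- floor(top_frac * length(idx))
    if (k > 0) {
      ceil_g <- sort(n_genes[idx])[length(idx) - k]
      ceil_u <- sort(n_umis[idx])[length(idx) - k]
      removed[idx] <- removed[idx] | n_genes[idx] > ceil_g | n_umis[idx] > ceil_u
    }
  }
  removed | mito_frac > max_mito
}

# A 100-cell scripted QC fixture with known per-cell summaries, including
# boundary cells at exactly 200 genes and exactly 50% mitochondrial content.
make_qc_fixture <- function() {
  n_cells <- 100
  n_reg <- 290
  genes <- c(sprintf("MT-%02d", 1:10), sprintf("R%03d", seq_len(n_reg)))
  set.seed(42)
  spec <- data.frame(
    n_genes = pmin(sample(150:280, n_cells, replace = TRUE), n_reg),
    mito_frac = sample(c(0, 0.1, 0.2, 0.4), n_cells, replace = TRUE))
  # scripted boundary and extreme cells
  spec$n_genes[1] <- 199;  spec$mito_frac[1] <- 0     # below the gene floor
  spec$n_genes[2] <- 200;  spec$mito_frac[2] <- 0     # at the floor: kept
  spec$n_genes[3] <- 290;  spec$mito_frac[3] <- 0     # top by genes
  spec$n_genes[4] <- 289;  spec$mito_frac[4] <- 0
  spec$n_genes[5] <- 240;  spec$mito_frac[5] <- 0.5   # at the mito bound: kept
  spec$n_genes[6] <- 240;  spec$mito_frac[6] <- 0.51  # just above: removed
  counts <- matrix(0L, n_cells, length(genes),
                   dimnames = list(sprintf("cell%03d", seq_len(n_cells)), genes))
  for (i in seq_len(n_cells)) {
    g <- spec$n_genes[i]
    counts[i, 10 + seq_len(g)] <- 1L
    # pad UMIs so totals vary, then add mitochondrial counts at the target
    extra <- (i %% 7) * 10L
    counts[i, 11] <- counts[i, 11] + extra
    non_mito <- sum(counts[i, -(1:10)])
    m <- spec$mito_frac[i]
    if (m > 0) counts[i, 1] <- as.integer(round(m / (1 - m) * non_mito))
  }
  counts[7, 11] <- counts[7, 11] + 5000L  # top by UMIs
  counts[8, 12] <- counts[8, 12] + 4000L
  list(counts = metaniche:::.as_sparse(counts),
       sample = rep("s1", n_cells))
}

# Program truth builder: gene sets drawn from genes of moderate baseline
# expression, so activation moves detection across the 70% program-cell rule.
make_program_truth <- function(cfg_seedonly, n_programs, genes_per_program = 50,
                               pick_seed = 99) {
  bl <- sim_gene_baselines(cfg_seedonly)
  bl <- bl[!startsWith(names(bl), "MT-")]
  # genes of moderate baseline (centered near 1.1), so activation moves
  # detection across the 70% program-cell threshold
  cand <- names(sort(abs(log(bl / 1.1))))[seq_len(n_programs * genes_per_program)]
  set.seed(pick_seed)
  split(sample(cand), rep(seq_len(n_programs), each = genes_per_program))
}

new_program <- function(id, genes, fold, frac) {
  list(program_id = id, genes = genes, activation_fold = fold,
       active_fraction = frac)
}

jaccard <- function(a, b) length(intersect(a, b)) / length(union(a, b))

# Haldane-Anscombe-corrected log odds ratio from an explicit 2x2 table.
hand_log_or <- function(a, b, c, d) {
  log(((a + 0.5) * (d + 0.5)) / ((b + 0.5) * (c + 0.5)))
}

# Build a logical cells x 2 assignment matrix realizing an exact 2x2 table.
assignment_from_table <- function(a, b, c, d) {
  m <- matrix(FALSE, a + b + c + d, 2, dimnames = list(NULL, c("P1", "P2")))
  if (a > 0) m[seq_len(a), ] <- TRUE
  if (b > 0) m[a + seq_len(b), 1] <- TRUE
  if (c > 0) m[a + b + seq_len(c), 2] <- TRUE
  m
}
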