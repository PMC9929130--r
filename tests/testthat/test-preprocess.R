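test_that("qc_filter matches hand enumeration of the four rules on a scripted fixture", {
  fx <- make_qc_fixture()
  res <- qc_filter(fx$counts, fx$sample)
  ann <- res$annotation
  removed_oracle <- enumerate_qc(ann$n_genes, ann$n_umis, ann$mito_fraction,
                                 fx$sample)
  expect_identical(!ann$qc_pass, unname(removed_oracle))
  expect_identical(rownames(res$counts), ann$barcode[ann$qc_pass])
  # scripted boundaries: 199 genes removed, 200 kept; mito 0.5 kept, >0.5 removed
  expect_false(ann$qc_pass[1])
  expect_true(ann$fail_low_genes[1])
  expect_true(ann$qc_pass[2])
  expect_true(ann$qc_pass[5])
  expect_false(ann$qc_pass[6])
  expect_true(ann$fail_mito[6])
  expect_true(all(ann$fail_top_genes[3:4]))
  expect_true(all(ann$fail_top_umis[7:8]))
})

test_that("qc_filter re-applied with the original ceilings removes nothing", {
  fx <- make_qc_fixture()
  once <- qc_filter(fx$counts, fx$sample)
  again <- qc_filter(once$counts, fx$sample[once$annotation$qc_pass],
                     ceilings = once$ceilings)
  expect_identical(rownames(again$counts), rownames(once$counts))
})

test_that("qc_filter handles empty input and unknown mito prefixes", {
  empty <- Matrix::sparseMatrix(i = integer(), j = integer(), x = numeric(),
                                dims = c(0, 5),
                                dimnames = list(character(), paste0("G", 1:5)))
  expect_warning(res <- qc_filter(empty), "empty")
  expect_equal(nrow(res$counts), 0)
  fx <- make_qc_fixture()
  expect_warning(res2 <- qc_filter(fx$counts, fx$sample, mito_prefix = "ZZ-"),
                 "mito")
  expect_true(all(res2$annotation$mito_fraction == 0))
})

test_that("normalize_log matches hand arithmetic and preserves ranks", {
  m <- Matrix::Matrix(matrix(c(1, 0, 3,
                               0, 0, 0,
                               5, 5, 0), 3, 3, byrow = TRUE,
                             dimnames = list(paste0("c", 1:3), paste0("g", 1:3))),
                      sparse = TRUE)
  expect_warning(norm <- normalize_log(m), "zero total")
  expect_equal(as.numeric(norm[2, ]), c(0, 0, 0))
  expect_equal(norm[1, 1], log1p(1 / 4 * 1e4))
  expect_equal(norm[1, 3], log1p(3 / 4 * 1e4))
  expect_equal(norm[3, 1], log1p(5 / 10 * 1e4))
  # one expressed gene always maps to log1p(target)
  single <- Matrix::Matrix(matrix(c(7, 0), 1, 2,
                                  dimnames = list("c", c("a", "b"))), sparse = TRUE)
  expect_equal(normalize_log(single)[1, 1], log1p(1e4))
  # rank preservation within a cell
  set.seed(1)
  big <- Matrix::Matrix(matrix(rpois(200, 2), 10, 20,
                               dimnames = list(paste0("c", 1:10), paste0("g", 1:20))),
                        sparse = TRUE)
  nb <- normalize_log(big)
  for (i in 1:10)
    expect_equal(rank(as.numeric(nb[i, ])), rank(as.numeric(big[i, ])))
})

test_that("clustering recovers well-separated planted populations exactly", {
  cfg <- sim_config(n_samples = 1, organ_per_sample = "liver",
                    cells_per_type = c(cancer = 80, Tcell = 80, Bcell = 80),
                    n_genes = 500, n_chromosomes = 5, seed = 2)
  sim <- simulate_counts(cfg)
  norm <- normalize_log(sim$counts)
  cl <- cluster_cells(norm, seed = 1)
  expect_equal(ari(cl, sim$cell_info$cell_type), 1.0)
  expect_identical(cl, cluster_cells(norm, seed = 1))  # seeded determinism
})

test_that("a homogeneous population at low resolution is a single cluster", {
  cfg <- sim_config(n_samples = 1, organ_per_sample = "liver",
                    cells_per_type = c(cancer = 120), n_genes = 300,
                    n_chromosomes = 3, seed = 9)
  sim <- simulate_counts(cfg)
  cl <- cluster_cells(normalize_log(sim$counts), resolution = 0.1, seed = 1)
  expect_equal(nlevels(droplevels(cl)), 1L)
})

test_that("clustering is invariant to gene and cell order up to label names", {
  cfg <- sim_config(n_samples = 1, organ_per_sample = "liver",
                    cells_per_type = c(cancer = 60, Tcell = 60),
                    n_genes = 300, n_chromosomes = 3, seed = 4)
  sim <- simulate_counts(cfg)
  norm <- normalize_log(sim$counts)
  cl <- cluster_cells(norm, seed = 1)
  set.seed(33)
  gperm <- sample(ncol(norm))
  cl_g <- cluster_cells(norm[, gperm], seed = 1)
  expect_equal(ari(cl, cl_g), 1.0)
  cperm <- sample(nrow(norm))
  cl_c <- cluster_cells(norm[cperm, ], seed = 1)
  expect_equal(ari(cl[cperm], cl_c), 1.0)
})

test_that("find_markers agrees with stats::wilcox.test and applies the stated filters", {
  set.seed(5)
  n <- 60
  x <- matrix(rpois(n * 6, 3), n, 6,
              dimnames = list(paste0("c", 1:n), paste0("g", 1:6)))
  x[1:30, 1] <- x[1:30, 1] + 6            # strong marker of cluster 1
  x[31:60, 2] <- 0; x[31:45, 2] <- 1      # detected in 50% outside
  norm <- normalize_log(Matrix::Matrix(x, sparse = TRUE))
  labels <- rep(c("1", "2"), each = 30)
  mk <- find_markers(norm, labels, min_pct = 0, min_logfc = -Inf)
  for (g in c("g1", "g3")) {
    row <- mk[mk$cluster == "1" & mk$gene == g, ]
    ref_p <- wilcox.test(as.numeric(norm[1:30, g]), as.numeric(norm[31:60, g]),
                         exact = FALSE)$p.value
    expect_equal(row$p_value, ref_p, tolerance = 1e-10)
  }
  mk_filt <- find_markers(norm, labels)
  expect_true(all(mk_filt$pct_in_cluster > 0.10))
  expect_true(all(mk_filt$log_fold_change > 0.25))
  expect_true("g1" %in% mk_filt$gene[mk_filt$cluster == "1"])
})

test_that("a gene detected in 5% of a cluster never enters the marker table", {
  set.seed(6)
  n <- 200
  x <- matrix(rpois(n * 4, 2), n, 4,
              dimnames = list(paste0("c", 1:n), paste0("g", 1:4)))
  x[, 1] <- 0
  x[1:5, 1] <- 50  # 5% of cluster 1, huge fold change
  norm <- normalize_log(Matrix::Matrix(x, sparse = TRUE))
  labels <- rep(c("1", "2"), each = 100)
  mk <- find_markers(norm, labels)
  expect_false("g1" %in% mk$gene[mk$cluster == "1"])
})

test_that("label-permuted identical clusters give no significant markers", {
  cfg <- sim_config(n_samples = 1, organ_per_sample = "liver",
                    cells_per_type = c(cancer = 200), n_genes = 300,
                    n_chromosomes = 3, seed = 12)
  norm <- normalize_log(simulate_counts(cfg)$counts)
  hits <- 0L
  for (s in 1:3) {
    set.seed(s)
    labels <- sample(rep(c("a", "b"), each = 100))
    mk <- find_markers(norm, labels)
    hits <- hits + sum(mk$adjusted_p < 0.05)
  }
  expect_equal(hits, 0L)
})

test_that("single-cell clusters are skipped with a warning", {
  set.seed(7)
  x <- matrix(rpois(30 * 5, 3), 30, 5,
              dimnames = list(paste0("c", 1:30), paste0("g", 1:5)))
  norm <- normalize_log(Matrix::Matrix(x, sparse = TRUE))
  labels <- c("solo", rep(c("a", "b"), times = c(14, 15)))
  expect_warning(mk <- find_markers(norm, labels), "solo")
  expect_false("solo" %in% mk$cluster)
})

test_that("annotation assigns planted types, flags ties, and falls back to unassigned", {
  cfg <- sim_config(n_samples = 1, organ_per_sample = "liver",
                    cells_per_type = c(cancer = 60, Tcell = 60),
                    n_genes = 400, n_chromosomes = 4, seed = 3)
  sim <- simulate_counts(cfg)
  norm <- normalize_log(sim$counts)
  cl <- cluster_cells(norm, seed = 1)
  db <- lapply(sim$truth$markers, function(d) d$gene)
  ann <- annotate_clusters(norm, cl, db)
  truth <- sim$cell_info$cell_type[match(rownames(norm), sim$cell_info$barcode)]
  expect_gt(mean(ann$cell_type[rownames(norm)] == truth), 0.95)
  # exact tie between two identically-defined types -> lexicographic winner
  db_tie <- list(zeta = db$cancer, alpha = db$cancer)
  ann_tie <- annotate_clusters(norm, cl, db_tie)
  cancer_cl <- names(which.max(table(cl[truth == "cancer"])))
  row <- ann_tie$cluster_table[ann_tie$cluster_table$cluster == cancer_cl, ]
  expect_equal(row$cell_type, "alpha")
  expect_true(row$tie)
  # a marker set absent from the data -> unassigned
  zero <- norm
  zero@x[] <- 0
  ann0 <- annotate_clusters(zero, cl, db)
  expect_true(all(ann0$cluster_table$cell_type == "unassigned"))
})
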