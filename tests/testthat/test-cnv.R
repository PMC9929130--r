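make_cnv_sim <- function(seed, cells = c(cancer = 150, Tcell = 80, Bcell = 70),
                         seg = NULL, n_genes = 1000, n_chromosomes = 5) {
  cfg <- sim_config(n_samples = 1, organ_per_sample = "liver",
                    cells_per_type = cells, n_genes = n_genes,
                    n_chromosomes = n_chromosomes, cnv_segments = seg,
                    seed = seed)
  sim <- simulate_counts(cfg)
  norm <- normalize_log(sim$counts)
  ref <- sim$cell_info$barcode[sim$cell_info$cell_type %in% c("Tcell", "Bcell")]
  list(sim = sim, norm = norm, ref = ref)
}

test_that("smoothed profiles equal the naive moving-average oracle to 1e-10", {
  seg <- data.frame(chrom = "chr2", start_gene = 21, end_gene = 170,
                    fold_change = 2, carrier_fraction = 1, subclone = "A")
  s <- make_cnv_sim(1, cells = c(cancer = 60, Tcell = 40), seg = seg,
                    n_genes = 500, n_chromosomes = 2)
  prof <- infer_cnv(s$norm, s$sim$gene_info, s$ref)
  oracle <- naive_cnv(s$norm, s$sim$gene_info, s$ref)
  expect_equal(dim(prof$dev), dim(oracle))
  expect_lt(max(abs(prof$dev - oracle)), 1e-10)
  # planted segment stands out against the off-segment background
  mal <- s$sim$cell_info$barcode[s$sim$cell_info$is_malignant]
  on_seg <- prof$genes$chrom == "chr2" & prof$genes$start >= 20 &
    prof$genes$start <= 169
  expect_gt(mean(prof$dev[mal, on_seg]), mean(prof$dev[mal, !on_seg]) + 0.1)
})

test_that("identical cells yield an exactly neutral profile", {
  n_genes <- 220
  gp <- data.frame(gene = paste0("g", seq_len(n_genes)), chrom = "chr1",
                   start = seq_len(n_genes) - 1)
  row <- rpois(n_genes, 5)
  x <- Matrix::Matrix(matrix(rep(row, each = 30), 30, n_genes,
                             dimnames = list(paste0("c", 1:30), gp$gene)),
                      sparse = TRUE)
  prof <- infer_cnv(x, gp, reference_cells = paste0("c", 1:10), min_cells = 0)
  expect_lt(max(abs(prof$dev)), 1e-12)
})

test_that("a constant offset cell deviates by exactly that constant", {
  n_genes <- 101
  gp <- data.frame(gene = paste0("g", seq_len(n_genes)), chrom = "chr1",
                   start = seq_len(n_genes) - 1)
  d <- 0.4
  base <- rep(5, n_genes)
  x <- rbind(base, base, base + d, base + d)
  dimnames(x) <- list(paste0("c", 1:4), gp$gene)
  prof <- infer_cnv(Matrix::Matrix(x, sparse = TRUE), gp,
                    reference_cells = c("c1", "c2"), min_cells = 0)
  expect_equal(unname(prof$dev["c3", ]), rep(d, n_genes), tolerance = 1e-12)
})

test_that("profiles are invariant to adding a constant everywhere", {
  s <- make_cnv_sim(2, cells = c(cancer = 40, Tcell = 30), n_genes = 400,
                    n_chromosomes = 4)
  # keep every gene in both runs so the smoothing windows are identical
  prof1 <- infer_cnv(s$norm, s$sim$gene_info, s$ref, min_cells = -1)
  prof2 <- infer_cnv(s$norm + 3, s$sim$gene_info, s$ref, min_cells = -1)
  expect_equal(prof1$dev, prof2$dev, tolerance = 1e-10)
})

test_that("on-segment deviation grows monotonically with planted fold change", {
  means <- vapply(c(1.2, 1.5, 2.0), function(f) {
    seg <- data.frame(chrom = "chr2", start_gene = 21, end_gene = 170,
                      fold_change = f, carrier_fraction = 1, subclone = "A")
    s <- make_cnv_sim(3, seg = seg)
    prof <- infer_cnv(s$norm, s$sim$gene_info, s$ref)
    mal <- s$sim$cell_info$barcode[s$sim$cell_info$is_malignant]
    on_seg <- prof$genes$chrom == "chr2" & prof$genes$start >= 20 &
      prof$genes$start <= 169
    mean(prof$dev[mal, on_seg])
  }, 0)
  expect_true(all(diff(means) > 0))
})

test_that("short chromosomes are smoothed with a reduced window, with warning", {
  n_genes <- 60
  gp <- data.frame(gene = paste0("g", seq_len(n_genes)), chrom = "chr1",
                   start = seq_len(n_genes) - 1)
  set.seed(1)
  x <- Matrix::Matrix(matrix(rpois(40 * n_genes, 5), 40, n_genes,
                             dimnames = list(paste0("c", 1:40), gp$gene)),
                      sparse = TRUE)
  expect_warning(prof <- infer_cnv(x, gp, paste0("c", 1:20), min_cells = 0),
                 "window")
  expect_equal(ncol(prof$dev), n_genes)
  expect_error(infer_cnv(x, gp, character()), "reference")
})

test_that("cnv_score has its closed forms and separates planted malignancy", {
  dev0 <- matrix(0, 3, 10, dimnames = list(paste0("c", 1:3), paste0("g", 1:10)))
  expect_equal(unname(cnv_score(dev0)), rep(0, 3))
  devc <- matrix(0.3, 2, 8, dimnames = list(c("a", "b"), paste0("g", 1:8)))
  expect_equal(unname(cnv_score(devc)), rep(log1p(0.09), 2))
  seg <- data.frame(chrom = c("chr2", "chr4"), start_gene = c(21, 31),
                    end_gene = c(170, 180), fold_change = c(2, 0.5),
                    carrier_fraction = 1, subclone = "A")
  s <- make_cnv_sim(4, seg = seg)
  prof <- infer_cnv(s$norm, s$sim$gene_info, s$ref)
  sc <- cnv_score(prof)
  mal <- s$sim$cell_info$is_malignant[match(names(sc), s$sim$cell_info$barcode)]
  expect_gt(median(sc[mal]), quantile(sc[names(sc) %in% s$ref], 0.95))
})

test_that("CNV profile clustering separates planted subclones and is deterministic", {
  seg <- data.frame(chrom = c("chr2", "chr4"), start_gene = c(21, 31),
                    end_gene = c(170, 180), fold_change = c(2, 2),
                    carrier_fraction = 1, subclone = c("A", "B"))
  s <- make_cnv_sim(5, seg = seg)
  prof <- infer_cnv(s$norm, s$sim$gene_info, s$ref)
  mal <- s$sim$cell_info$barcode[s$sim$cell_info$is_malignant]
  cl <- cluster_cnv_profiles(prof, k = 2, cells = mal)
  truth <- s$sim$cell_info$subclone[match(mal, s$sim$cell_info$barcode)]
  expect_equal(ari(cl, truth), 1.0)
  expect_identical(cl, cluster_cnv_profiles(prof, k = 2, cells = mal))
  same <- list(dev = matrix(1, 4, 6, dimnames = list(paste0("c", 1:4), NULL)))
  expect_equal(nlevels(droplevels(cluster_cnv_profiles(same, k = 1))), 1L)
  expect_error(cluster_cnv_profiles(same, k = 9), "k exceeds")
})

test_that("malignancy calling is calibrated on neutral data", {
  # a single homogeneous population: every cell is copy-neutral
  cfg <- sim_config(n_samples = 1, organ_per_sample = "liver",
                    cells_per_type = c(cancer = 300), n_genes = 1000,
                    n_chromosomes = 5, seed = 6)
  sim <- simulate_counts(cfg)
  norm <- normalize_log(sim$counts)
  ref <- sim$cell_info$barcode[1:150]
  prof <- infer_cnv(norm, sim$gene_info, ref)
  sc <- cnv_score(prof)
  call <- call_malignant(sc, sc[names(sc) %in% ref])
  expect_lte(mean(call$is_malignant), 0.02)
  ref_med <- names(sc)[which.min(abs(sc - median(sc[names(sc) %in% ref])))]
  expect_false(call$is_malignant[call$barcode == ref_med])
  expect_warning(call_malignant(c(a = 1), c(1, 1, 1)), "degenerate")
})

test_that("event calling applies the 90% canonical rule and span thresholds", {
  n_genes <- 200
  gp <- data.frame(gene = paste0("g", seq_len(n_genes)), chrom = "chr1",
                   start = seq_len(n_genes) - 1)
  dev <- matrix(0, 100, n_genes, dimnames = list(paste0("c", 1:100), gp$gene))
  dev[1:60, 41:100] <- 0.3     # carried by 60% of the subclone
  prof <- structure(list(dev = dev, genes = gp), class = "cnv_profile")
  sub <- setNames(rep("S1", 100), rownames(dev))
  ev <- call_events(prof, sub)
  expect_equal(nrow(ev), 1L)
  expect_equal(ev$direction, "gain")
  expect_equal(ev$cell_percent, 60)
  expect_false(ev$canonical)
  dev2 <- dev; dev2[, 41:100] <- 0.3  # carried by every cell
  prof2 <- structure(list(dev = dev2, genes = gp), class = "cnv_profile")
  ev2 <- call_events(prof2, sub)
  expect_true(ev2$canonical)
  expect_equal(ev2$cell_percent, 100)
  # neutral profile and sub-threshold spans produce nothing
  dev3 <- matrix(0, 50, n_genes, dimnames = list(paste0("c", 1:50), gp$gene))
  dev3[, 10:30] <- 0.4  # 21 genes < min_span_genes
  prof3 <- structure(list(dev = dev3, genes = gp), class = "cnv_profile")
  expect_equal(nrow(call_events(prof3, setNames(rep("S1", 50), rownames(dev3)))), 0L)
})

test_that("clonality trees recover a constructed trunk-and-branches truth", {
  ev <- data.frame(
    event_id = c("chr1:gain:1-50", "chr1:gain:1-50", "chr2:gain:10-60",
                 "chr3:loss:5-55"),
    subclone = c("s1", "s2", "s1", "s2"),
    chrom = c("chr1", "chr1", "chr2", "chr3"),
    start_index = c(1, 1, 10, 5), end_index = c(50, 50, 60, 55),
    n_genes = c(50, 50, 51, 51),
    direction = c("gain", "gain", "gain", "loss"),
    mean_dev = c(0.3, 0.3, 0.3, -0.3),
    cell_percent = c(100, 100, 95, 97), canonical = TRUE,
    stringsAsFactors = FALSE)
  tree <- build_clonality_tree(ev, c(s1 = 120, s2 = 80))
  trunk <- tree$root$children[[1]]
  expect_equal(sort(trunk$subclones), c("s1", "s2"))
  expect_equal(trunk$events_acquired$event_id, "chr1:gain:1-50")
  expect_equal(length(trunk$children), 2L)
  leaves <- setNames(trunk$children,
                     vapply(trunk$children, `[[`, "", "name"))
  expect_equal(leaves$s1$events_acquired$event_id, "chr2:gain:10-60")
  expect_equal(leaves$s2$events_acquired$event_id, "chr3:loss:5-55")
  expect_equal(sum(vapply(trunk$children, `[[`, 0, "cell_count")), 200)
  expect_length(tree$conflicts, 0)
  expect_true(all(ev$cell_percent[ev$canonical] > 90))
  nw <- tree_newick(tree)
  expect_match(nw, "^\\(.*\\)root:0;$")
  if (requireNamespace("ape", quietly = TRUE))
    expect_silent(ape::read.tree(text = nw))
})

test_that("degenerate trees: single subclone and no events", {
  ev <- data.frame(event_id = "chr1:gain:1-40", subclone = "s1",
                   chrom = "chr1", start_index = 1, end_index = 40,
                   n_genes = 40, direction = "gain", mean_dev = 0.4,
                   cell_percent = 100, canonical = TRUE,
                   stringsAsFactors = FALSE)
  tree <- build_clonality_tree(ev, c(s1 = 50))
  leaf <- tree$root$children[[1]]
  expect_equal(leaf$name, "s1")
  expect_equal(leaf$events_acquired$event_id, "chr1:gain:1-40")
  empty <- build_clonality_tree(ev[0, ], c(s1 = 30, s2 = 20, s3 = 10))
  star <- empty$root$children[[1]]
  expect_equal(nrow(star$events_acquired), 0L)
  expect_length(star$children, 3L)
  expect_true(all(vapply(star$children, function(ch) nrow(ch$events_acquired), 0L) == 0L))
  expect_equal(empty$root$cell_count, 60)
})
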