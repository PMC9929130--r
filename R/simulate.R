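#' Build a simulation configuration
#'
#' Defines a multi-sample single-cell cohort with planted ground truth:
#' discrete cell types with marker genes, malignant cells carrying segmental
#' expression-level copy-number changes organized into subclones, activity
#' programs spanning samples with controlled co-occurrence, and
#' ligand-receptor effects between chosen type pairs. Counts are negative
#' binomial with a lognormal library-size factor and independent dropout.
#'
#' Genes are laid out on `n_chromosomes` synthetic chromosomes with 0-based
#' index coordinates; only gene order matters downstream. The first
#' `n_mito_genes` genes carry the `MT-` prefix so mitochondrial QC is
#' exercised.
#'
#' @param n_samples number of samples (tumors).
#' @param organ_per_sample organ context per sample, `"liver"` or `"brain"`.
#' @param cells_per_type named integer vector: cells of each type per sample.
#'   The type named by `malignant_type` provides the malignant compartment.
#' @param n_genes,n_chromosomes gene universe size and chromosome count.
#' @param n_mito_genes number of genes given the mitochondrial prefix.
#' @param baseline_mean scale of per-gene negative-binomial means; per-gene
#'   baselines are `baseline_mean * lognormal(0, 1)`.
#' @param nb_dispersion shared negative-binomial size parameter.
#' @param library_size `c(mu, sigma)` of the lognormal per-cell library factor.
#' @param dropout_rate probability that an observed count is zeroed.
#' @param markers_per_type,marker_fold number of marker genes auto-assigned
#'   to each type (spread along the genome) and their fold change. Ignored
#'   for a type listed in `marker_genes`.
#' @param marker_genes optional named list type -> data.frame(gene, fold).
#' @param malignant_type the cell type treated as malignant.
#' @param cnv_segments optional data.frame with columns `chrom`,
#'   `start_gene`, `end_gene` (1-based gene indices within the chromosome),
#'   `fold_change`, `carrier_fraction`, `subclone`. A truncal event is a row
#'   repeated for every subclone.
#' @param subclone_fractions optional named fractions of malignant cells per
#'   subclone; defaults to an even split over the subclones named in
#'   `cnv_segments`.
#' @param programs optional list of lists with fields `program_id`, `genes`,
#'   `activation_fold`, `active_fraction` (scalar or named per sample).
#'   Programs act on malignant cells.
#' @param program_dependency optional data.frame(`program_a`, `program_b`,
#'   `rule`) with rule one of `"independent"`, `"cooccur"`, `"exclude"`,
#'   applied per sample while preserving marginal activity fractions.
#' @param lr_truth optional data.frame(`ligand`, `receptor`, `sender`,
#'   `receiver`, `effect_fold`) of planted ligand-receptor effects.
#' @param seed integer seed; identical configurations give identical output.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_samples = 4,
                       organ_per_sample = rep(c("liver", "brain"), length.out = n_samples),
                       cells_per_type = c(cancer = 300, Tcell = 120, Bcell = 80,
                                          myeloid = 60, fibroblast = 40),
                       n_genes = 2000,
                       n_chromosomes = 10,
                       n_mito_genes = 10,
                       baseline_mean = 3,
                       nb_dispersion = 2,
                       library_size = c(mu = 0, sigma = 0.25),
                       dropout_rate = 0.05,
                       markers_per_type = 20,
                       marker_fold = 8,
                       marker_genes = NULL,
                       malignant_type = "cancer",
                       cnv_segments = NULL,
                       subclone_fractions = NULL,
                       programs = NULL,
                       program_dependency = NULL,
                       lr_truth = NULL,
                       seed = 1) {
  cfg <- list(
    n_samples = as.integer(n_samples),
    organ_per_sample = organ_per_sample,
    cells_per_type = cells_per_type,
    n_genes = as.integer(n_genes),
    n_chromosomes = as.integer(n_chromosomes),
    n_mito_genes = as.integer(n_mito_genes),
    baseline_mean = baseline_mean,
    nb_dispersion = nb_dispersion,
    library_size = library_size,
    dropout_rate = dropout_rate,
    markers_per_type = as.integer(markers_per_type),
    marker_fold = marker_fold,
    marker_genes = marker_genes,
    malignant_type = malignant_type,
    cnv_segments = cnv_segments,
    subclone_fractions = subclone_fractions,
    programs = programs,
    program_dependency = program_dependency,
    lr_truth = lr_truth,
    seed = as.integer(seed)
  )
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

#' Gene universe implied by a simulation configuration
#'
#' @param config a `sim_config`.
#' @return data.frame with `gene`, `chrom`, `start` (0-based index on the
#'   chromosome), ordered by chromosome then position.
#' @export
sim_gene_table <- function(config) {
  g <- config$n_genes
  per <- ceiling(g / config$n_chromosomes)
  chrom_idx <- rep(seq_len(config$n_chromosomes), each = per)[seq_len(g)]
  start <- unlist(lapply(split(seq_len(g), chrom_idx), seq_along),
                  use.names = FALSE) - 1L
  gene <- sprintf("G%04d", seq_len(g))
  if (config$n_mito_genes > 0L) {
    idx <- seq_len(config$n_mito_genes)
    gene[idx] <- sprintf("MT-%02d", idx)
  }
  data.frame(gene = gene, chrom = paste0("chr", chrom_idx), start = start,
             stringsAsFactors = FALSE)
}

#' Per-gene baseline negative-binomial means of a configuration
#'
#' The baseline mean of each gene is `baseline_mean * lognormal(0, 1)`,
#' drawn deterministically from the configuration seed (the same draw
#' [simulate_counts()] uses). Useful for choosing planted gene sets with a
#' target baseline detection rate, e.g. program genes whose detection only
#' crosses the program-cell threshold when activated.
#'
#' @param config a `sim_config`.
#' @return named numeric vector of baseline means per gene.
#' @export
sim_gene_baselines <- function(config) {
  set.seed(config$seed)
  setNames(config$baseline_mean * rlnorm(config$n_genes, 0, 1),
           sim_gene_table(config)$gene)
}

validate_sim_config <- function(cfg) {
  .assert(cfg$n_samples >= 1L, "need at least one sample", "n_samples")
  .assert(length(cfg$organ_per_sample) == cfg$n_samples &&
            all(cfg$organ_per_sample %in% c("liver", "brain")),
          "must be one of 'liver'/'brain' per sample", "organ_per_sample")
  .assert(!is.null(names(cfg$cells_per_type)) && all(cfg$cells_per_type >= 0),
          "must be a named nonnegative vector", "cells_per_type")
  .assert(cfg$n_genes >= cfg$n_chromosomes, "fewer genes than chromosomes", "n_genes")
  .assert(cfg$baseline_mean > 0, "must be positive", "baseline_mean")
  .assert(cfg$nb_dispersion > 0, "must be positive", "nb_dispersion")
  .assert(cfg$dropout_rate >= 0 && cfg$dropout_rate < 1,
          "must be in [0, 1)", "dropout_rate")
  .assert(cfg$malignant_type %in% names(cfg$cells_per_type),
          "not among cells_per_type", "malignant_type")
  genes <- sim_gene_table(cfg)
  per_chrom <- table(genes$chrom)
  if (!is.null(cfg$marker_genes)) {
    for (ty in names(cfg$marker_genes)) {
      .assert(ty %in% names(cfg$cells_per_type), paste("unknown type", ty),
              "marker_genes")
      .assert(all(cfg$marker_genes[[ty]]$gene %in% genes$gene),
              paste("unknown gene for type", ty), "marker_genes")
    }
  }
  if (!is.null(cfg$cnv_segments)) {
    seg <- cfg$cnv_segments
    need <- c("chrom", "start_gene", "end_gene", "fold_change",
              "carrier_fraction", "subclone")
    .assert(all(need %in% names(seg)), paste("missing columns:",
            paste(setdiff(need, names(seg)), collapse = ", ")), "cnv_segments")
    .assert(all(seg$chrom %in% genes$chrom), "unknown chromosome", "cnv_segments")
    .assert(all(seg$start_gene >= 1 & seg$start_gene <= seg$end_gene),
            "need 1 <= start_gene <= end_gene", "cnv_segments")
    .assert(all(seg$end_gene <= per_chrom[seg$chrom]),
            "gene index out of range for chromosome", "cnv_segments")
    .assert(all(seg$fold_change > 0), "fold_change must be positive", "cnv_segments")
    .assert(all(seg$carrier_fraction > 0 & seg$carrier_fraction <= 1),
            "carrier_fraction must be in (0, 1]", "cnv_segments")
  }
  if (!is.null(cfg$programs)) {
    ids <- vapply(cfg$programs, `[[`, "", "program_id")
    .assert(!anyDuplicated(ids), "duplicate program_id", "programs")
    for (p in cfg$programs) {
      .assert(length(p$genes) > 0 && all(p$genes %in% genes$gene),
              paste("empty or unknown gene set for", p$program_id), "programs")
      .assert(p$activation_fold > 0, "activation_fold must be positive", "programs")
      .assert(all(p$active_fraction >= 0 & p$active_fraction <= 1),
              "active_fraction must be in [0, 1]", "programs")
    }
    if (!is.null(cfg$program_dependency)) {
      dep <- cfg$program_dependency
      .assert(all(c(dep$program_a, dep$program_b) %in% ids),
              "unknown program id", "program_dependency")
      .assert(all(dep$rule %in% c("independent", "cooccur", "exclude")),
              "rule must be independent/cooccur/exclude", "program_dependency")
    }
  }
  if (!is.null(cfg$lr_truth)) {
    lr <- cfg$lr_truth
    .assert(all(c(lr$ligand, lr$receptor) %in% genes$gene),
            "unknown ligand/receptor gene", "lr_truth")
    .assert(all(c(lr$sender, lr$receiver) %in% names(cfg$cells_per_type)),
            "unknown sender/receiver type", "lr_truth")
    .assert(all(lr$effect_fold >= 1), "effect_fold must be >= 1", "lr_truth")
  }
  invisible(cfg)
}

# Marker assignment: each type's markers are spread along the genome so no
# 101-gene window is dominated by one type's markers (which would mimic a CNV).
.default_markers <- function(cfg, genes) {
  types <- names(cfg$cells_per_type)
  out <- list()
  cand <- which(!startsWith(genes$gene, "MT-"))
  m <- cfg$markers_per_type
  for (i in seq_along(types)) {
    if (!is.null(cfg$marker_genes[[types[i]]])) {
      out[[types[i]]] <- cfg$marker_genes[[types[i]]]
      next
    }
    if (m == 0L) {
      out[[types[i]]] <- data.frame(gene = character(), fold = numeric(),
                                    stringsAsFactors = FALSE)
      next
    }
    pos <- round(seq(1, length(cand) - length(types), length.out = m)) + (i - 1L)
    out[[types[i]]] <- data.frame(gene = genes$gene[cand[pos]],
                                  fold = cfg$marker_fold,
                                  stringsAsFactors = FALSE)
  }
  out
}

#' Simulate a multi-sample count matrix with planted ground truth
#'
#' @param config a [sim_config()].
#' @return A list of class `mn_sim` with elements `counts` (sparse cells x
#'   genes integer matrix, barcodes x genes), `cell_info` (barcode, sample,
#'   organ, cell_type, is_malignant, subclone), `gene_info` (gene, chrom,
#'   start), and `truth` (program activity matrix, segment table with
#'   per-cell carrier matrix, ligand-receptor table, marker table, config).
#' @export
simulate_counts <- function(config) {
  validate_sim_config(config)
  base_mean <- unname(sim_gene_baselines(config))  # seeds the RNG
  genes <- sim_gene_table(config)
  n_genes <- nrow(genes)

  types <- names(config$cells_per_type)
  samples <- sprintf("S%d", seq_len(config$n_samples))
  cell_info <- do.call(rbind, lapply(seq_len(config$n_samples), function(si) {
    tv <- rep(types, times = config$cells_per_type)
    data.frame(sample = samples[si], organ = config$organ_per_sample[si],
               cell_type = tv, stringsAsFactors = FALSE)
  }))
  n_cells <- nrow(cell_info)
  cell_info$barcode <- sprintf("%s_c%05d", cell_info$sample,
                               unlist(lapply(samples, function(s)
                                 seq_len(sum(cell_info$sample == s)))))
  cell_info <- cell_info[, c("barcode", "sample", "organ", "cell_type")]
  cell_info$is_malignant <- cell_info$cell_type == config$malignant_type

  # subclone assignment among malignant cells, per sample
  seg <- config$cnv_segments
  subclones <- if (!is.null(seg)) sort(unique(as.character(seg$subclone))) else character()
  if (length(subclones) == 0L && any(cell_info$is_malignant)) subclones <- "S1"
  fr <- config$subclone_fractions %||%
    setNames(rep(1 / length(subclones), length(subclones)), subclones)
  cell_info$subclone <- NA_character_
  for (s in samples) {
    idx <- which(cell_info$sample == s & cell_info$is_malignant)
    if (!length(idx)) next
    cnt <- floor(fr[subclones] * length(idx))
    rem <- length(idx) - sum(cnt)
    if (rem > 0) cnt[seq_len(rem)] <- cnt[seq_len(rem)] + 1L
    cell_info$subclone[idx] <- sample(rep(subclones, times = cnt))
  }

  # program activity over malignant cells
  prog_ids <- vapply(config$programs %||% list(), `[[`, "", "program_id")
  activity <- matrix(FALSE, n_cells, length(prog_ids),
                     dimnames = list(cell_info$barcode, prog_ids))
  for (p in config$programs %||% list()) {
    for (s in samples) {
      idx <- which(cell_info$sample == s & cell_info$is_malignant)
      if (!length(idx)) next
      f <- p$active_fraction
      if (!is.null(names(f))) f <- f[[s]] %||% 0
      k <- round(f * length(idx))
      if (k > 0) activity[sample(idx, k), p$program_id] <- TRUE
    }
  }
  if (!is.null(config$program_dependency)) {
    dep <- config$program_dependency
    for (r in seq_len(nrow(dep))) {
      for (s in samples) {
        idx <- which(cell_info$sample == s & cell_info$is_malignant)
        if (!length(idx)) next
        ab <- plant_dependency(activity[idx, dep$program_a[r]],
                               activity[idx, dep$program_b[r]],
                               rule = dep$rule[r])
        activity[idx, dep$program_a[r]] <- ab[, 1L]
        activity[idx, dep$program_b[r]] <- ab[, 2L]
      }
    }
  }

  # expected means: baseline x library factor, then multiplicative effects
  lib <- rlnorm(n_cells, config$library_size[[1]], config$library_size[[2]])
  mu <- outer(lib, base_mean)
  markers <- .default_markers(config, genes)
  for (ty in names(markers)) {
    rows <- which(cell_info$cell_type == ty)
    cols <- match(markers[[ty]]$gene, genes$gene)
    if (length(rows) && length(cols))
      mu[rows, cols] <- sweep(mu[rows, cols, drop = FALSE], 2L,
                              markers[[ty]]$fold, "*")
  }
  carriers <- NULL
  if (!is.null(seg)) {
    carriers <- matrix(FALSE, n_cells, nrow(seg),
                       dimnames = list(cell_info$barcode, NULL))
    chrom_offset <- c(0L, cumsum(table(factor(genes$chrom, unique(genes$chrom)))))
    names(chrom_offset) <- c(unique(genes$chrom), "end")
    for (i in seq_len(nrow(seg))) {
      cols <- chrom_offset[[seg$chrom[i]]] + seg$start_gene[i]:seg$end_gene[i]
      rows <- which(!is.na(cell_info$subclone) &
                      cell_info$subclone == as.character(seg$subclone[i]))
      rows <- rows[runif(length(rows)) < seg$carrier_fraction[i]]
      if (length(rows)) {
        carriers[rows, i] <- TRUE
        mu[rows, cols] <- mu[rows, cols, drop = FALSE] * seg$fold_change[i]
      }
    }
  }
  for (p in config$programs %||% list()) {
    rows <- which(activity[, p$program_id])
    cols <- match(p$genes, genes$gene)
    if (length(rows))
      mu[rows, cols] <- mu[rows, cols, drop = FALSE] * p$activation_fold
  }
  if (!is.null(config$lr_truth)) {
    lr <- config$lr_truth
    for (i in seq_len(nrow(lr))) {
      snd <- which(cell_info$cell_type == lr$sender[i])
      rcv <- which(cell_info$cell_type == lr$receiver[i])
      mu[snd, match(lr$ligand[i], genes$gene)] <-
        mu[snd, match(lr$ligand[i], genes$gene)] * lr$effect_fold[i]
      mu[rcv, match(lr$receptor[i], genes$gene)] <-
        mu[rcv, match(lr$receptor[i], genes$gene)] * lr$effect_fold[i]
    }
  }

  counts <- matrix(rnbinom(length(mu), mu = mu, size = config$nb_dispersion),
                   n_cells, n_genes)
  if (config$dropout_rate > 0)
    counts[runif(length(counts)) < config$dropout_rate] <- 0L
  dimnames(counts) <- list(cell_info$barcode, genes$gene)
  counts <- .as_sparse(counts)

  structure(list(
    counts = counts,
    cell_info = cell_info,
    gene_info = genes,
    truth = list(program_activity = activity,
                 segments = seg,
                 segment_carriers = carriers,
                 lr = config$lr_truth,
                 markers = markers,
                 config = config)
  ), class = "mn_sim")
}

#' Plant a pairwise dependency between two program activity vectors
#'
#' Rewires the joint distribution of two boolean activity vectors over the
#' same cells to be co-occurring, mutually exclusive, or independent, while
#' preserving each program's marginal activity count exactly.
#'
#' @param a,b logical vectors over the same cells.
#' @param rule `"independent"`, `"cooccur"` or `"exclude"`.
#' @param overlap optional target joint-activity fraction; defaults to the
#'   maximum feasible for `"cooccur"`, the minimum feasible for `"exclude"`,
#'   and the product of marginals for `"independent"`. Must lie within the
#'   Frechet bounds implied by the marginals.
#' @param seed optional integer; when supplied the RNG is seeded, otherwise
#'   the current RNG stream is used.
#' @return logical matrix with columns `a`, `b`.
#' @export
plant_dependency <- function(a, b,
                             rule = c("independent", "cooccur", "exclude"),
                             overlap = NULL, seed = NULL) {
  rule <- match.arg(rule)
  .assert(length(a) == length(b), "activity vectors must have equal length")
  if (!is.null(seed)) set.seed(seed)
  n <- length(a)
  m1 <- sum(a); m2 <- sum(b)
  lo <- max(0L, m1 + m2 - n); hi <- min(m1, m2)
  j <- switch(rule,
              cooccur = hi,
              exclude = lo,
              independent = round(m1 * m2 / n))
  if (!is.null(overlap)) {
    j <- round(overlap * n)
    .assert(j >= lo && j <= hi,
            sprintf("requested overlap %d outside feasible [%d, %d] for marginals %d/%d",
                    j, lo, hi, m1, m2), "overlap")
  }
  both <- if (j > 0) sample(n, j) else integer()
  rest <- setdiff(seq_len(n), both)
  a_only <- if (m1 - j > 0) sample(rest, m1 - j) else integer()
  rest2 <- setdiff(rest, a_only)
  b_only <- if (m2 - j > 0) sample(rest2, m2 - j) else integer()
  out <- matrix(FALSE, n, 2L, dimnames = list(names(a), c("a", "b")))
  out[c(both, a_only), 1L] <- TRUE
  out[c(both, b_only), 2L] <- TRUE
  out
}
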