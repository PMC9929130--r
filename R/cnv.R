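#' Infer per-cell copy-number deviation profiles from expression
#'
#' Expression-based copy-number inference in the InferCNV tradition: genes
#' detected in enough cells are ordered along each chromosome, expression is
#' centered per gene, extreme values are clipped at `clip_sd` standard
#' deviations, a centered running mean over `window` genes smooths out
#' gene-specific effects, and the mean profile of presumed-diploid reference
#' cells (typically T and B lymphocytes) is subtracted. The result is a
#' deviation profile per cell in which 0 is copy-neutral, positive values
#' suggest gains and negative values losses.
#'
#' @param norm cells x genes log-normalized matrix.
#' @param gene_positions data.frame with `gene`, `chrom`, `start`.
#' @param reference_cells barcodes of reference (diploid) cells.
#' @param window running-mean window in genes (default 101); chromosomes
#'   shorter than the window are smoothed with the largest centered window
#'   available, with a warning.
#' @param clip_sd symmetric clipping bound in per-gene standard deviations.
#' @param min_cells genes detected in `min_cells` or fewer cells are dropped.
#' @return list of class `cnv_profile`: `dev` (cells x ordered-genes
#'   deviation matrix), `genes` (ordered position table), `reference_cells`.
#' @export
infer_cnv <- function(norm, gene_positions, reference_cells, window = 101,
                      clip_sd = 1.5, min_cells = 20) {
  .assert(length(reference_cells) > 0, "reference_cells must be nonempty")
  .assert(all(reference_cells %in% rownames(norm)),
          "all reference cells must be present in the matrix")
  .assert(window >= 1 && window %% 2 == 1, "window must be a positive odd count")
  expressed <- Matrix::colSums(norm > 0)
  keep <- names(expressed)[expressed > min_cells]
  keep <- keep[keep %in% gene_positions$gene]
  .assert(length(keep) > 1, "too few genes pass the expression filter")
  gp <- gene_positions[match(keep, gene_positions$gene), ]
  gp <- gp[order(match(gp$chrom, unique(gene_positions$chrom)), gp$start), ]
  x <- as.matrix(norm[, gp$gene, drop = FALSE])

  x <- sweep(x, 2L, colMeans(x), "-")
  bound <- clip_sd * apply(x, 2L, sd)
  x <- pmin(pmax(x, rep(-bound, each = nrow(x))), rep(bound, each = nrow(x)))

  for (ch in unique(gp$chrom)) {
    cols <- which(gp$chrom == ch)
    w <- window
    if (length(cols) < window) {
      w <- max(1L, length(cols) - (1 - length(cols) %% 2))  # largest odd <= n
      warning("chromosome ", ch, " has ", length(cols),
              " genes < window; using window ", w)
    }
    x[, cols] <- .running_mean(x[, cols, drop = FALSE], w)
  }
  ref <- colMeans(x[reference_cells, , drop = FALSE])
  x <- sweep(x, 2L, ref, "-")
  structure(list(dev = x, genes = gp, reference_cells = reference_cells),
            class = "cnv_profile")
}

#' Per-cell CNV score
#'
#' `log1p` of the mean squared deviation over all profiled genes: 0 for an
#' exactly neutral profile and increasing with copy-number load.
#'
#' @param profile a [infer_cnv()] result (or a deviation matrix).
#' @return named numeric vector of scores.
#' @export
cnv_score <- function(profile) {
  dev <- if (is.list(profile)) profile$dev else profile
  log1p(rowMeans(dev^2))
}

#' Cluster CNV profiles hierarchically
#'
#' Agglomerative clustering (Ward linkage on Euclidean distances) of the
#' deviation matrix; deterministic.
#'
#' @param profile a [infer_cnv()] result.
#' @param k number of clusters.
#' @param cells optional subset of barcodes (e.g. putative malignant cells).
#' @return factor of cluster labels (`HCL1`, `HCL2`, ...) named by barcode.
#' @export
cluster_cnv_profiles <- function(profile, k, cells = NULL) {
  dev <- profile$dev
  if (!is.null(cells)) dev <- dev[cells, , drop = FALSE]
  .assert(nrow(dev) >= 2, "need at least 2 cells")
  .assert(k <= nrow(dev), "k exceeds the number of cells")
  hc <- hclust(dist(dev), method = "ward.D2")
  labels <- factor(paste0("HCL", cutree(hc, k = k)),
                   levels = paste0("HCL", seq_len(k)))
  names(labels) <- rownames(dev)
  labels
}

#' Call malignant cells from CNV scores
#'
#' A cell is called malignant when its own score exceeds the `q` quantile of
#' the reference scores and its CNV cluster's mean score does too; the
#' conjunction suppresses isolated noisy cells inside quiet clusters.
#'
#' @param scores named per-cell scores from [cnv_score()].
#' @param reference_scores scores of the reference cells.
#' @param clusters cluster labels per scored cell (e.g.
#'   [cluster_cnv_profiles()]); when `NULL` only the per-cell rule applies.
#' @param q reference quantile (default 0.99).
#' @return data.frame (barcode, score, cell_pass, cluster_pass, is_malignant).
#' @export
call_malignant <- function(scores, reference_scores, clusters = NULL, q = 0.99) {
  .assert(length(reference_scores) > 0, "reference scores must be nonempty")
  thr <- quantile(reference_scores, q, names = FALSE)
  if (max(reference_scores) == min(reference_scores)) {
    warning("degenerate reference scores; threshold set just above the common value")
    thr <- thr + 1e-9
  }
  cell_pass <- scores > thr
  if (is.null(clusters)) {
    cluster_pass <- rep(TRUE, length(scores))
  } else {
    cl_mean <- tapply(scores, clusters[names(scores)], mean)
    cluster_pass <- cl_mean[as.character(clusters[names(scores)])] > thr
  }
  data.frame(barcode = names(scores), score = as.numeric(scores),
             cell_pass = as.logical(cell_pass),
             cluster_pass = as.logical(cluster_pass),
             is_malignant = as.logical(cell_pass & cluster_pass),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Call copy-number events per subclone
#'
#' Within each subclone (CNV cluster), contiguous runs of at least
#' `min_span_genes` genes whose mean deviation exceeds `gain_threshold` (or
#' falls below `loss_threshold`) become gain (loss) events. Each event
#' reports the percentage of the subclone's cells whose own mean deviation
#' over the span passes half the threshold; events above 90% carriage are
#' canonical, the rest noncanonical.
#'
#' @param profile a [infer_cnv()] result.
#' @param subclone_of_cell labels (e.g. CNV clusters) for the cells to scan;
#'   cells absent from the profile are ignored.
#' @param gain_threshold,loss_threshold mean-deviation thresholds.
#' @param min_span_genes minimum run length in genes.
#' @param canonical_percent carriage percentage above which an event is
#'   canonical (default 90).
#' @return data.frame of events: event_id, subclone, chrom, start_index,
#'   end_index (positions in the profile's gene order), n_genes, direction,
#'   mean_dev, cell_percent, canonical.
#' @export
call_events <- function(profile, subclone_of_cell, gain_threshold = 0.15,
                        loss_threshold = -0.15, min_span_genes = 30,
                        canonical_percent = 90) {
  dev <- profile$dev
  gp <- profile$genes
  subclone_of_cell <- subclone_of_cell[names(subclone_of_cell) %in% rownames(dev)]
  out <- list()
  for (sc in sort(unique(as.character(subclone_of_cell)))) {
    cells <- names(subclone_of_cell)[subclone_of_cell == sc]
    m <- colMeans(dev[cells, , drop = FALSE])
    state <- ifelse(m > gain_threshold, 1L, ifelse(m < loss_threshold, -1L, 0L))
    for (ch in unique(gp$chrom)) {
      cols <- which(gp$chrom == ch)
      r <- rle(state[cols])
      ends <- cumsum(r$lengths)
      starts <- ends - r$lengths + 1L
      for (i in seq_along(r$values)) {
        if (r$values[i] == 0L || r$lengths[i] < min_span_genes) next
        span <- cols[starts[i]:ends[i]]
        dirn <- if (r$values[i] > 0) "gain" else "loss"
        cell_mean <- rowMeans(dev[cells, span, drop = FALSE])
        carry <- if (dirn == "gain") cell_mean > gain_threshold / 2 else
          cell_mean < loss_threshold / 2
        pct <- 100 * mean(carry)
        out[[length(out) + 1L]] <- data.frame(
          subclone = sc, chrom = ch, start_index = span[1L],
          end_index = span[length(span)], n_genes = length(span),
          direction = dirn, mean_dev = mean(m[span]), cell_percent = pct,
          canonical = pct > canonical_percent, stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(out))
    return(data.frame(event_id = character(), subclone = character(),
                      chrom = character(), start_index = integer(),
                      end_index = integer(), n_genes = integer(),
                      direction = character(), mean_dev = numeric(),
                      cell_percent = numeric(), canonical = logical(),
                      stringsAsFactors = FALSE))
  ev <- do.call(rbind, out)
  ev$event_id <- .match_event_ids(ev)
  ev[, c("event_id", "subclone", "chrom", "start_index", "end_index",
         "n_genes", "direction", "mean_dev", "cell_percent", "canonical")]
}

# Events from different subclones describe the same genomic lesion when they
# share chromosome and direction and overlap by at least half of the smaller
# span; shared lesions get one id via single-linkage grouping.
.match_event_ids <- function(ev) {
  n <- nrow(ev)
  group <- seq_len(n)
  find <- function(i) { while (group[i] != i) i <- group[i]; i }
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (j <= i) next
    if (ev$chrom[i] != ev$chrom[j] || ev$direction[i] != ev$direction[j]) next
    ov <- min(ev$end_index[i], ev$end_index[j]) -
      max(ev$start_index[i], ev$start_index[j]) + 1L
    if (ov >= 0.5 * min(ev$n_genes[i], ev$n_genes[j]))
      group[find(j)] <- find(i)
  }
  root <- vapply(seq_len(n), find, 0L)
  vapply(seq_len(n), function(i) {
    members <- which(root == root[i])
    sprintf("%s:%s:%d-%d", ev$chrom[i], ev$direction[i],
            min(ev$start_index[members]), max(ev$end_index[members]))
  }, "")
}

#' Build a clonality tree from subclone CNV events
#'
#' Events shared by every subclone form the trunk; below it, subclones are
#' nested greedily by shared remaining events (the event carried by the most
#' subclones defines each split). Branches record the events acquired on
#' them with their carriage percentage and canonical flag. Event sets that
#' violate perfect-phylogeny containment are attached at the deepest
#' compatible node and the offending events are flagged, never an error.
#'
#' @param events a [call_events()] table.
#' @param subclone_sizes named integer vector: cells per subclone.
#' @return list of class `clonality_tree` with `root` (nested nodes carrying
#'   `name`, `cell_count`, `events_acquired`, `children`), `conflicts`
#'   (event ids acquired on more than one branch), and `events`.
#' @export
build_clonality_tree <- function(events, subclone_sizes) {
  subs <- names(subclone_sizes)
  sets <- lapply(subs, function(s) unique(events$event_id[events$subclone == s]))
  names(sets) <- subs
  ev_info <- events[!duplicated(paste(events$event_id, events$subclone)), ]

  event_rows <- function(sc, ids) {
    if (!length(ids)) return(ev_info[0, ])
    rows <- ev_info[ev_info$subclone == sc & ev_info$event_id %in% ids, ]
    rows[match(ids, rows$event_id), ]
  }
  build <- function(members, inherited) {
    common <- Reduce(intersect, sets[members])
    acquired <- setdiff(common, inherited)
    node <- list(name = if (length(members) == 1L) members else
                   paste(members, collapse = "+"),
                 subclones = members,
                 cell_count = sum(subclone_sizes[members]),
                 events_acquired = event_rows(members[1L], acquired),
                 children = list())
    if (length(members) == 1L) return(node)
    remaining <- members
    seen <- union(inherited, common)
    while (length(remaining) > 0L) {
      pool <- lapply(sets[remaining], setdiff, y = seen)
      counts <- table(unlist(pool))
      if (!length(counts)) {  # nothing shared: each remaining subclone a leaf
        for (s in remaining)
          node$children[[length(node$children) + 1L]] <- build(s, seen)
        break
      }
      counts <- counts[order(-as.numeric(counts), names(counts))]
      e <- names(counts)[1L]
      grp <- remaining[vapply(pool, function(x) e %in% x, TRUE)]
      if (!length(grp)) grp <- remaining[1L]
      node$children[[length(node$children) + 1L]] <- build(grp, seen)
      remaining <- setdiff(remaining, grp)
    }
    node
  }
  root <- list(name = "root", subclones = subs,
               cell_count = sum(subclone_sizes),
               events_acquired = ev_info[0, ], children = list())
  if (length(subs)) root$children <- list(build(subs, character()))
  # an event acquired on more than one branch breaks perfect phylogeny
  acq <- character()
  walk <- function(nd) {
    acq <<- c(acq, nd$events_acquired$event_id)
    for (ch in nd$children) walk(ch)
  }
  walk(root)
  conflicts <- unique(acq[duplicated(acq)])
  structure(list(root = root, conflicts = conflicts, events = events),
            class = "clonality_tree")
}

#' Serialize a clonality tree to Newick
#'
#' Branch labels are the acquired event ids joined by `|`; branch length is
#' the number of events acquired on the branch.
#'
#' @param tree a [build_clonality_tree()] result.
#' @return single-element character vector (Newick string).
#' @export
tree_newick <- function(tree) {
  lab <- function(nd) {
    ids <- nd$events_acquired$event_id
    nm <- gsub("[,;:() ]", "_", nd$name)
    if (length(ids)) paste0(nm, "/", paste(gsub("[,;:()]", "_", ids),
                                           collapse = "|")) else nm
  }
  rec <- function(nd) {
    if (!length(nd$children))
      return(sprintf("%s:%d", lab(nd), nrow(nd$events_acquired)))
    sprintf("(%s)%s:%d", paste(vapply(nd$children, rec, ""), collapse = ","),
            lab(nd), nrow(nd$events_acquired))
  }
  paste0(rec(tree$root), ";")
}

#' Serialize a clonality tree to JSON
#'
#' @param tree a [build_clonality_tree()] result.
#' @param path optional output file; the JSON string is returned invisibly.
#' @return JSON string.
#' @export
tree_json <- function(tree, path = NULL) {
  strip <- function(nd) {
    list(name = nd$name, cell_count = nd$cell_count,
         events = nd$events_acquired[, intersect(
           c("event_id", "direction", "cell_percent", "canonical"),
           names(nd$events_acquired))],
         children = lapply(nd$children, strip))
  }
  js <- jsonlite::toJSON(list(root = strip(tree$root),
                              conflicts = tree$conflicts),
                         auto_unbox = TRUE, digits = NA, null = "null")
  if (!is.null(path)) writeLines(js, path)
  invisible(js)
}
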