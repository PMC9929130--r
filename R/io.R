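#' Read a 10x-style Matrix Market triplet directory
#'
#' Expects `matrix.mtx` (genes x cells, the 10x convention), `features.tsv`
#' (gene ids, optionally symbols) and `barcodes.tsv`. The matrix is returned
#' transposed to cells x genes, the orientation used throughout this package.
#'
#' @param dir directory containing the three files.
#' @return sparse cells x genes matrix with barcode rownames, gene colnames.
#' @export
read_10x <- function(dir) {
  m <- Matrix::readMM(file.path(dir, "matrix.mtx"))
  feats <- read.delim(file.path(dir, "features.tsv"), header = FALSE,
                      stringsAsFactors = FALSE)
  bcs <- read.delim(file.path(dir, "barcodes.tsv"), header = FALSE,
                    stringsAsFactors = FALSE)[, 1L]
  .assert(nrow(m) == nrow(feats), "features.tsv does not match matrix rows")
  .assert(ncol(m) == length(bcs), "barcodes.tsv does not match matrix columns")
  m <- .as_sparse(Matrix::t(m))
  dimnames(m) <- list(bcs, feats[, 1L])
  m
}

#' Write a count matrix as a 10x-style triplet
#'
#' @param counts cells x genes matrix; written transposed (genes x cells).
#' @param dir output directory, created if needed.
#' @export
write_10x <- function(counts, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  Matrix::writeMM(.as_sparse(Matrix::t(counts)), file.path(dir, "matrix.mtx"))
  write.table(data.frame(colnames(counts), colnames(counts)),
              file.path(dir, "features.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE, col.names = FALSE)
  write.table(rownames(counts), file.path(dir, "barcodes.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(dir)
}

#' Write a simulated cohort to disk
#'
#' Emits the 10x triplet, the gene-position table (`genes.tsv`), the
#' ground-truth table keyed by barcode (`truth.tsv`, including per-program
#' activity columns), and the configuration as JSON.
#'
#' @param sim result of [simulate_counts()].
#' @param dir output directory.
#' @export
write_sim <- function(sim, dir) {
  write_10x(sim$counts, dir)
  write.table(sim$gene_info, file.path(dir, "genes.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  truth <- sim$cell_info
  act <- sim$truth$program_activity
  if (ncol(act) > 0)
    truth <- cbind(truth, as.data.frame(act)[match(truth$barcode, rownames(act)), ,
                                             drop = FALSE])
  write.table(truth, file.path(dir, "truth.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  jsonlite::write_json(unclass(sim$truth$config), file.path(dir, "config.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(dir)
}

#' Read a gene-position table
#'
#' @param path TSV with columns `gene`, `chrom`, `start` (0-based).
#' @return data.frame of gene positions.
#' @export
read_gene_positions <- function(path) {
  gp <- read.delim(path, stringsAsFactors = FALSE)
  .assert(all(c("gene", "chrom", "start") %in% names(gp)),
          "gene position table needs columns gene, chrom, start")
  gp
}

#' Read gene sets from a two-column TSV or a JSON mapping
#'
#' TSV input needs columns `set` and `gene` (header optional as long as the
#' first two columns are set name then gene); JSON input is a map from set
#' name to a gene array.
#'
#' @param path file path.
#' @return named list of character vectors.
#' @export
read_gene_sets <- function(path) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    sets <- jsonlite::read_json(path, simplifyVector = TRUE)
    return(lapply(sets, as.character))
  }
  df <- read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("set", "gene") %in% names(df))) {
    df <- read.delim(path, header = FALSE, stringsAsFactors = FALSE)
    names(df)[1:2] <- c("set", "gene")
  }
  split(as.character(df$gene), df$set)
}
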