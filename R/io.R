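# Readers and writers for the plain-text interchange formats used by the
# pipeline: Matrix Market counts with gene/cell TSV sidecars, and TSV tables
# for lineage/homology/CNV/variant/clinical inputs and all outputs.

#' Write a counts container to a Matrix Market directory
#'
#' Writes `matrix.mtx` plus `genes.tsv` (gene_id, symbol, chrom, start, end;
#' 0-based half-open coordinates) and `cells.tsv` (cell_id, sample_id,
#' platform).
#'
#' @param x `tam_counts` object.
#' @param dir output directory, created if missing.
#' @return `dir`, invisibly.
#' @export
write_counts_mtx <- function(x, dir) {
  stopifnot(inherits(x, "tam_counts"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  Matrix::writeMM(x$counts, file.path(dir, "matrix.mtx"))
  write_tsv_file(x$genes, file.path(dir, "genes.tsv"))
  write_tsv_file(x$cells, file.path(dir, "cells.tsv"))
  invisible(dir)
}

#' Read a counts container from a Matrix Market directory
#'
#' @param dir directory holding `matrix.mtx`, `genes.tsv`, `cells.tsv` as
#'   written by [write_counts_mtx()].
#' @return A `tam_counts` object.
#' @export
read_counts_mtx <- function(dir) {
  m <- Matrix::readMM(file.path(dir, "matrix.mtx"))
  genes <- read_tsv_file(file.path(dir, "genes.tsv"))
  cells <- read_tsv_file(file.path(dir, "cells.tsv"))
  tam_counts(m, genes, cells)
}

#' Write a data frame as tab-separated text
#'
#' @param df data frame.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_tsv_file <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a tab-separated table written by [write_tsv_file()]
#'
#' @param path input file.
#' @return A data frame (strings kept as character).
#' @export
read_tsv_file <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
}

#' Write a bulk cohort as a pair of TSV files
#'
#' @param cohort `bulk_cohort` object.
#' @param expr_path,clinical_path output files for the sample-by-gene matrix
#'   and the survival/covariate/subtype annotation.
#' @return `expr_path`, invisibly.
#' @export
write_bulk_cohort <- function(cohort, expr_path, clinical_path) {
  stopifnot(inherits(cohort, "bulk_cohort"))
  df <- data.frame(sample_id = rownames(cohort$expr),
                   as.data.frame(cohort$expr, check.names = FALSE),
                   check.names = FALSE)
  write_tsv_file(df, expr_path)
  write_tsv_file(cohort$clinical, clinical_path)
  invisible(expr_path)
}

#' Read a bulk cohort from TSV files
#'
#' @param expr_path,clinical_path files written by [write_bulk_cohort()].
#' @return A `bulk_cohort` object.
#' @export
read_bulk_cohort <- function(expr_path, clinical_path) {
  df <- read_tsv_file(expr_path)
  clinical <- read_tsv_file(clinical_path)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  bulk_cohort(m[match(clinical$sample_id, rownames(m)), , drop = FALSE], clinical)
}

#' Write a regional atlas as TSV
#'
#' @param atlas `regional_atlas` object.
#' @param path output file; the first three columns are `sample_id`,
#'   `structure`, `tumor_id`, followed by one column per gene.
#' @return `path`, invisibly.
#' @export
write_regional_atlas <- function(atlas, path) {
  stopifnot(inherits(atlas, "regional_atlas"))
  df <- data.frame(sample_id = rownames(atlas$values) %||%
                     paste0("RS", seq_len(nrow(atlas$values))),
                   structure = atlas$structure,
                   tumor_id = atlas$tumor_id,
                   as.data.frame(atlas$values, check.names = FALSE),
                   check.names = FALSE)
  write_tsv_file(df, path)
  invisible(path)
}

#' Read a regional atlas from TSV
#'
#' @param path file written by [write_regional_atlas()].
#' @return A `regional_atlas` object.
#' @export
read_regional_atlas <- function(path) {
  df <- read_tsv_file(path)
  m <- as.matrix(df[, -(1:3), drop = FALSE])
  rownames(m) <- df$sample_id
  regional_atlas(m, df$structure, df$tumor_id)
}
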