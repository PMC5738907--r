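#' Single-cell counts container
#'
#' Bundles a sparse gene-by-cell integer count matrix with its gene and cell
#' annotation tables. Gene coordinates are 0-based half-open, synthesized or
#' read from the `genes.tsv` sidecar of a Matrix Market directory.
#'
#' @param counts gene-by-cell matrix of non-negative integer counts
#'   (coerced to a sparse `dgCMatrix`).
#' @param genes `data.frame` with columns `gene_id`, `symbol`, `chrom`,
#'   `start`, `end`; one row per matrix row.
#' @param cells `data.frame` with columns `cell_id`, `sample_id`, `platform`;
#'   one row per matrix column.
#'
#' @return An object of class `tam_counts`: a list with elements `counts`,
#'   `genes`, `cells`.
#' @export
tam_counts <- function(counts, genes, cells) {
  counts <- methods::as(methods::as(methods::as(counts, "dMatrix"), "generalMatrix"),
                        "CsparseMatrix")
  need_g <- c("gene_id", "symbol", "chrom", "start", "end")
  need_c <- c("cell_id", "sample_id", "platform")
  if (!all(need_g %in% names(genes))) {
    stop("`genes` must have columns: ", paste(need_g, collapse = ", "))
  }
  if (!all(need_c %in% names(cells))) {
    stop("`cells` must have columns: ", paste(need_c, collapse = ", "))
  }
  if (nrow(genes) != nrow(counts) || nrow(cells) != ncol(counts)) {
    stop("dimension mismatch between counts and gene/cell tables")
  }
  if (anyDuplicated(genes$gene_id)) stop("duplicate gene ids")
  if (anyDuplicated(cells$cell_id)) stop("duplicate cell ids")
  if (any(counts@x < 0)) stop("counts must be non-negative")
  if (any(genes$start >= genes$end)) stop("gene coordinates must satisfy start < end")
  rownames(counts) <- genes$gene_id
  colnames(counts) <- cells$cell_id
  structure(list(counts = counts, genes = as.data.frame(genes),
                 cells = as.data.frame(cells)),
            class = "tam_counts")
}

#' @export
dim.tam_counts <- function(x) dim(x$counts)

#' @export
print.tam_counts <- function(x, ...) {
  cat(sprintf("<tam_counts> %d genes x %d cells; platforms: %s\n",
              nrow(x$counts), ncol(x$counts),
              paste(unique(x$cells$platform), collapse = ", ")))
  invisible(x)
}

#' Subset a counts container
#'
#' @param x `tam_counts` object.
#' @param i,j gene and cell indices (any standard matrix index type).
#' @param ... ignored.
#' @export
`[.tam_counts` <- function(x, i, j, ...) {
  if (missing(i)) i <- seq_len(nrow(x$counts))
  if (missing(j)) j <- seq_len(ncol(x$counts))
  gi <- stats::setNames(seq_len(nrow(x$counts)), rownames(x$counts))[i]
  ci <- stats::setNames(seq_len(ncol(x$counts)), colnames(x$counts))[j]
  if (is.logical(i)) gi <- which(i)
  if (is.logical(j)) ci <- which(j)
  if (is.numeric(i)) gi <- seq_len(nrow(x$counts))[i]
  if (is.numeric(j)) ci <- seq_len(ncol(x$counts))[j]
  tam_counts(x$counts[gi, ci, drop = FALSE],
             x$genes[gi, , drop = FALSE],
             x$cells[ci, , drop = FALSE])
}

#' Expression matrix with a scale tag
#'
#' Same axes as [tam_counts()] but holding transformed values. The `scale`
#' tag records which transform produced the values and is checked by every
#' downstream operation: `"cpm"` (counts per million), `"logcpm"`
#' (log2(CPM/10 + 1)) or `"z"` (per-platform z-scores of log values).
#'
#' @param values gene-by-cell numeric matrix (sparse or dense).
#' @param genes,cells annotation tables as in [tam_counts()].
#' @param scale one of `"cpm"`, `"logcpm"`, `"z"`.
#' @param flagged_genes optional character vector of genes flagged during the
#'   transform (e.g. zero-variance genes set to 0 by z-scoring).
#'
#' @return An object of class `tam_expr`.
#' @export
tam_expr <- function(values, genes, cells, scale = c("cpm", "logcpm", "z"),
                     flagged_genes = character()) {
  scale <- match.arg(scale)
  if (nrow(genes) != nrow(values) || nrow(cells) != ncol(values)) {
    stop("dimension mismatch between values and gene/cell tables")
  }
  rownames(values) <- genes$gene_id
  colnames(values) <- cells$cell_id
  structure(list(values = values, genes = as.data.frame(genes),
                 cells = as.data.frame(cells), scale = scale,
                 flagged_genes = flagged_genes),
            class = "tam_expr")
}

#' @export
dim.tam_expr <- function(x) dim(x$values)

#' @export
print.tam_expr <- function(x, ...) {
  cat(sprintf("<tam_expr:%s> %d genes x %d cells\n", x$scale,
              nrow(x$values), ncol(x$values)))
  invisible(x)
}

#' @export
`[.tam_expr` <- function(x, i, j, ...) {
  if (missing(i)) i <- seq_len(nrow(x$values))
  if (missing(j)) j <- seq_len(ncol(x$values))
  if (is.logical(i)) i <- which(i)
  if (is.logical(j)) j <- which(j)
  if (is.character(i)) i <- match(i, rownames(x$values))
  if (is.character(j)) j <- match(j, colnames(x$values))
  tam_expr(x$values[i, j, drop = FALSE],
           x$genes[i, , drop = FALSE],
           x$cells[j, , drop = FALSE],
           scale = x$scale,
           flagged_genes = x$flagged_genes)
}

#' Bulk expression cohort with clinical annotation
#'
#' @param expr sample-by-gene numeric matrix on the log2(CPM + 1) scale.
#' @param clinical `data.frame` with columns `sample_id`, `time` (days),
#'   `event` (0/1), `age` (years), `gender`, `subtype`; one row per sample,
#'   aligned with `expr` rows.
#'
#' @return An object of class `bulk_cohort`.
#' @export
bulk_cohort <- function(expr, clinical) {
  need <- c("sample_id", "time", "event", "age", "gender", "subtype")
  if (!all(need %in% names(clinical))) {
    stop("`clinical` must have columns: ", paste(need, collapse = ", "))
  }
  if (nrow(expr) != nrow(clinical)) stop("expr and clinical sample counts differ")
  if (any(clinical$time <= 0)) stop("survival times must be positive")
  if (!all(clinical$event %in% c(0, 1))) stop("event must be 0/1")
  rownames(expr) <- clinical$sample_id
  structure(list(expr = expr, clinical = as.data.frame(clinical)),
            class = "bulk_cohort")
}

#' @export
print.bulk_cohort <- function(x, ...) {
  cat(sprintf("<bulk_cohort> %d samples x %d genes; %d events\n",
              nrow(x$expr), ncol(x$expr), sum(x$clinical$event)))
  invisible(x)
}

#' Regional expression atlas
#'
#' Sample-by-gene expression from microdissected tumor compartments, on the
#' per-gene z-score scale, with an anatomic structure label and tumor id per
#' sample.
#'
#' @param values sample-by-gene numeric matrix (z-scores per gene across
#'   samples).
#' @param structure character vector of structure labels, one per sample.
#' @param tumor_id character vector of tumor ids, one per sample.
#'
#' @return An object of class `regional_atlas`.
#' @export
regional_atlas <- function(values, structure, tumor_id) {
  if (length(structure) != nrow(values) || length(tumor_id) != nrow(values)) {
    stop("structure/tumor_id length must match sample count")
  }
  if (length(unique(structure)) < 2) stop("at least 2 structures required")
  structure(list(values = values, structure = as.character(structure),
                 tumor_id = as.character(tumor_id)),
            class = "regional_atlas")
}

#' @export
print.regional_atlas <- function(x, ...) {
  cat(sprintf("<regional_atlas> %d samples x %d genes; %d structures\n",
              nrow(x$values), ncol(x$values), length(unique(x$structure))))
  invisible(x)
}

#' Lineage signature gene set
#'
#' @param gene character vector of human gene symbols.
#' @param lineage `"blood"` or `"microglia"` per gene.
#' @param loading rotated PC1 loading per gene.
#' @param threshold absolute-loading threshold used for extraction.
#' @param orientation_p Fisher p value of the enrichment test that fixed the
#'   lineage orientation of the axis.
#'
#' @return A `data.frame` of class `signature_gene_set` with columns `gene`,
#'   `lineage`, `loading` and attributes `threshold`, `orientation_p`.
#' @export
signature_gene_set <- function(gene, lineage, loading, threshold = NA_real_,
                               orientation_p = NA_real_) {
  stopifnot(length(gene) == length(lineage), length(gene) == length(loading))
  if (!all(lineage %in% c("blood", "microglia"))) {
    stop("lineage must be 'blood' or 'microglia'")
  }
  out <- data.frame(gene = as.character(gene), lineage = as.character(lineage),
                    loading = as.double(loading), stringsAsFactors = FALSE)
  attr(out, "threshold") <- threshold
  attr(out, "orientation_p") <- orientation_p
  class(out) <- c("signature_gene_set", "data.frame")
  out
}
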