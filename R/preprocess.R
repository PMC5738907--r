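# Quality filtering, normalization, and TAM vs neoplastic cell
# classification from marker expression, expressed somatic mutations and
# copy-number evidence.

#' Default macrophage marker panel
#'
#' Canonical myeloid/macrophage markers used to call TAMs. The panel is a
#' configurable input, not a constant of the method.
#'
#' @return Character vector of gene symbols.
#' @export
default_marker_panel <- function() {
  c("PTPRC", "ITGAM", "AIF1", "CD14", "CSF1R", "HLA-DRA")
}

#' Scale counts to counts per million
#'
#' Each retained cell's values sum to 1e6; zero counts map to zero. Cells
#' with no counts at all cannot be scaled: they are excluded with a warning
#' and listed in the `excluded_cells` attribute.
#'
#' @param counts a [tam_counts()] object.
#' @return A `tam_expr` object on the `"cpm"` scale.
#' @export
cpm_normalize <- function(counts) {
  stopifnot(inherits(counts, "tam_counts"))
  tot <- Matrix::colSums(counts$counts)
  bad <- tot == 0
  if (any(bad)) {
    warning(sprintf("excluding %d all-zero cell(s): %s", sum(bad),
                    paste(utils::head(counts$cells$cell_id[bad], 5), collapse = ", ")))
  }
  keep <- which(!bad)
  m <- counts$counts[, keep, drop = FALSE] %*%
    Matrix::Diagonal(x = 1e6 / tot[keep])
  colnames(m) <- counts$cells$cell_id[keep]
  out <- tam_expr(m, counts$genes, counts$cells[keep, , drop = FALSE], scale = "cpm")
  attr(out, "excluded_cells") <- counts$cells$cell_id[bad]
  out
}

#' Filter low-quality cells
#'
#' Retains cells detecting at least `min_genes` genes and carrying at least
#' `min_reads` aligned reads; both boundaries are inclusive. When no
#' alignment metadata exists, the total count of a cell stands in for its
#' uniquely aligned reads (a monotone proxy).
#'
#' @param counts a [tam_counts()] object.
#' @param min_genes minimum genes detected (count > 0).
#' @param min_reads minimum total reads.
#' @return A list with `counts` (the retained cells) and `qc`, a per-cell
#'   record (`cell_id`, `genes_detected`, `aligned_reads`, `passed`) covering
#'   every input cell.
#' @export
filter_cells <- function(counts, min_genes = 800, min_reads = 50000) {
  stopifnot(inherits(counts, "tam_counts"))
  if (min_genes < 0 || min_reads < 0) stop("thresholds must be >= 0")
  genes_detected <- Matrix::colSums(counts$counts > 0)
  aligned_reads <- Matrix::colSums(counts$counts)
  passed <- genes_detected >= min_genes & aligned_reads >= min_reads
  qc <- data.frame(cell_id = counts$cells$cell_id,
                   genes_detected = as.integer(genes_detected),
                   aligned_reads = as.numeric(aligned_reads),
                   passed = as.logical(passed),
                   stringsAsFactors = FALSE)
  keep <- which(passed)
  kept <- tam_counts(counts$counts[, keep, drop = FALSE],
                     counts$genes, counts$cells[keep, , drop = FALSE])
  list(counts = kept, qc = qc)
}

#' Quantify planted or called CNV segments in single cells
#'
#' For each cell and segment, the score is the mean over the segment's genes
#' of the cell's log expression centered and scaled by a set of control
#' (non-malignant) cells:
#' `score(c, s) = mean_g (x[g, c] - mean_ctrl[g]) / max(sd_ctrl[g], sd_floor)`.
#' Segments overlapped by fewer than `min_genes` measured genes are reported
#' as `NA`.
#'
#' @param expr a `tam_expr` on a log scale (`"logcpm"` or `"z"`).
#' @param segments CNV segment table (`chrom`, `start`, `end`, `direction`),
#'   0-based half-open.
#' @param control_cells cell ids to use as the non-malignant reference.
#' @param min_genes minimum measured genes per segment.
#' @param sd_floor lower bound for the per-gene control SD (guards against
#'   division blow-ups on low-variance genes).
#' @return A cells-by-segments numeric matrix of scores; segment directions
#'   are carried in the `directions` attribute.
#' @export
quantify_cnv_in_cells <- function(expr, segments, control_cells,
                                  min_genes = 5, sd_floor = 0.1) {
  stopifnot(inherits(expr, "tam_expr"))
  if (!expr$scale %in% c("logcpm", "z")) stop("expr must be on a log scale")
  if (length(control_cells) == 0) stop("control_cells must be non-empty")
  ctrl <- match(control_cells, expr$cells$cell_id)
  if (anyNA(ctrl)) stop("unknown control cell ids")
  x <- as.matrix(expr$values)
  seg_genes <- lapply(seq_len(nrow(segments)), function(k) {
    which(expr$genes$chrom == segments$chrom[k] &
            expr$genes$start < segments$end[k] &
            expr$genes$end > segments$start[k])
  })
  if (all(lengths(seg_genes) == 0)) stop("no genes overlap any segment")
  mu <- rowMeans(x[, ctrl, drop = FALSE])
  sd_ctrl <- pmax(apply(x[, ctrl, drop = FALSE], 1, stats::sd), sd_floor)
  scores <- matrix(NA_real_, nrow = ncol(x), ncol = nrow(segments),
                   dimnames = list(expr$cells$cell_id,
                                   sprintf("seg%02d", seq_len(nrow(segments)))))
  for (k in seq_len(nrow(segments))) {
    g <- seg_genes[[k]]
    if (length(g) < min_genes) next
    z <- (x[g, , drop = FALSE] - mu[g]) / sd_ctrl[g]
    scores[, k] <- colMeans(z)
  }
  attr(scores, "directions") <- segments$direction
  scores
}

#' Classify cells as TAM, neoplastic or unassigned
#'
#' A cell is called neoplastic if it shows at least one variant-supported
#' SNV (`alt_count >= min_alt`), or if its copy-number evidence is strong:
#' mean absolute segment score above `cnv_tau` with sign concordance to the
#' called segment directions of at least `cnv_kappa`. A non-neoplastic cell
#' is called TAM when its mean log marker expression exceeds
#' `marker_threshold`; remaining cells are unassigned.
#'
#' @param expr a `tam_expr` on the `"logcpm"` scale.
#' @param markers marker gene symbols; unknown genes are skipped with a
#'   warning, and an error is raised if none are present.
#' @param variants variant allele table (`variant_id`, `cell_id`,
#'   `ref_count`, `alt_count`); may be `NULL`.
#' @param cnv_scores cells-by-segments matrix from
#'   [quantify_cnv_in_cells()]; may be `NULL`.
#' @param min_alt minimum alt reads for a variant to count as expressed.
#' @param cnv_tau mean |score| threshold for CNV evidence.
#' @param cnv_kappa minimum fraction of scored segments whose score sign
#'   matches the called direction.
#' @param marker_threshold mean log2(CPM/10 + 1) marker expression above
#'   which a non-neoplastic cell is a TAM.
#' @return A `data.frame` (class `cell_annotation`) with one row per cell:
#'   `cell_id`, `class`, `marker_score`, `n_expressed_snvs`,
#'   `mean_abs_cnv`, `cnv_concordance`.
#' @export
classify_cells <- function(expr, markers, variants = NULL, cnv_scores = NULL,
                           min_alt = 2, cnv_tau = 0.5, cnv_kappa = 2 / 3,
                           marker_threshold = 1.0) {
  stopifnot(inherits(expr, "tam_expr"))
  if (expr$scale != "logcpm") stop("expr must be on the logcpm scale")
  if (length(markers) == 0) stop("marker set must be non-empty")
  hit <- match(markers, expr$genes$symbol)
  if (anyNA(hit)) {
    warning("markers absent from matrix, skipped: ",
            paste(markers[is.na(hit)], collapse = ", "))
    hit <- hit[!is.na(hit)]
  }
  if (length(hit) == 0) stop("none of the marker genes are present")
  marker_score <- Matrix::colMeans(expr$values[hit, , drop = FALSE])

  ids <- expr$cells$cell_id
  n_snv <- integer(length(ids))
  if (!is.null(variants) && nrow(variants) > 0) {
    v <- variants[variants$alt_count >= min_alt, , drop = FALSE]
    tab <- table(factor(v$cell_id, levels = ids))
    n_snv <- as.integer(tab)
  }
  mean_abs <- rep(NA_real_, length(ids))
  concord <- rep(NA_real_, length(ids))
  if (!is.null(cnv_scores) && ncol(cnv_scores) > 0) {
    sc <- cnv_scores[match(ids, rownames(cnv_scores)), , drop = FALSE]
    dirs <- attr(cnv_scores, "directions")
    sign_expect <- ifelse(dirs == "amp", 1, -1)
    mean_abs <- rowMeans(abs(sc), na.rm = TRUE)
    match_dir <- sweep(sign(sc), 2, sign_expect, `==`)
    concord <- rowMeans(match_dir, na.rm = TRUE)
    mean_abs[is.nan(mean_abs)] <- NA_real_
    concord[is.nan(concord)] <- NA_real_
  }
  cnv_call <- !is.na(mean_abs) & !is.na(concord) &
    mean_abs > cnv_tau & concord >= cnv_kappa
  neoplastic <- n_snv >= 1 | cnv_call
  class <- ifelse(neoplastic, "neoplastic",
                  ifelse(marker_score > marker_threshold, "TAM", "unassigned"))
  out <- data.frame(cell_id = ids, class = class,
                    marker_score = as.numeric(marker_score),
                    n_expressed_snvs = n_snv,
                    mean_abs_cnv = mean_abs,
                    cnv_concordance = concord,
                    stringsAsFactors = FALSE)
  class(out) <- c("cell_annotation", "data.frame")
  out
}
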