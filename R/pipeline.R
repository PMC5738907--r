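# End-to-end orchestration: QC and cell annotation, then signature
# derivation on the retained TAMs.

#' Annotate cells of a cohort as TAM, neoplastic or unassigned
#'
#' Runs the preprocessing chain: QC filtering, CPM and log transforms,
#' provisional control-cell selection (marker-positive cells without
#' variant-supported SNVs stand in for a non-malignant reference),
#' CNV quantification against the controls, and the final classification
#' from marker, SNV and CNV evidence.
#'
#' @param counts a [tam_counts()] object.
#' @param cnv CNV segment table (`chrom`, `start`, `end`, `direction`); may
#'   be `NULL`.
#' @param variants variant allele table; may be `NULL`.
#' @param markers marker gene panel.
#' @param min_genes,min_reads QC thresholds, see [filter_cells()].
#' @param ... further thresholds passed to [classify_cells()].
#' @return A list: `annotation` ([classify_cells()] output for QC-passing
#'   cells), `qc`, `counts` (QC-passing cells), `expr_cpm`, `expr_log`,
#'   `cnv_scores`, `control_cells`.
#' @export
annotate_cells <- function(counts, cnv = NULL, variants = NULL,
                           markers = default_marker_panel(),
                           min_genes = 800, min_reads = 50000, ...) {
  flt <- filter_cells(counts, min_genes = min_genes, min_reads = min_reads)
  expr_cpm <- cpm_normalize(flt$counts)
  expr_log <- log_transform(expr_cpm)

  cnv_scores <- NULL
  control_cells <- character()
  if (!is.null(cnv) && nrow(cnv) > 0) {
    hit <- match(markers, expr_log$genes$symbol)
    hit <- hit[!is.na(hit)]
    marker_score <- Matrix::colMeans(expr_log$values[hit, , drop = FALSE])
    mutated <- character()
    if (!is.null(variants) && nrow(variants) > 0) {
      mutated <- unique(variants$cell_id[variants$alt_count >= 2])
    }
    control_cells <- expr_log$cells$cell_id[marker_score > 1 &
                                              !expr_log$cells$cell_id %in% mutated]
    if (length(control_cells) < 10) {
      # fall back to the least-mutated half of cells
      control_cells <- expr_log$cells$cell_id[order(marker_score,
                                                    decreasing = TRUE)]
      control_cells <- utils::head(control_cells, max(10, ncol(expr_log$values) %/% 2))
    }
    cnv_scores <- quantify_cnv_in_cells(expr_log, cnv, control_cells)
  }
  annotation <- classify_cells(expr_log, markers, variants = variants,
                               cnv_scores = cnv_scores, ...)
  list(annotation = annotation, qc = flt$qc, counts = flt$counts,
       expr_cpm = expr_cpm, expr_log = expr_log,
       cnv_scores = cnv_scores, control_cells = control_cells)
}

#' Derive the ontogeny signature from a single-cell cohort
#'
#' The full derivation chain: cell annotation ([annotate_cells()]),
#' homologue feature selection on the TAM cells, per-platform z-scoring,
#' Varimax-rotated PCA, two-component Gaussian-mixture partitioning of PC1,
#' and loading-threshold signature extraction with enrichment-based lineage
#' orientation.
#'
#' @param counts a [tam_counts()] object.
#' @param mouse_table murine lineage table.
#' @param homology mouse-to-human homology map.
#' @param cnv,variants,markers evidence passed to [annotate_cells()].
#' @param threshold PC1 loading threshold for the signature.
#' @param n_components components retained before rotation.
#' @param min_mean_cpm candidate expression filter.
#' @param seed seed for the GMM restarts.
#' @param min_genes,min_reads QC thresholds.
#' @return A list of class `tam_signature_run`: `signature`, `pca`, `gmm`,
#'   `partition` (per-TAM lineage call from the oriented GMM), `candidates`,
#'   `annotation`, `qc`, `expr_tam_cpm`, `expr_tam_z`, `enrichment`.
#' @export
derive_ontogeny_signature <- function(counts, mouse_table, homology,
                                      cnv = NULL, variants = NULL,
                                      markers = default_marker_panel(),
                                      threshold = 0.2, n_components = 10,
                                      min_mean_cpm = 1, seed = 1L,
                                      min_genes = 800, min_reads = 50000) {
  ann <- annotate_cells(counts, cnv = cnv, variants = variants,
                        markers = markers, min_genes = min_genes,
                        min_reads = min_reads)
  tam_ids <- ann$annotation$cell_id[ann$annotation$class == "TAM"]
  if (length(tam_ids) < 20) stop("too few TAM cells after annotation")
  tam_cpm <- ann$expr_cpm[, ann$expr_cpm$cells$cell_id %in% tam_ids]
  candidates <- select_homologue_features(tam_cpm, mouse_table, homology,
                                          min_mean_cpm = min_mean_cpm)
  tam_z <- zscore_by_platform(log_transform(tam_cpm))
  pca <- pca_varimax(tam_z, candidates, n_components = n_components)
  gmm <- fit_gmm_1d(pca$scores[, 1], k = 2, seed = seed)
  signature <- extract_signature(pca, mouse_table, homology, threshold = threshold)
  enrichment <- lineage_enrichment_test(pca$loadings[abs(pca$loadings[, 1]) > threshold, 1],
                                        mouse_table, homology)
  # orient the GMM partition: the component with the higher mean PC1 score
  # carries the lineage labeled on the positive loading side
  pos_lineage <- enrichment$positive_lineage
  neg_lineage <- setdiff(c("blood", "microglia"), pos_lineage)
  partition <- data.frame(cell_id = rownames(pca$scores),
                          pc1 = pca$scores[, 1],
                          component = gmm$assignment,
                          lineage = ifelse(gmm$assignment == 2, pos_lineage, neg_lineage),
                          stringsAsFactors = FALSE)
  structure(list(signature = signature, pca = pca, gmm = gmm,
                 partition = partition, candidates = candidates,
                 annotation = ann$annotation, qc = ann$qc,
                 expr_tam_cpm = tam_cpm, expr_tam_z = tam_z,
                 enrichment = enrichment),
            class = "tam_signature_run")
}

#' @export
print.tam_signature_run <- function(x, ...) {
  cat(sprintf(paste0("<tam_signature_run> %d candidates -> %d signature genes ",
                     "(%d blood, %d microglia); GMM overlap %.4f\n"),
              length(x$candidates), nrow(x$signature),
              sum(x$signature$lineage == "blood"),
              sum(x$signature$lineage == "microglia"),
              x$gmm$overlap))
  invisible(x)
}
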