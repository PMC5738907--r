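# Mapping the lineage signature onto anatomically annotated regional
# expression data and testing structure-level enrichment.

#' Score regional samples with the lineage signature
#'
#' Per-sample mean z-score over each lineage's signature genes, with
#' per-structure summaries (mean and SD of each score).
#'
#' @param atlas a [regional_atlas()] object.
#' @param signature a [signature_gene_set()].
#' @return A list: `samples` (`sample_id`, `structure`, `tumor_id`,
#'   `blood_score`, `microglia_score`) and `structures` (per-structure
#'   `n`, mean and SD of both scores, ordered by decreasing blood score).
#' @export
regional_signature_scores <- function(atlas, signature) {
  stopifnot(inherits(atlas, "regional_atlas"),
            inherits(signature, "signature_gene_set"))
  present <- signature$gene %in% colnames(atlas$values)
  if (!any(present)) stop("no signature gene present in atlas")
  sig <- signature[present, , drop = FALSE]
  score_for <- function(lin) {
    g <- sig$gene[sig$lineage == lin]
    if (length(g) == 0) return(rep(NA_real_, nrow(atlas$values)))
    rowMeans(atlas$values[, g, drop = FALSE])
  }
  samples <- data.frame(sample_id = rownames(atlas$values),
                        structure = atlas$structure,
                        tumor_id = atlas$tumor_id,
                        blood_score = score_for("blood"),
                        microglia_score = score_for("microglia"),
                        stringsAsFactors = FALSE)
  agg <- function(v) {
    data.frame(mean = tapply(v, samples$structure, mean),
               sd = tapply(v, samples$structure, stats::sd))
  }
  ab <- agg(samples$blood_score); am <- agg(samples$microglia_score)
  structures <- data.frame(structure = rownames(ab), n = as.integer(table(samples$structure)[rownames(ab)]),
                           blood_mean = ab$mean, blood_sd = ab$sd,
                           microglia_mean = am$mean, microglia_sd = am$sd,
                           stringsAsFactors = FALSE)
  structures <- structures[order(-structures$blood_mean), , drop = FALSE]
  rownames(structures) <- NULL
  list(samples = samples, structures = structures)
}

#' Test structure-level lineage enrichment
#'
#' For each structure and each lineage score, a one-vs-rest two-sided
#' Wilcoxon rank-sum test with BH adjustment across all structure-lineage
#' tests; the effect size is the difference of mean scores (structure minus
#' rest). Samples from the same tumor are treated as independent, which the
#' output flags as a caveat. Structures with fewer than 2 samples are
#' skipped with a warning.
#'
#' @param scores the `samples` table from [regional_signature_scores()] (or
#'   any data frame with `structure`, `blood_score`, `microglia_score`).
#' @param structures optional structure labels overriding the table column.
#' @return A `data.frame` (class `tam_regional`): `structure`, `lineage`,
#'   `n`, `effect` (mean difference), `p`, `padj`; the independence caveat
#'   is in the `caveat` attribute.
#' @export
structure_enrichment <- function(scores, structures = NULL) {
  structures <- structures %||% scores$structure
  structures <- as.character(structures)
  if (length(unique(structures)) < 2) {
    stop("need at least 2 structures for a one-vs-rest test")
  }
  res <- list()
  for (s in unique(structures)) {
    inn <- structures == s
    if (sum(inn) < 2) {
      warning(sprintf("structure '%s' has < 2 samples; skipped", s))
      next
    }
    for (lin in c("blood", "microglia")) {
      v <- scores[[paste0(lin, "_score")]]
      if (is.null(v) || all(is.na(v))) next
      wt <- stats::wilcox.test(v[inn], v[!inn], exact = FALSE)
      res[[paste(s, lin)]] <- data.frame(structure = s, lineage = lin,
                                         n = sum(inn),
                                         effect = mean(v[inn]) - mean(v[!inn]),
                                         p = wt$p.value,
                                         stringsAsFactors = FALSE)
    }
  }
  if (length(res) == 0) stop("no structure with enough samples")
  out <- do.call(rbind, res)
  out$padj <- bh_adjust(out$p)
  rownames(out) <- NULL
  attr(out, "caveat") <- "samples sharing a tumor are treated as independent"
  class(out) <- c("tam_regional", "data.frame")
  out
}
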