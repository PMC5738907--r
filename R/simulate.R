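# Synthetic-data generators. These define the study conditions under which
# the pipeline is exercised: two macrophage lineages with a planted subset of
# lineage-specific genes among a murine-homologue candidate pool, two
# full-length capture platforms with distinct depth/detection profiles,
# neoplastic cells carrying clonal expressed SNVs and megabase-scale CNVs,
# bulk cohorts as lineage mixtures with proportional-hazards survival, and a
# regional atlas with structure-specific lineage enrichment. Every generator
# is a pure function of its arguments including the seed, and every output
# is paired with ground-truth labels.

#' Simulation configuration
#'
#' Assembles and validates the parameters of the synthetic single-cell
#' cohort. Defaults describe a 19-sample cohort yielding roughly 3000
#' quality-passing TAMs, of which about 70% are blood-derived, with a
#' 237-gene murine-homologue candidate pool containing 66 truly
#' lineage-specific genes.
#'
#' @param n_cells_per_sample cells captured per sample before QC.
#' @param n_samples number of patient samples.
#' @param n_genes total genes in the simulated transcriptome.
#' @param n_candidate_genes size of the homologue-filtered candidate pool.
#' @param n_true_signature number of candidates that are truly
#'   lineage-specific in the human cells.
#' @param bmdm_fraction fraction of TAMs that are blood-derived.
#' @param neoplastic_fraction fraction of cells that are neoplastic.
#' @param effect_size mean absolute log2 fold-change between lineages for
#'   true signature genes.
#' @param platform_mix fraction of samples captured on the first platform
#'   (`"C1"`); the remainder use `"SS2"`.
#' @param detection_rates named per-platform probability that an expressed
#'   gene is detected in a cell (Bernoulli thinning).
#' @param library_size_params named list of per-platform log-normal
#'   parameters `c(meanlog, sdlog)` for total reads per cell.
#' @param nb_dispersion negative-binomial dispersion (variance =
#'   mu + dispersion * mu^2).
#' @param n_cnv_segments number of planted CNV segments in neoplastic cells.
#' @param cnv_fold expression fold-change of amplified segments (deletions
#'   use its reciprocal).
#' @param snv_capture_rate probability that an expressed clonal SNV is
#'   observed (with >= 2 alt reads) in a neoplastic cell.
#' @param n_snvs number of clonal SNVs carried by neoplastic cells.
#' @param marker_genes macrophage marker panel planted in TAM cells.
#' @param seed master seed; stage seeds are derived from it by fixed offsets.
#'
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(n_cells_per_sample = 240,
                       n_samples = 19,
                       n_genes = 2000,
                       n_candidate_genes = 237,
                       n_true_signature = 66,
                       bmdm_fraction = 0.70,
                       neoplastic_fraction = 0.25,
                       effect_size = 4.0,
                       platform_mix = 0.5,
                       detection_rates = c(C1 = 0.60, SS2 = 0.75),
                       library_size_params = list(C1 = c(meanlog = log(3e5), sdlog = 0.9),
                                                  SS2 = c(meanlog = log(4e5), sdlog = 1.0)),
                       nb_dispersion = 0.4,
                       n_cnv_segments = 4,
                       cnv_fold = 2,
                       snv_capture_rate = 0.6,
                       n_snvs = 12,
                       marker_genes = default_marker_panel(),
                       seed = 1L) {
  check_count(n_cells_per_sample, "n_cells_per_sample", min = 1)
  check_count(n_samples, "n_samples", min = 1)
  check_count(n_genes, "n_genes", min = 1)
  check_count(n_candidate_genes, "n_candidate_genes", min = 1)
  check_count(n_true_signature, "n_true_signature", min = 0)
  check_proportion(bmdm_fraction, "bmdm_fraction")
  check_proportion(neoplastic_fraction, "neoplastic_fraction")
  check_proportion(platform_mix, "platform_mix")
  for (r in detection_rates) check_proportion(r, "detection_rates")
  if (effect_size < 0) stop("`effect_size` must be >= 0")
  if (nb_dispersion < 0) stop("`nb_dispersion` must be >= 0")
  if (cnv_fold <= 0) stop("`cnv_fold` must be > 0")
  check_proportion(snv_capture_rate, "snv_capture_rate")
  check_count(n_cnv_segments, "n_cnv_segments", min = 0)
  check_count(n_snvs, "n_snvs", min = 0)
  if (n_true_signature > n_candidate_genes) {
    stop("n_true_signature must be <= n_candidate_genes")
  }
  if (n_candidate_genes + length(marker_genes) > n_genes) {
    stop("n_candidate_genes must be <= n_genes (after reserving marker genes)")
  }
  structure(list(n_cells_per_sample = as.integer(n_cells_per_sample),
                 n_samples = as.integer(n_samples),
                 n_genes = as.integer(n_genes),
                 n_candidate_genes = as.integer(n_candidate_genes),
                 n_true_signature = as.integer(n_true_signature),
                 bmdm_fraction = bmdm_fraction,
                 neoplastic_fraction = neoplastic_fraction,
                 effect_size = effect_size,
                 platform_mix = platform_mix,
                 detection_rates = detection_rates,
                 library_size_params = library_size_params,
                 nb_dispersion = nb_dispersion,
                 n_cnv_segments = as.integer(n_cnv_segments),
                 cnv_fold = cnv_fold,
                 snv_capture_rate = snv_capture_rate,
                 n_snvs = as.integer(n_snvs),
                 marker_genes = marker_genes,
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Simulate a murine lineage differential-expression table
#'
#' Emulates the input table of genes differentially expressed between
#' blood-derived and microglial TAMs in two independent mouse glioma models.
#' Exactly `n_lineage` genes are flagged as differential in both models with
#' a consistent sign; lineage assignments of the flagged genes are balanced
#' between blood and microglia.
#'
#' @param n_total total genes in the table.
#' @param n_lineage number of genes differential in both models.
#' @param effect_size log2 fold-change scale of the differential genes.
#' @param seed RNG seed.
#' @param p_cutoff adjusted-p cutoff under which a gene counts as
#'   differential in a model (recorded in the `p_cutoff` attribute).
#' @param dual_genes,dual_lineage optional gene names and lineage labels to
#'   use for the flagged subset (plumbing for coordinated simulations);
#'   auto-generated when `NULL`.
#'
#' @return A `data.frame` with columns `mouse_gene`, `lineage`,
#'   `log2fc_model1`, `log2fc_model2`, `padj_model1`, `padj_model2`,
#'   `dual_model_flag`.
#' @export
simulate_mouse_lineage_table <- function(n_total, n_lineage, effect_size, seed,
                                         p_cutoff = 0.05,
                                         dual_genes = NULL, dual_lineage = NULL) {
  check_count(n_total, "n_total", min = 0)
  check_count(n_lineage, "n_lineage", min = 0)
  if (n_lineage > n_total) stop("n_lineage must be <= n_total")
  with_seed(seed, {
    genes <- sprintf("mgene%05d", seq_len(n_total))
    if (!is.null(dual_genes)) {
      stopifnot(length(dual_genes) == n_lineage)
      genes[seq_len(n_lineage)] <- dual_genes
    }
    lineage <- rep(NA_character_, n_total)
    if (n_lineage > 0) {
      lin <- if (!is.null(dual_lineage)) {
        stopifnot(length(dual_lineage) == n_lineage)
        dual_lineage
      } else {
        sample(rep_len(c("blood", "microglia"), n_lineage))
      }
      lineage[seq_len(n_lineage)] <- lin
    }
    dual <- seq_len(n_total) <= n_lineage
    sgn <- ifelse(lineage == "blood", 1, -1)
    mag1 <- effect_size * stats::runif(n_total, 0.75, 1.25)
    mag2 <- effect_size * stats::runif(n_total, 0.75, 1.25)
    lfc1 <- ifelse(dual, sgn * mag1, stats::rnorm(n_total, 0, 0.3))
    lfc2 <- ifelse(dual, sgn * mag2, stats::rnorm(n_total, 0, 0.3))
    p1 <- ifelse(dual, stats::runif(n_total, 0, p_cutoff / 2),
                 stats::runif(n_total, p_cutoff * 1.2, 1))
    # non-dual genes may still be significant in one model
    one_hit <- !dual & stats::runif(n_total) < 0.15
    p1[one_hit] <- stats::runif(sum(one_hit), 0, p_cutoff / 2)
    p2 <- ifelse(dual, stats::runif(n_total, 0, p_cutoff / 2),
                 stats::runif(n_total, p_cutoff * 1.2, 1))
    out <- data.frame(mouse_gene = genes, lineage = lineage,
                      log2fc_model1 = lfc1, log2fc_model2 = lfc2,
                      padj_model1 = p1, padj_model2 = p2,
                      dual_model_flag = dual, stringsAsFactors = FALSE)
    out <- out[sample(nrow(out)), , drop = FALSE]
    rownames(out) <- NULL
    attr(out, "p_cutoff") <- p_cutoff
    out
  })
}

#' Simulate a mouse-to-human homology map
#'
#' One-to-one mapping covering `floor(n * (1 - drop_fraction))` of the input
#' mouse genes; the remainder have no homologue and are absent from the map.
#'
#' @param mouse_genes character vector of mouse gene names.
#' @param drop_fraction fraction of genes without a mapped homologue, in
#'   `[0, 1)`.
#' @param seed RNG seed.
#' @param human_genes optional human names aligned with `mouse_genes`;
#'   defaults to the upper-cased mouse names.
#'
#' @return A `data.frame` with columns `mouse_gene`, `human_gene`.
#' @export
simulate_homology_map <- function(mouse_genes, drop_fraction, seed,
                                  human_genes = NULL) {
  check_proportion(drop_fraction, "drop_fraction", allow_one = FALSE)
  n <- length(mouse_genes)
  human_genes <- human_genes %||% toupper(mouse_genes)
  stopifnot(length(human_genes) == n)
  with_seed(seed, {
    keep <- sort(sample(n, floor(n * (1 - drop_fraction))))
    data.frame(mouse_gene = mouse_genes[keep], human_gene = human_genes[keep],
               stringsAsFactors = FALSE)
  })
}

# Gene annotation table with synthesized coordinates: genes laid out on 20
# chromosomes at 1 Mb spacing (0-based half-open), so contiguous gene blocks
# correspond to megabase-scale segments.
make_gene_table <- function(symbols) {
  n <- length(symbols)
  n_chrom <- 20L
  per <- ceiling(n / n_chrom)
  chrom <- paste0("chr", rep(seq_len(n_chrom), each = per))[seq_len(n)]
  pos <- (seq_len(n) - 1L) %% per
  data.frame(gene_id = sprintf("GID%05d", seq_len(n)),
             symbol = symbols,
             chrom = chrom,
             start = as.numeric(pos) * 1e6,
             end = as.numeric(pos) * 1e6 + 2e4,
             stringsAsFactors = FALSE)
}

#' Simulate a dual-platform single-cell glioma cohort
#'
#' Generates negative-binomial counts for a mixture of blood-derived TAMs,
#' microglial TAMs and neoplastic cells across `n_samples` patients captured
#' on two platforms. True signature genes are shifted by `effect_size` log2
#' units between TAM lineages; neoplastic cells carry planted CNV segments
#' (contiguous gene blocks scaled by `cnv_fold`) and clonal expressed SNVs
#' observed with probability `snv_capture_rate` per cell; macrophage marker
#' genes are expressed in TAMs and silenced in neoplastic cells. Per-platform
#' log-normal library sizes and Bernoulli detection thinning reproduce the
#' depth/detection differences between a full-length microfluidic capture
#' and a plate-based protocol.
#'
#' @param config a [sim_config()] object.
#'
#' @return A list with elements:
#'   \describe{
#'     \item{counts}{`tam_counts` object.}
#'     \item{cnv}{CNV segment table (`chrom`, `start`, `end`, `direction`),
#'       BED-style 0-based half-open.}
#'     \item{variants}{variant allele table (`variant_id`, `cell_id`,
#'       `ref_count`, `alt_count`).}
#'     \item{truth}{ground-truth labels: `cells` (per-cell lineage),
#'       `candidates` (candidate pool with mouse lineage, signature flag and
#'       planted effect), `signature` (the planted signature genes with
#'       lineage), `cnv_segments`, `snv_ids`.}
#'   }
#' @export
simulate_single_cell_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  cf <- config
  with_seed(cf$seed, {
    n_mark <- length(cf$marker_genes)
    n_bg <- cf$n_genes - cf$n_candidate_genes - n_mark
    if (n_bg < 0) stop("n_genes too small for candidate pool plus markers")
    symbols <- c(cf$marker_genes,
                 sprintf("HOM%04d", seq_len(cf$n_candidate_genes)),
                 sprintf("BG%05d", seq_len(n_bg)))
    symbols <- sample(symbols)        # scatter categories across the genome
    genes <- make_gene_table(symbols)
    is_marker <- symbols %in% cf$marker_genes
    is_cand <- grepl("^HOM", symbols)
    is_bg <- grepl("^BG", symbols)

    # baseline relative abundance: a low-expression tier among background
    # genes makes the mean-CPM > 1 homologue filter meaningful
    alpha <- numeric(cf$n_genes)
    alpha[is_bg] <- stats::rlnorm(sum(is_bg), meanlog = 0, sdlog = 1.5)
    low <- is_bg & stats::runif(cf$n_genes) < 0.15
    alpha[low] <- stats::rlnorm(sum(low), meanlog = -6, sdlog = 1)
    alpha[is_cand] <- stats::rlnorm(sum(is_cand), meanlog = 2.5, sdlog = 0.8)
    alpha[is_marker] <- stats::rlnorm(sum(is_marker), meanlog = 3, sdlog = 0.3)

    # candidate truth: all candidates are homologues of dual-model mouse
    # lineage genes; a planted subset is truly lineage-specific in human
    cand_idx <- which(is_cand)
    cand_symbols <- symbols[cand_idx]
    mouse_lineage <- sample(rep_len(c("blood", "microglia"), cf$n_candidate_genes))
    sig_pick <- sort(sample(cf$n_candidate_genes, cf$n_true_signature))
    is_sig <- seq_len(cf$n_candidate_genes) %in% sig_pick
    effect <- ifelse(is_sig, cf$effect_size * stats::runif(cf$n_candidate_genes, 0.75, 1.25), 0)
    candidates <- data.frame(gene = cand_symbols,
                             mouse_lineage = mouse_lineage,
                             is_signature = is_sig,
                             effect_log2fc = effect,
                             stringsAsFactors = FALSE)

    # CNV segments: contiguous gene runs on distinct chromosomes
    seg_len <- 10L
    chroms <- unique(genes$chrom)
    seg_chroms <- sample(chroms, min(cf$n_cnv_segments, length(chroms)))
    cnv_rows <- list()
    cnv_gene_idx <- list()
    for (k in seq_along(seg_chroms)) {
      gi <- which(genes$chrom == seg_chroms[k])
      gi <- gi[order(genes$start[gi])]
      if (length(gi) < seg_len) next
      s <- sample(length(gi) - seg_len + 1L, 1L)
      idx <- gi[s:(s + seg_len - 1L)]
      dir <- if (k %% 2 == 1) "amp" else "del"
      cnv_rows[[k]] <- data.frame(chrom = seg_chroms[k],
                                  start = min(genes$start[idx]),
                                  end = max(genes$end[idx]),
                                  direction = dir, stringsAsFactors = FALSE)
      cnv_gene_idx[[k]] <- idx
    }
    cnv <- do.call(rbind, cnv_rows)
    if (is.null(cnv)) {
      cnv <- data.frame(chrom = character(), start = numeric(), end = numeric(),
                        direction = character(), stringsAsFactors = FALSE)
    }

    # three expression profiles (relative abundance per gene)
    prof_blood <- prof_mg <- prof_neo <- alpha
    half <- 2^(candidates$effect_log2fc / 2)
    up_blood <- ifelse(candidates$mouse_lineage == "blood", half, 1 / half)
    prof_blood[cand_idx] <- alpha[cand_idx] * up_blood
    prof_mg[cand_idx] <- alpha[cand_idx] / up_blood
    prof_neo[is_marker] <- alpha[is_marker] * 2^-4
    for (k in seq_along(cnv_gene_idx)) {
      f <- if (cnv$direction[k] == "amp") cf$cnv_fold else 1 / cf$cnv_fold
      prof_neo[cnv_gene_idx[[k]]] <- prof_neo[cnv_gene_idx[[k]]] * f
    }
    profiles <- cbind(blood = prof_blood / sum(prof_blood),
                      microglia = prof_mg / sum(prof_mg),
                      neoplastic = prof_neo / sum(prof_neo))

    # cells
    n_cells <- cf$n_cells_per_sample * cf$n_samples
    sample_id <- rep(sprintf("S%02d", seq_len(cf$n_samples)),
                     each = cf$n_cells_per_sample)
    n_c1 <- round(cf$platform_mix * cf$n_samples)
    platform_by_sample <- c(rep("C1", n_c1), rep("SS2", cf$n_samples - n_c1))
    platform <- platform_by_sample[match(sample_id, sprintf("S%02d", seq_len(cf$n_samples)))]
    is_neo <- stats::rbinom(n_cells, 1, cf$neoplastic_fraction) == 1
    is_blood <- stats::rbinom(n_cells, 1, cf$bmdm_fraction) == 1
    lineage <- ifelse(is_neo, "neoplastic", ifelse(is_blood, "blood", "microglia"))
    cell_id <- sprintf("%s_C%04d", sample_id, stats::ave(seq_len(n_cells), sample_id,
                                                         FUN = seq_along))
    lib <- numeric(n_cells)
    for (p in names(cf$library_size_params)) {
      sel <- platform == p
      pars <- cf$library_size_params[[p]]
      lib[sel] <- stats::rlnorm(sum(sel), pars[["meanlog"]], pars[["sdlog"]])
    }

    # counts: NB around library-scaled profiles, then detection thinning
    mu <- profiles[, lineage, drop = FALSE] * rep(lib, each = cf$n_genes)
    size <- if (cf$nb_dispersion > 0) 1 / cf$nb_dispersion else Inf
    cnt <- stats::rnbinom(length(mu), mu = as.vector(mu), size = size)
    det <- cf$detection_rates[platform]
    keep <- stats::rbinom(length(cnt), 1, rep(det, each = cf$n_genes))
    cnt <- matrix(cnt * keep, nrow = cf$n_genes)

    counts <- tam_counts(Matrix::Matrix(cnt, sparse = TRUE),
                         genes,
                         data.frame(cell_id = cell_id, sample_id = sample_id,
                                    platform = platform, stringsAsFactors = FALSE))

    # variant allele table: clonal SNVs observed in neoplastic cells
    variants <- simulate_variant_table(cell_id, lineage, cf)

    sig <- candidates[candidates$is_signature, , drop = FALSE]
    truth <- list(cells = data.frame(cell_id = cell_id, lineage = lineage,
                                     stringsAsFactors = FALSE),
                  candidates = candidates,
                  signature = signature_gene_set(sig$gene, sig$mouse_lineage,
                                                 loading = rep(NA_real_, nrow(sig))),
                  cnv_segments = cnv,
                  snv_ids = sprintf("SNV%03d", seq_len(cf$n_snvs)))
    list(counts = counts, cnv = cnv, variants = variants, truth = truth)
  })
}

# Variant-by-cell allele counts. Neoplastic cells show alt-supporting reads
# at clonal SNVs with the configured capture probability; TAM cells only
# ever show reference reads.
simulate_variant_table <- function(cell_id, lineage, cf) {
  if (cf$n_snvs == 0) {
    return(data.frame(variant_id = character(), cell_id = character(),
                      ref_count = integer(), alt_count = integer(),
                      stringsAsFactors = FALSE))
  }
  snv_ids <- sprintf("SNV%03d", seq_len(cf$n_snvs))
  neo <- cell_id[lineage == "neoplastic"]
  tam <- cell_id[lineage != "neoplastic"]
  rows <- list()
  if (length(neo)) {
    grid <- expand.grid(variant_id = snv_ids, cell_id = neo,
                        KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    captured <- stats::runif(nrow(grid)) < cf$snv_capture_rate
    ref_only <- !captured & stats::runif(nrow(grid)) < 0.25
    alt <- integer(nrow(grid))
    ref <- integer(nrow(grid))
    alt[captured] <- 2L + stats::rpois(sum(captured), 2)
    ref[captured] <- stats::rpois(sum(captured), 2)
    ref[ref_only] <- 1L + stats::rpois(sum(ref_only), 2)
    sel <- captured | ref_only
    rows$neo <- cbind(grid[sel, , drop = FALSE],
                      data.frame(ref_count = ref[sel], alt_count = alt[sel]))
  }
  if (length(tam)) {
    grid <- expand.grid(variant_id = snv_ids, cell_id = tam,
                        KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    sel <- stats::runif(nrow(grid)) < 0.05
    rows$tam <- cbind(grid[sel, , drop = FALSE],
                      data.frame(ref_count = 1L + stats::rpois(sum(sel), 2),
                                 alt_count = 0L))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Simulate a bulk expression cohort with survival
#'
#' Samples are mixtures of the two lineage profiles: each sample has a latent
#' blood-derived content drawn uniformly on `[0, 1]`; blood-signature genes
#' increase with that content and microglial genes decrease, on the
#' log2(CPM + 1) scale, plus measurement noise. Survival times are
#' exponential with the hazard multiplied by `true_hr` for samples in the top
#' half of planted blood content, with additional age and gender effects;
#' censoring is independent exponential calibrated to the stated rate.
#'
#' @param n_samples number of samples (>= 10; the Cox stage is
#'   unidentifiable below that).
#' @param signature a [signature_gene_set()] giving the measured lineage
#'   genes.
#' @param true_hr hazard ratio planted for the high-blood-content half.
#' @param censor_rate expected fraction of censored samples.
#' @param seed RNG seed.
#' @param effect_amp log2 expression swing of a signature gene across the
#'   full content range.
#' @param noise_sd per-gene measurement noise (log2 scale).
#' @param n_background_genes non-signature genes included in the matrix.
#'
#' @return A `bulk_cohort` whose `truth` attribute holds the latent content,
#'   the planted high/low split and `true_hr`.
#' @export
simulate_bulk_cohort <- function(n_samples, signature, true_hr,
                                 censor_rate = 0.3, seed = 1L,
                                 effect_amp = 1.0, noise_sd = 0.15,
                                 n_background_genes = 200) {
  check_count(n_samples, "n_samples", min = 0)
  if (n_samples < 10) stop("n_samples must be >= 10 for an identifiable Cox stage")
  if (true_hr <= 0) stop("true_hr must be > 0")
  check_proportion(censor_rate, "censor_rate", allow_one = FALSE)
  stopifnot(inherits(signature, "signature_gene_set"))
  with_seed(seed, {
    f <- stats::runif(n_samples)
    group <- f > stats::median(f)
    genes <- c(signature$gene, sprintf("BULKBG%04d", seq_len(n_background_genes)))
    base <- stats::runif(length(genes), 2, 8)
    mu <- matrix(rep(base, each = n_samples), nrow = n_samples)
    for (j in seq_len(nrow(signature))) {
      shift <- if (signature$lineage[j] == "blood") f - 0.5 else 0.5 - f
      mu[, j] <- mu[, j] + effect_amp * shift
    }
    bgcols <- nrow(signature) + seq_len(n_background_genes)
    expr <- mu + cbind(matrix(stats::rnorm(n_samples * nrow(signature), 0, noise_sd),
                              nrow = n_samples),
                       matrix(stats::rnorm(n_samples * n_background_genes, 0, 0.5),
                              nrow = n_samples))
    colnames(expr) <- genes

    age <- pmin(85, pmax(18, round(stats::rnorm(n_samples, 55, 12))))
    gender <- sample(c("female", "male"), n_samples, replace = TRUE)
    subtype_latent <- f + stats::rnorm(n_samples, 0, 0.25)
    subtype <- c("OLIG", "ASTRO", "GBM")[cut(rank(subtype_latent, ties.method = "first"),
                                             breaks = 3, labels = FALSE)]
    h <- (1 / 1500) * exp(log(true_hr) * group + 0.02 * (age - 55) +
                            0.1 * (gender == "male"))
    t_event <- stats::rexp(n_samples, h)
    if (censor_rate > 0) {
      rc <- mean(h) * censor_rate / (1 - censor_rate)
      t_cens <- stats::rexp(n_samples, rc)
    } else {
      t_cens <- rep(Inf, n_samples)
    }
    time <- pmin(t_event, t_cens)
    event <- as.integer(t_event <= t_cens)
    clinical <- data.frame(sample_id = sprintf("B%04d", seq_len(n_samples)),
                           time = time, event = event, age = age,
                           gender = gender, subtype = subtype,
                           stringsAsFactors = FALSE)
    out <- bulk_cohort(expr, clinical)
    attr(out, "truth") <- list(content = f, group = group, true_hr = true_hr)
    out
  })
}

#' Default anatomic structures and planted lineage biases
#'
#' Vascular and necrotic compartments carry a blood-lineage bias; the tumor
#' margin compartments carry a microglial bias; the cellular tumor is
#' neutral.
#'
#' @param bias bias magnitude in pre-normalization expression units.
#' @return A `data.frame` with columns `structure`, `blood_bias`,
#'   `microglia_bias`.
#' @export
default_structure_enrichment <- function(bias = 2.0) {
  data.frame(structure = c("leading edge", "infiltrated white matter",
                           "cellular tumor", "hyperplastic blood vessels",
                           "microvascular proliferation", "peri-necrotic zone"),
             blood_bias = c(0, 0, 0, bias, bias, bias),
             microglia_bias = c(bias, bias, 0, 0, 0, 0),
             stringsAsFactors = FALSE)
}

#' Simulate a regional expression atlas
#'
#' Per-sample expression over anatomically annotated tumor compartments:
#' blood-signature genes are shifted upward in blood-biased structures and
#' microglial genes in microglia-biased structures. Samples from the same
#' tumor share a random intercept (structures within a tumor are not
#' independent). Values are z-scored per gene across samples.
#'
#' @param structures character vector of structure labels (>= 2), or `NULL`
#'   to take them from `enrichment`.
#' @param enrichment `data.frame` as from [default_structure_enrichment()].
#' @param seed RNG seed.
#' @param signature a [signature_gene_set()] naming the lineage genes.
#' @param n_per_structure samples per structure (>= 2).
#' @param n_background non-signature genes.
#' @param n_tumors tumors the samples are drawn from.
#' @param tumor_sd SD of the shared per-tumor intercept.
#' @param noise_sd per-gene residual SD.
#'
#' @return A `regional_atlas`; its `truth` attribute holds the planted
#'   enrichment table.
#' @export
simulate_regional_atlas <- function(structures = NULL,
                                    enrichment = default_structure_enrichment(),
                                    seed = 1L, signature,
                                    n_per_structure = 20,
                                    n_background = 150,
                                    n_tumors = 10,
                                    tumor_sd = 0.2,
                                    noise_sd = 1.0) {
  stopifnot(inherits(signature, "signature_gene_set"))
  structures <- structures %||% enrichment$structure
  if (length(structures) < 2) stop("at least 2 structures required")
  if (n_per_structure < 2) stop("at least 2 samples per structure required")
  enrichment <- enrichment[match(structures, enrichment$structure), , drop = FALSE]
  if (anyNA(enrichment$structure)) stop("enrichment must cover all structures")
  with_seed(seed, {
    struct <- rep(structures, each = n_per_structure)
    n <- length(struct)
    tumor <- sprintf("T%02d", rep_len(seq_len(n_tumors), n))
    tumor_eff <- stats::rnorm(n_tumors, 0, tumor_sd)[rep_len(seq_len(n_tumors), n)]
    genes <- c(signature$gene, sprintf("RBG%04d", seq_len(n_background)))
    x <- matrix(stats::rnorm(n * length(genes), 0, noise_sd), nrow = n)
    colnames(x) <- genes
    bb <- enrichment$blood_bias[match(struct, enrichment$structure)]
    mb <- enrichment$microglia_bias[match(struct, enrichment$structure)]
    for (j in seq_len(nrow(signature))) {
      x[, j] <- x[, j] + if (signature$lineage[j] == "blood") bb else mb
    }
    x <- x + tumor_eff
    x <- scale(x)                      # z per gene across samples
    x[, attr(x, "scaled:scale") == 0] <- 0
    x <- x[, , drop = FALSE]
    attr(x, "scaled:center") <- NULL
    attr(x, "scaled:scale") <- NULL
    rownames(x) <- sprintf("RS%03d", seq_len(n))
    out <- regional_atlas(x, struct, tumor)
    attr(out, "truth") <- list(enrichment = enrichment)
    out
  })
}

#' Simulate the complete study inputs
#'
#' Orchestrates the generators into one coherent set of pipeline inputs: a
#' murine lineage table whose dual-model genes include the mouse counterparts
#' of the cohort's candidate pool, a homology map linking them to the human
#' symbols (with decoy homologues that fail the expression filter and
#' homologues absent from the matrix), and the single-cell cohort with CNV
#' and variant evidence. Stage seeds are derived from `config$seed` by fixed
#' offsets.
#'
#' @param config a [sim_config()] object.
#' @param n_mouse_total,n_mouse_dual size of the murine table and of its
#'   dual-model differential subset.
#'
#' @return A list: `config`, `counts`, `cnv`, `variants`, `truth`,
#'   `mouse_table`, `homology`, `markers`.
#' @export
simulate_study <- function(config, n_mouse_total = 1200, n_mouse_dual = 836) {
  stopifnot(inherits(config, "sim_config"))
  cohort_cf <- config
  cohort_cf$seed <- child_seed(config$seed, 1)
  cohort <- simulate_single_cell_cohort(cohort_cf)
  cand <- cohort$truth$candidates
  if (n_mouse_dual < nrow(cand)) stop("n_mouse_dual must be >= candidate pool size")

  # mouse counterparts: candidates first, then decoys (low-expression human
  # genes present in the matrix), then homologues absent from the matrix
  n_extra_dual <- n_mouse_dual - nrow(cand)
  low_candidates <- with_seed(child_seed(config$seed, 2), {
    cpm_mean <- Matrix::rowMeans(cpm_normalize(cohort$counts)$values)
    pool <- cohort$counts$genes$symbol[cpm_mean <= 0.5 &
                                         grepl("^BG", cohort$counts$genes$symbol)]
    sample(pool, min(30, length(pool)))
  })
  n_absent <- max(0, n_extra_dual - length(low_candidates) - 200)
  absent <- sprintf("ABSENT%04d", seq_len(n_absent))
  dual_human <- c(cand$gene, low_candidates, absent)   # mapped dual genes
  n_unmapped <- n_mouse_dual - length(dual_human)      # dual genes w/o homologue
  dual_mouse_named <- paste0("mm.", tolower(dual_human))
  unmapped_mouse <- sprintf("mm.orphan%04d", seq_len(n_unmapped))
  dual_lineage <- with_seed(child_seed(config$seed, 3), {
    c(cand$mouse_lineage,
      sample(rep_len(c("blood", "microglia"), n_mouse_dual - nrow(cand))))
  })
  mouse_table <- simulate_mouse_lineage_table(
    n_total = n_mouse_total, n_lineage = n_mouse_dual,
    effect_size = config$effect_size, seed = child_seed(config$seed, 4),
    dual_genes = c(dual_mouse_named, unmapped_mouse),
    dual_lineage = dual_lineage)
  homology <- data.frame(mouse_gene = dual_mouse_named, human_gene = dual_human,
                         stringsAsFactors = FALSE)
  list(config = config, counts = cohort$counts, cnv = cohort$cnv,
       variants = cohort$variants, truth = cohort$truth,
       mouse_table = mouse_table, homology = homology,
       markers = config$marker_genes)
}
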