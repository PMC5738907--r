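# Synthetic-data generators: determinism, construction guarantees, and
# marginal fidelity of the count model.

test_that("mouse lineage table plants exactly the requested dual-model genes", {
  tab <- simulate_mouse_lineage_table(1000, 300, 2.0, seed = 1)
  expect_equal(sum(tab$dual_model_flag), 300)
  cutoff <- attr(tab, "p_cutoff")
  dual <- tab[tab$dual_model_flag, ]
  # flag is consistent with its definition: both models significant, same sign
  expect_true(all(dual$padj_model1 < cutoff & dual$padj_model2 < cutoff))
  expect_true(all(sign(dual$log2fc_model1) == sign(dual$log2fc_model2)))
  nondual <- tab[!tab$dual_model_flag, ]
  expect_false(any(nondual$padj_model1 < cutoff & nondual$padj_model2 < cutoff))
  # lineage signs balanced within 10%
  expect_lte(abs(sum(dual$lineage == "blood") - 150), 30)

  empty <- simulate_mouse_lineage_table(1000, 0, 2.0, seed = 1)
  expect_equal(sum(empty$dual_model_flag), 0)

  expect_identical(simulate_mouse_lineage_table(1000, 300, 2.0, seed = 1),
                   simulate_mouse_lineage_table(1000, 300, 2.0, seed = 1))
  expect_error(simulate_mouse_lineage_table(-5, 3, 2.0, seed = 1), "integer")
  expect_error(simulate_mouse_lineage_table(10, 30, 2.0, seed = 1), "<=")
})

test_that("homology map drops the stated fraction and partitions the input", {
  genes <- sprintf("mg%04d", 1:836)
  full <- simulate_homology_map(genes, 0.0, seed = 1)
  expect_equal(nrow(full), 836)
  half <- simulate_homology_map(genes, 0.5, seed = 1)
  expect_equal(nrow(half), 418)   # floor(836 * 0.5)
  dropped <- setdiff(genes, half$mouse_gene)
  expect_length(intersect(half$mouse_gene, dropped), 0)
  expect_equal(length(dropped) + nrow(half), 836)
  expect_false(anyDuplicated(half$human_gene) > 0)
  expect_error(simulate_homology_map(genes, 1, seed = 1), "proportion")
})

test_that("single-cell cohort generation is deterministic and honors fractions", {
  cf <- small_config(seed = 7)
  a <- simulate_single_cell_cohort(cf)
  b <- simulate_single_cell_cohort(cf)
  expect_identical(as.matrix(a$counts$counts), as.matrix(b$counts$counts))
  expect_identical(a$variants, b$variants)
  expect_identical(a$truth$candidates, b$truth$candidates)

  # realized TAM lineage fraction within 3 binomial SD of bmdm_fraction
  tam <- a$truth$cells[a$truth$cells$lineage != "neoplastic", ]
  n <- nrow(tam); p <- cf$bmdm_fraction
  expect_lt(abs(mean(tam$lineage == "blood") - p), 3 * sqrt(p * (1 - p) / n))

  # structure guarantees
  expect_equal(nrow(a$counts$genes), cf$n_genes)
  expect_equal(nrow(a$truth$candidates), cf$n_candidate_genes)
  expect_equal(sum(a$truth$candidates$is_signature), cf$n_true_signature)
  expect_true(all(a$truth$candidates$gene %in% a$counts$genes$symbol))
  expect_true(all(a$cnv$start < a$cnv$end))
  # every cell has exactly one truth label
  expect_setequal(a$truth$cells$cell_id, a$counts$cells$cell_id)
  expect_true(all(a$truth$cells$lineage %in% c("blood", "microglia", "neoplastic")))
  # variant alt evidence is confined to neoplastic cells
  neo <- a$truth$cells$cell_id[a$truth$cells$lineage == "neoplastic"]
  expect_true(all(a$variants$cell_id[a$variants$alt_count > 0] %in% neo))
})

test_that("counts follow the NB mean-variance relation at constant depth", {
  # one platform, one lineage, no thinning, constant library size: the
  # marginal of each gene is exactly NB with dispersion nb_dispersion
  cf <- sim_config(n_samples = 1, n_cells_per_sample = 1200, n_genes = 250,
                   n_candidate_genes = 40, n_true_signature = 0,
                   neoplastic_fraction = 0, bmdm_fraction = 1,
                   platform_mix = 1, detection_rates = c(C1 = 1, SS2 = 1),
                   library_size_params = list(C1 = c(meanlog = log(2e5), sdlog = 0),
                                              SS2 = c(meanlog = log(2e5), sdlog = 0)),
                   nb_dispersion = 0.4, n_cnv_segments = 0, n_snvs = 0, seed = 5)
  sim <- simulate_single_cell_cohort(cf)
  m <- as.matrix(sim$counts$counts)
  mu <- rowMeans(m)
  s2 <- apply(m, 1, var)
  keep <- mu > 5
  n <- ncol(m)
  # z-score of the observed variance against exact NB moments, aggregated;
  # the variance of s^2 - sigma^2(mu-hat) carries delta-method corrections
  # for the plugged-in mean (cov(mu-hat, s^2) = mu3/n, var(mu-hat) = sig2/n)
  z2 <- vapply(which(keep), function(g) {
    mean_g <- mu[g]
    phi <- cf$nb_dispersion
    size <- 1 / phi
    sig2 <- mean_g + phi * mean_g^2
    hi <- qnbinom(1 - 1e-12, mu = mean_g, size = size)
    x <- 0:hi
    px <- dnbinom(x, mu = mean_g, size = size)
    mu3 <- sum(px * (x - mean_g)^3)
    mu4 <- sum(px * (x - mean_g)^4)
    dsig <- 1 + 2 * phi * mean_g
    var_s2 <- (mu4 - sig2^2 * (n - 3) / (n - 1)) / n -
      2 * dsig * mu3 / n + dsig^2 * sig2 / n
    ((s2[g] - sig2) / sqrt(var_s2))^2
  }, numeric(1))
  p <- pchisq(sum(z2), df = length(z2), lower.tail = FALSE)
  expect_gt(p, 0.01)
  # also the other tail: variances not systematically small
  expect_gt(pchisq(sum(z2), df = length(z2)), 0.01)
})

test_that("bulk cohort respects censoring, determinism and argument checks", {
  sig <- toy_signature()
  a <- simulate_bulk_cohort(60, sig, true_hr = 2, censor_rate = 0, seed = 3)
  expect_true(all(a$clinical$event == 1))
  b1 <- simulate_bulk_cohort(60, sig, true_hr = 2, seed = 4)
  b2 <- simulate_bulk_cohort(60, sig, true_hr = 2, seed = 4)
  expect_identical(b1$expr, b2$expr)
  expect_identical(b1$clinical, b2$clinical)
  expect_true(all(b1$clinical$time > 0))
  tr <- attr(b1, "truth")
  expect_equal(sum(tr$group), sum(!tr$group), tolerance = 0.05)
  expect_error(simulate_bulk_cohort(9, sig, true_hr = 2, seed = 1), ">= 10")
  expect_error(simulate_bulk_cohort(50, sig, true_hr = -1, seed = 1), "> 0")
})

test_that("regional atlas is deterministic, z-scaled, and encodes the planted bias", {
  sig <- toy_signature()
  a <- simulate_regional_atlas(seed = 2, signature = sig)
  b <- simulate_regional_atlas(seed = 2, signature = sig)
  expect_identical(a$values, b$values)
  expect_equal(unname(colMeans(a$values)), rep(0, ncol(a$values)), tolerance = 1e-10)
  sds <- apply(a$values, 2, sd)
  expect_equal(unname(sds), rep(1, ncol(a$values)), tolerance = 1e-10)
  expect_error(simulate_regional_atlas(structures = "one", seed = 1, signature = sig),
               "2 structures")
})

test_that("study orchestration yields a coherent homologue pool", {
  st <- simulate_study(small_config(seed = 9), n_mouse_total = 500, n_mouse_dual = 300)
  expect_equal(sum(st$mouse_table$dual_model_flag), 300)
  # every candidate's mouse counterpart is dual-model and mapped
  cand <- st$truth$candidates
  mouse_of <- st$homology$mouse_gene[match(cand$gene, st$homology$human_gene)]
  expect_false(anyNA(mouse_of))
  rows <- st$mouse_table[match(mouse_of, st$mouse_table$mouse_gene), ]
  expect_true(all(rows$dual_model_flag))
  expect_identical(rows$lineage, cand$mouse_lineage)
  # the homologue filter recovers exactly the candidate pool
  expr <- cpm_normalize(st$counts)
  tam_ids <- st$truth$cells$cell_id[st$truth$cells$lineage != "neoplastic"]
  feats <- select_homologue_features(expr[, expr$cells$cell_id %in% tam_ids],
                                     st$mouse_table, st$homology)
  expect_setequal(feats, cand$gene)
})
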