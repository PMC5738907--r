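# Transforms, Varimax PCA, GMM partitioning, signature extraction,
# enrichment, MFA and consensus clustering.

make_expr <- function(values, platform = NULL, scale = "logcpm") {
  ng <- nrow(values); nc <- ncol(values)
  genes <- data.frame(gene_id = sprintf("G%03d", seq_len(ng)),
                      symbol = rownames(values) %||% sprintf("S%03d", seq_len(ng)),
                      chrom = "chr1", start = (seq_len(ng) - 1) * 1e6,
                      end = (seq_len(ng) - 1) * 1e6 + 2e4)
  cells <- data.frame(cell_id = colnames(values) %||% sprintf("c%03d", seq_len(nc)),
                      sample_id = "S",
                      platform = platform %||% rep("C1", nc))
  tam_expr(values, genes, cells, scale = scale)
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("log transform hits its fixed points and guards its domain", {
  v <- matrix(c(0, 10, 70, 30), nrow = 4,
              dimnames = list(NULL, "c1"))
  expr <- make_expr(v, scale = "cpm")
  lg <- log_transform(expr)
  expect_identical(as.numeric(lg$values[1:3, 1]), c(0, 1, 3))
  expect_equal(lg$scale, "logcpm")
  neg <- make_expr(matrix(c(-1, 2), nrow = 2), scale = "cpm")
  expect_error(log_transform(neg), "negative")
  expect_error(log_transform(lg), "cpm scale")
})

test_that("per-platform z-scoring centers, scales, flags and absorbs offsets", {
  set.seed(3)
  v <- matrix(rnorm(50 * 40, 5), nrow = 50)
  v[7, 1:20] <- 2                      # constant within platform C1
  plat <- rep(c("C1", "SS2"), each = 20)
  expr <- make_expr(abs(v), platform = plat, scale = "logcpm")
  z <- zscore_by_platform(expr)
  for (p in c("C1", "SS2")) {
    j <- plat == p
    expect_equal(unname(rowMeans(z$values[, j])), rep(0, 50), tolerance = 1e-10)
    sds <- apply(z$values[, j], 1, sd)
    expect_equal(unname(sds[-7][1:10]), rep(1, 10), tolerance = 1e-10)
  }
  expect_true(z$genes$symbol[7] %in% z$flagged_genes)
  expect_true(all(z$values[7, plat == "C1"] == 0))
  # platform-constant offsets vanish
  shifted <- expr
  shifted$values[, plat == "SS2"] <- shifted$values[, plat == "SS2"] + 3
  z2 <- zscore_by_platform(shifted)
  expect_equal(z$values, z2$values, tolerance = 1e-12)
  # a single-cell platform is an error
  one <- make_expr(abs(v[, 1:21]), platform = c(rep("C1", 20), "SS2"),
                   scale = "logcpm")
  expect_error(zscore_by_platform(one), "fewer than 2")
})

test_that("homologue selection applies the strict mean-CPM filter", {
  v <- matrix(c(2.0, 2.0,      # mean 2.0 -> retained
                1.0, 1.0,      # mean 1.0 -> dropped (strict >)
                9.0, 9.0),     # unmapped -> absent
              nrow = 3, byrow = TRUE,
              dimnames = list(c("KEEP", "EDGE", "LOST"), NULL))
  expr <- make_expr(v, scale = "cpm")
  mouse <- data.frame(mouse_gene = c("mkeep", "medge", "mlost"),
                      lineage = "blood", dual_model_flag = TRUE)
  map <- data.frame(mouse_gene = c("mkeep", "medge"),
                    human_gene = c("KEEP", "EDGE"))
  expect_identical(select_homologue_features(expr, mouse, map), "KEEP")
  empty_map <- data.frame(mouse_gene = "mnone", human_gene = "NONE")
  expect_error(select_homologue_features(expr, mouse, empty_map), "diagnostic|filtering")
})

test_that("pca_varimax recovers the analytic two-gene case and is orthogonal", {
  set.seed(11)
  g1 <- rnorm(40)
  x <- rbind(A = scale(g1)[, 1], B = -scale(g1)[, 1])
  expr <- make_expr(x, scale = "logcpm")
  expr$scale <- "z"
  suppressWarnings(pc <- pca_varimax(expr, c("A", "B"), n_components = 2))
  expect_equal(unname(pc$explained_variance[1]), 1, tolerance = 1e-10)
  # unit eigenvector entries are sqrt(2)/2 each
  expect_equal(abs(unname(pc$unrotated$rotation[, 1])), rep(sqrt(2) / 2, 2),
               tolerance = 1e-10)
  # perfectly anticorrelated genes load with opposite sign and equal weight
  expect_equal(abs(pc$loadings["A", 1]), abs(pc$loadings["B", 1]), tolerance = 1e-10)
  expect_lt(pc$loadings["A", 1] * pc$loadings["B", 1], 0)
})

test_that("varimax rotation is orthogonal, variance-ordered and reconstruction-preserving", {
  set.seed(12)
  x <- matrix(rnorm(50 * 20), nrow = 20)   # 20 genes x 50 cells
  rownames(x) <- sprintf("S%03d", 1:20)
  expr <- make_expr(x, scale = "logcpm"); expr$scale <- "z"
  pc <- pca_varimax(expr, rownames(x), n_components = 8)
  R <- pc$rotmat
  expect_lt(max(abs(crossprod(R) - diag(ncol(R)))), 1e-8)
  # components ordered by post-rotation sum of squared loadings
  ss <- colSums(pc$loadings^2)
  expect_true(all(diff(ss) <= 1e-10))
  # rotation stays within the retained subspace: rotated reconstruction
  # equals the unrotated k-component reconstruction
  rec_rot <- pc$scores %*% t(pc$loadings)
  rec_raw <- pc$unrotated$x %*% t(pc$unrotated$rotation)
  expect_lt(max(abs(rec_rot - rec_raw)), 1e-8)
  # Varimax criterion never decreases
  crit <- function(L) sum(apply(L^2, 2, var))
  expect_gte(crit(pc$loadings), crit(pc$unrotated$loadings) - 1e-12)
  # sign convention: largest-magnitude entry of each column is positive
  expect_true(all(apply(pc$loadings, 2, function(v) v[which.max(abs(v))] > 0)))
  # requesting more components than the rank warns and reduces
  small <- make_expr(x[1:3, ], scale = "logcpm"); small$scale <- "z"
  expect_warning(pca_varimax(small, rownames(x)[1:3], n_components = 10),
                 "rank")
})

test_that("1-D GMM separates planted components and quantifies overlap", {
  set.seed(21)
  x <- c(rnorm(100, -3), rnorm(100, 3))
  fit <- fit_gmm_1d(x, seed = 5)
  expect_gt(matthews_correlation(fit$assignment, rep(1:2, each = 100)), 0.95)
  expect_lt(fit$overlap, 0.05)
  expect_equal(sum(fit$weight), 1, tolerance = 1e-12)
  expect_true(all(diff(fit$mean) > 0))
  # coincident equal-weight components overlap by exactly one half
  expect_equal(tamont:::gmm_overlap(c(0, 0), c(1, 1), c(0.5, 0.5)), 0.5,
               tolerance = 1e-10)
  # two points get one component each
  two <- fit_gmm_1d(c(-1, 1), seed = 2)
  expect_equal(two$assignment, 1:2)
  expect_error(fit_gmm_1d(c(1, NA, 3)), "finite")
  # same seed, same fit
  expect_identical(fit_gmm_1d(x, seed = 5)$loglik, fit$loglik)
})

test_that("EM log-likelihood matches an independent mixture implementation", {
  skip_if_not_installed("mclust")
  mclustBIC <- mclust::mclustBIC   # Mclust resolves this in the caller
  set.seed(22)
  x <- c(rnorm(150, -2, 1), rnorm(100, 2, 1.5))
  ours <- fit_gmm_1d(x, seed = 7)
  theirs <- mclust::Mclust(x, G = 2, modelNames = "V", verbose = FALSE)
  # the restarted EM must do at least as well, and land on the same optimum
  expect_gte(ours$loglik, theirs$loglik - 1e-6)
  expect_lt(abs(ours$loglik - theirs$loglik) / abs(theirs$loglik), 1e-3)
})

test_that("signature extraction thresholds strictly and orients by enrichment", {
  genes <- sprintf("H%02d", 1:10)
  loadings <- matrix(c(0.85, 0.7, 0.6, 0.5, 0.20, -0.75, -0.65, -0.55, -0.05, 0.02),
                     ncol = 1, dimnames = list(genes, "PC1"))
  pca <- structure(list(loadings = loadings), class = "tam_pca")
  mouse <- data.frame(mouse_gene = paste0("m", genes),
                      lineage = c(rep("blood", 5), rep("microglia", 5)),
                      dual_model_flag = TRUE)
  map <- data.frame(mouse_gene = paste0("m", genes), human_gene = genes)
  sig <- extract_signature(pca, mouse, map, threshold = 0.2)
  # |loading| = 0.20 exactly is excluded (strict >)
  expect_false("H05" %in% sig$gene)
  expect_setequal(sig$gene, c("H01", "H02", "H03", "H04", "H06", "H07", "H08"))
  # positive loaders are blood (their mouse counterparts are blood markers)
  expect_true(all(sig$lineage[sig$loading > 0] == "blood"))
  expect_true(all(sig$lineage[sig$loading < 0] == "microglia"))
  expect_lt(attr(sig, "orientation_p"), 0.1)
  # no gene passing the threshold is an error
  tiny <- structure(list(loadings = loadings / 10), class = "tam_pca")
  expect_error(extract_signature(tiny, mouse, map), "threshold")
  # ambiguous orientation is an error
  mixed <- mouse
  mixed$lineage <- rep(c("blood", "microglia"), 5)
  expect_error(extract_signature(pca, mixed, map), "ambiguous")
})

test_that("lineage enrichment matches exact hypergeometric enumeration", {
  mk_inputs <- function(pos_blood, pos_mg, neg_blood, neg_mg) {
    n <- pos_blood + pos_mg + neg_blood + neg_mg
    genes <- sprintf("G%03d", seq_len(n))
    lineage <- c(rep("blood", pos_blood), rep("microglia", pos_mg),
                 rep("blood", neg_blood), rep("microglia", neg_mg))
    loadings <- setNames(c(rep(0.5, pos_blood + pos_mg),
                           rep(-0.5, neg_blood + neg_mg)), genes)
    mouse <- data.frame(mouse_gene = paste0("m", genes), lineage = lineage,
                        dual_model_flag = TRUE)
    map <- data.frame(mouse_gene = paste0("m", genes), human_gene = genes)
    list(loadings = loadings, mouse = mouse, map = map)
  }
  inp <- mk_inputs(10, 0, 0, 10)
  res <- lineage_enrichment_test(inp$loadings, inp$mouse, inp$map)
  expect_equal(res$p, fisher_p_enum(10, 0, 0, 10))
  expect_true(is.infinite(res$or))
  expect_equal(res$positive_lineage, "blood")
  # independent margins give p = 1
  bal <- mk_inputs(5, 5, 5, 5)
  expect_equal(lineage_enrichment_test(bal$loadings, bal$mouse, bal$map)$p, 1.0)
  # swapping the sign rows leaves p unchanged
  sw <- mk_inputs(0, 10, 10, 0)
  expect_equal(lineage_enrichment_test(sw$loadings, sw$mouse, sw$map)$p, res$p)
  # empty margin flagged
  deg <- mk_inputs(4, 6, 0, 0)
  expect_true(lineage_enrichment_test(deg$loadings, deg$mouse, deg$map)$degenerate)
})

test_that("MFA scaling makes duplicated and rescaled tables contribute equally", {
  set.seed(31)
  m <- matrix(rnorm(30 * 12), nrow = 30,
              dimnames = list(NULL, sprintf("S%03d", 1:12)))
  dup <- mfa_combine(list(m, m))
  expect_equal(dup$inertia_ratio, 1.0, tolerance = 1e-8)
  tripled <- mfa_combine(list(m, 3 * m))
  expect_equal(tripled$inertia_ratio, 1.0, tolerance = 1e-8)
  expect_equal(tripled$scaling_factors[2] / tripled$scaling_factors[1], 3,
               tolerance = 1e-8)
  # single table degenerates to its own PCA scores
  single <- mfa_combine(list(m))
  pc <- prcomp(m, center = TRUE, scale. = FALSE)
  k <- ncol(single$scores)
  expect_lt(max(abs(abs(single$scores) - abs(pc$x[, 1:k]))), 1e-8)
  expect_true(is.na(single$inertia_ratio))
  # disjoint gene sets are an error
  m2 <- m; colnames(m2) <- sprintf("T%03d", 1:12)
  expect_error(mfa_combine(list(m, m2)), "share no genes")
})

test_that("consensus clustering recovers planted blobs deterministically", {
  set.seed(41)
  x <- rbind(matrix(rnorm(60 * 10, -2), ncol = 10),
             matrix(rnorm(60 * 10, 2), ncol = 10))
  truth <- rep(1:2, each = 60)
  cl <- consensus_cluster(x, k = 2, seed = 9)
  expect_gt(matthews_correlation(cl$label, truth), 0.95)
  cl2 <- consensus_cluster(x, k = 2, seed = 9)
  expect_identical(cl$label, cl2$label)
  # duplicated cells land in the same cluster as their originals
  xd <- rbind(x, x)
  cld <- consensus_cluster(xd, k = 2, seed = 9)
  expect_equal(unname(cld$label[1:120]), unname(cld$label[121:240]))
  expect_error(consensus_cluster(matrix(1, 20, 5), k = 2, seed = 1), "constant")
})

test_that("Matthews correlation handles matching, inversion and independence", {
  a <- rep(c(1, 2), 50)
  expect_equal(matthews_correlation(a, a), 1.0)
  expect_equal(matthews_correlation(a, 3 - a), 1.0)   # inverted labels match
  set.seed(51)
  r1 <- sample(1:2, 10000, replace = TRUE)
  r2 <- sample(1:2, 10000, replace = TRUE)
  expect_lt(abs(matthews_correlation(r1, r2)), 0.05)
  expect_warning(m0 <- matthews_correlation(rep(1, 10), rep(c(1, 2), 5)),
                 "degenerate")
  expect_equal(m0, 0)
  expect_error(matthews_correlation(1:3, 1:2), "same cells")
})

test_that("platform-wide count scaling leaves the derived signature unchanged", {
  st <- simulate_study(small_config(seed = 31))
  run1 <- derive_ontogeny_signature(st$counts, st$mouse_table, st$homology,
                                    cnv = st$cnv, variants = st$variants,
                                    markers = st$markers, seed = 2,
                                    min_genes = 150, min_reads = 0)
  # doubling every count on one platform leaves CPM and detection untouched
  # (with the read threshold out of play) and becomes a per-platform shift
  # on the log scale, which the z-scoring absorbs exactly
  counts2 <- st$counts
  ss2 <- counts2$cells$platform == "SS2"
  counts2$counts[, ss2] <- counts2$counts[, ss2] * 2L
  run2 <- derive_ontogeny_signature(counts2, st$mouse_table, st$homology,
                                    cnv = st$cnv, variants = st$variants,
                                    markers = st$markers, seed = 2,
                                    min_genes = 150, min_reads = 0)
  expect_identical(run1$signature, run2$signature)
  expect_identical(run1$partition$lineage, run2$partition$lineage)
})

test_that("the derivation is deterministic under a fixed seed", {
  st <- simulate_study(small_config(seed = 33))
  r1 <- derive_ontogeny_signature(st$counts, st$mouse_table, st$homology,
                                  cnv = st$cnv, variants = st$variants,
                                  markers = st$markers, seed = 4,
                                  min_genes = 150, min_reads = 20000)
  r2 <- derive_ontogeny_signature(st$counts, st$mouse_table, st$homology,
                                  cnv = st$cnv, variants = st$variants,
                                  markers = st$markers, seed = 4,
                                  min_genes = 150, min_reads = 20000)
  expect_identical(r1$signature, r2$signature)
  expect_identical(r1$partition, r2$partition)
})
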