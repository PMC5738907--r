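# Derivation of the lineage signature: homologue feature selection, log and
# per-platform z transforms, Varimax-rotated PCA, 1-D Gaussian-mixture
# partitioning of PC1, loading-threshold signature extraction, lineage
# enrichment, multi-table factor analysis, and consensus-clustering
# cross-validation.

#' Select murine-homologue candidate features
#'
#' Returns the human genes that (i) are mapped homologues of mouse genes
#' flagged as differential in both murine models and (ii) have mean CPM
#' strictly above `min_mean_cpm` across the supplied cells.
#'
#' @param expr a `tam_expr` on the `"cpm"` scale (typically TAM cells only).
#' @param mouse_table murine lineage table with columns `mouse_gene`,
#'   `dual_model_flag`.
#' @param map homology map with columns `mouse_gene`, `human_gene`.
#' @param min_mean_cpm expression filter threshold (strict inequality).
#' @return Character vector of retained human gene symbols.
#' @export
select_homologue_features <- function(expr, mouse_table, map, min_mean_cpm = 1) {
  stopifnot(inherits(expr, "tam_expr"))
  if (expr$scale != "cpm") stop("expr must be on the cpm scale")
  dual <- mouse_table$mouse_gene[mouse_table$dual_model_flag]
  mapped <- map$human_gene[map$mouse_gene %in% dual]
  present <- intersect(mapped, expr$genes$symbol)
  idx <- match(present, expr$genes$symbol)
  mean_cpm <- Matrix::rowMeans(expr$values[idx, , drop = FALSE])
  keep <- present[mean_cpm > min_mean_cpm]
  if (length(keep) == 0) {
    stop(sprintf(paste0("no candidate genes survive filtering: %d dual-model mouse genes, ",
                        "%d mapped homologues, %d present in matrix, 0 above %g mean CPM"),
                 length(dual), length(mapped), length(present), min_mean_cpm))
  }
  keep
}

#' Log-transform CPM values
#'
#' Applies `log2(CPM / 10 + 1)` elementwise; monotone and zero-preserving.
#'
#' @param expr a `tam_expr` on the `"cpm"` scale.
#' @return A `tam_expr` on the `"logcpm"` scale.
#' @export
log_transform <- function(expr) {
  stopifnot(inherits(expr, "tam_expr"))
  if (expr$scale != "cpm") stop("expr must be on the cpm scale")
  v <- expr$values
  if (inherits(v, "sparseMatrix")) {
    if (any(v@x < 0)) stop("negative expression values")
    v@x <- log2(v@x / 10 + 1)
  } else {
    if (any(v < 0)) stop("negative expression values")
    v <- log2(v / 10 + 1)
  }
  tam_expr(v, expr$genes, expr$cells, scale = "logcpm")
}

#' Z-score genes within each platform
#'
#' Within each capture platform independently, each gene is centered and
#' scaled to unit SD across that platform's cells, absorbing platform-level
#' location/scale differences. Genes constant within a platform are set to 0
#' there and recorded in `flagged_genes`.
#'
#' @param expr a `tam_expr` on the `"logcpm"` scale.
#' @return A dense `tam_expr` on the `"z"` scale.
#' @export
zscore_by_platform <- function(expr) {
  stopifnot(inherits(expr, "tam_expr"))
  if (expr$scale != "logcpm") stop("expr must be on the logcpm scale")
  platforms <- unique(expr$cells$platform)
  x <- as.matrix(expr$values)
  flagged <- character()
  for (p in platforms) {
    j <- which(expr$cells$platform == p)
    if (length(j) < 2) stop(sprintf("platform '%s' has fewer than 2 cells", p))
    mu <- rowMeans(x[, j, drop = FALSE])
    sd <- apply(x[, j, drop = FALSE], 1, stats::sd)
    zero <- sd == 0
    sd[zero] <- 1
    x[, j] <- (x[, j, drop = FALSE] - mu) / sd
    x[zero, j] <- 0
    flagged <- union(flagged, expr$genes$symbol[zero])
  }
  tam_expr(x, expr$genes, expr$cells, scale = "z", flagged_genes = flagged)
}

#' PCA with Varimax rotation
#'
#' Principal component analysis of cells in the space of the candidate
#' genes, followed by Kaiser-normalized Varimax rotation of the component
#' loadings. Loadings are on the correlation scale (unit eigenvectors scaled
#' by component SD), so for z-scored input a gene's unrotated PC1 loading is
#' its correlation with PC1; the raw unit eigenvectors are kept in
#' `$unrotated$rotation`. After rotation, components are reordered by
#' decreasing sum of squared loadings and each loading column is flipped so
#' its largest-magnitude entry is positive; lineage orientation is decided
#' later by the enrichment test, never by this sign convention.
#'
#' @param expr a `tam_expr` on the `"z"` scale.
#' @param genes candidate gene symbols (subset of the matrix genes).
#' @param n_components components retained before rotation; reduced with a
#'   warning when the matrix rank is lower.
#' @return An object of class `tam_pca`: `loadings` (genes x components,
#'   rotated), `scores` (cells x components, rotated standardized scores),
#'   `rotmat` (orthogonal Varimax rotation), `explained_variance`
#'   (post-rotation share of total variance), `sdev`, and `unrotated`
#'   (`rotation`, `x`, `loadings`).
#' @export
pca_varimax <- function(expr, genes, n_components = 10) {
  stopifnot(inherits(expr, "tam_expr"))
  if (expr$scale != "z") stop("expr must be on the z scale")
  idx <- match(genes, expr$genes$symbol)
  if (anyNA(idx)) stop("unknown candidate genes: ",
                       paste(utils::head(genes[is.na(idx)], 5), collapse = ", "))
  x <- t(as.matrix(expr$values[idx, , drop = FALSE]))   # cells x genes
  n <- nrow(x); p <- ncol(x)
  pc <- stats::prcomp(x, center = TRUE, scale. = FALSE)
  rank <- sum(pc$sdev > max(pc$sdev) * 1e-10)
  k <- min(n_components, rank, n - 1L, p)
  if (k < n_components) {
    warning(sprintf("rank-deficient input: retaining %d of %d requested components",
                    k, n_components))
  }
  load_raw <- pc$rotation[, seq_len(k), drop = FALSE] %*%
    diag(pc$sdev[seq_len(k)], k, k)                     # correlation-scale loadings
  scores_std <- sweep(pc$x[, seq_len(k), drop = FALSE], 2,
                      pc$sdev[seq_len(k)], `/`)         # unit-variance scores
  if (k >= 2) {
    vm <- stats::varimax(load_raw, normalize = TRUE, eps = 1e-9)
    rotmat <- vm$rotmat
  } else {
    rotmat <- diag(1)
  }
  loadings <- load_raw %*% rotmat
  scores <- scores_std %*% rotmat
  ss <- colSums(loadings^2)
  ord <- order(ss, decreasing = TRUE)
  loadings <- loadings[, ord, drop = FALSE]
  scores <- scores[, ord, drop = FALSE]
  rotmat <- rotmat[, ord, drop = FALSE]
  flip <- apply(loadings, 2, function(v) sign(v[which.max(abs(v))]))
  flip[flip == 0] <- 1
  loadings <- sweep(loadings, 2, flip, `*`)
  scores <- sweep(scores, 2, flip, `*`)
  rotmat <- sweep(rotmat, 2, flip, `*`)
  cn <- paste0("PC", seq_len(k))
  dimnames(loadings) <- list(genes, cn)
  dimnames(scores) <- list(expr$cells$cell_id, cn)
  total_var <- sum(pc$sdev^2)
  structure(list(loadings = loadings,
                 scores = scores,
                 rotmat = rotmat,
                 explained_variance = colSums(loadings^2) / total_var,
                 sdev = pc$sdev[seq_len(k)],
                 unrotated = list(rotation = pc$rotation[, seq_len(k), drop = FALSE],
                                  x = pc$x[, seq_len(k), drop = FALSE],
                                  loadings = load_raw,
                                  total_variance = total_var)),
            class = "tam_pca")
}

#' @export
print.tam_pca <- function(x, ...) {
  cat(sprintf("<tam_pca> %d genes, %d cells, %d rotated components (PC1 var share %.3f)\n",
              nrow(x$loadings), nrow(x$scores), ncol(x$loadings),
              x$explained_variance[1]))
  invisible(x)
}

#' Fit a 1-D two-component Gaussian mixture by EM
#'
#' Expectation-maximization with k-means-seeded restarts, a variance floor
#' to prevent component collapse, and convergence on the log-likelihood.
#' Components are ordered by increasing mean. The overlap mass is
#' `integral of min(pi_1 phi_1, pi_2 phi_2)` computed by trapezoidal
#' quadrature over the mean +/- 8 SD range; it equals 0.5 exactly for
#' coincident equal-weight components and is bounded by 0.5.
#'
#' @param x numeric vector of scores (PC1 values).
#' @param k number of components (the partitioning uses k = 2).
#' @param seed RNG seed for the restarts.
#' @param tol log-likelihood convergence tolerance.
#' @param max_iter maximum EM iterations per restart.
#' @param n_restarts k-means-seeded restarts; the best likelihood is kept.
#' @param var_floor lower bound on component variances.
#' @return An object of class `tam_gmm`: `mean`, `var`, `weight` (length k),
#'   `posterior` (n x k), `assignment` (component of maximum posterior),
#'   `overlap`, `loglik`, `n_iter`.
#' @export
fit_gmm_1d <- function(x, k = 2, seed = 1L, tol = 1e-8, max_iter = 500,
                       n_restarts = 10, var_floor = 1e-6) {
  if (!is.numeric(x) || any(!is.finite(x))) stop("scores must be finite numeric")
  n <- length(x)
  if (n < k) stop("need at least k observations")
  best <- NULL
  with_seed(seed, {
    for (r in seq_len(n_restarts)) {
      centers <- if (r == 1) {
        stats::quantile(x, probs = (seq_len(k) - 0.5) / k, names = FALSE)
      } else {
        tryCatch(stats::kmeans(x, centers = k, nstart = 1)$centers[, 1],
                 error = function(e) sample(x, k))
      }
      fit <- em_gmm_1d(x, sort(centers), tol, max_iter, var_floor)
      if (is.null(best) || fit$loglik > best$loglik) best <- fit
    }
  })
  ord <- order(best$mean)
  post <- best$posterior[, ord, drop = FALSE]
  out <- list(mean = best$mean[ord], var = best$var[ord],
              weight = best$weight[ord], posterior = post,
              assignment = max.col(post),
              overlap = gmm_overlap(best$mean[ord], best$var[ord], best$weight[ord]),
              loglik = best$loglik, n_iter = best$n_iter)
  class(out) <- "tam_gmm"
  out
}

em_gmm_1d <- function(x, mu, tol, max_iter, var_floor) {
  k <- length(mu)
  n <- length(x)
  sig2 <- rep(max(stats::var(x) / k, var_floor), k)
  w <- rep(1 / k, k)
  ll_old <- -Inf
  it <- 0L
  repeat {
    it <- it + 1L
    dens <- vapply(seq_len(k), function(j) w[j] * stats::dnorm(x, mu[j], sqrt(sig2[j])),
                   numeric(n))
    tot <- rowSums(dens)
    tot[tot == 0] <- .Machine$double.xmin
    post <- dens / tot
    ll <- sum(log(tot))
    nk <- colSums(post)
    nk[nk == 0] <- .Machine$double.eps
    w <- nk / n
    mu <- colSums(post * x) / nk
    sig2 <- pmax(colSums(post * (x - rep(mu, each = n))^2) / nk, var_floor)
    if (abs(ll - ll_old) < tol || it >= max_iter) break
    ll_old <- ll
  }
  list(mean = mu, var = sig2, weight = w, posterior = post, loglik = ll, n_iter = it)
}

# Overlap mass of a k-component 1-D mixture: integral of the pointwise
# minimum of the weighted component densities (k = 2 in practice).
gmm_overlap <- function(mu, sig2, w, n_grid = 20001L) {
  sd <- sqrt(sig2)
  lo <- min(mu - 8 * max(sd))
  hi <- max(mu + 8 * max(sd))
  g <- seq(lo, hi, length.out = n_grid)
  dens <- vapply(seq_along(mu), function(j) w[j] * stats::dnorm(g, mu[j], sd[j]),
                 numeric(n_grid))
  y <- apply(dens, 1, min)
  sum((y[-1] + y[-n_grid]) / 2) * (g[2] - g[1])
}

#' @export
print.tam_gmm <- function(x, ...) {
  cat(sprintf("<tam_gmm> k=%d; means %s; overlap %.4f\n", length(x$mean),
              paste(sprintf("%.3f", x$mean), collapse = ", "), x$overlap))
  invisible(x)
}

#' Extract the lineage signature from rotated PC1 loadings
#'
#' Genes with `|PC1 loading| > threshold` (strict) form the signature. The
#' lineage orientation of the axis is fixed by a two-sided Fisher's exact
#' test on the 2x2 table of loading sign against murine lineage among the
#' selected genes: the sign direction enriched for murine blood-derived
#' markers is labeled blood-derived. An ambiguous orientation (p > 0.1) is
#' an error, as is an empty selection.
#'
#' @param pca a [pca_varimax()] result.
#' @param mouse_table murine lineage table (`mouse_gene`, `lineage`,
#'   `dual_model_flag`).
#' @param map homology map (`mouse_gene`, `human_gene`).
#' @param threshold absolute-loading threshold.
#' @return A [signature_gene_set()] with the enrichment p recorded in the
#'   `orientation_p` attribute.
#' @export
extract_signature <- function(pca, mouse_table, map, threshold = 0.2) {
  stopifnot(inherits(pca, "tam_pca"))
  l1 <- pca$loadings[, 1]
  pass <- abs(l1) > threshold
  if (!any(pass)) stop("no gene passes the loading threshold")
  sel <- names(l1)[pass]
  enr <- lineage_enrichment_test(l1[pass], mouse_table, map)
  if (is.na(enr$p) || enr$p > 0.1) {
    stop(sprintf("lineage orientation of PC1 is ambiguous (Fisher p = %.3g)", enr$p))
  }
  pos_lineage <- enr$positive_lineage
  neg_lineage <- setdiff(c("blood", "microglia"), pos_lineage)
  lineage <- ifelse(l1[pass] > 0, pos_lineage, neg_lineage)
  signature_gene_set(sel, lineage, l1[pass], threshold = threshold,
                     orientation_p = enr$p)
}

#' Test lineage enrichment of PC1 loading signs
#'
#' Builds the 2x2 table of loading sign (positive/negative) against murine
#' lineage (blood/microglia) for the genes whose mouse counterparts carry a
#' lineage label, and applies a two-sided Fisher's exact test. The sample
#' odds ratio is `(a d)/(b c)` and is reported as `Inf`/0 with a flag when a
#' cell is empty.
#'
#' @param loadings named numeric vector of PC1 loadings (names are human
#'   gene symbols).
#' @param mouse_table,map as in [extract_signature()].
#' @return A list: `table` (2x2), `or`, `p`, `positive_lineage` (the lineage
#'   enriched among positive loadings), `degenerate` (flag for an empty
#'   margin, in which case `p` is `NA`).
#' @export
lineage_enrichment_test <- function(loadings, mouse_table, map) {
  human2mouse <- map$mouse_gene[match(names(loadings), map$human_gene)]
  lin <- mouse_table$lineage[match(human2mouse, mouse_table$mouse_gene)]
  ok <- !is.na(lin) & loadings != 0
  sgn <- factor(ifelse(loadings[ok] > 0, "positive", "negative"),
                levels = c("positive", "negative"))
  lin <- factor(lin[ok], levels = c("blood", "microglia"))
  tab <- table(sign = sgn, lineage = lin)
  degenerate <- any(rowSums(tab) == 0) || any(colSums(tab) == 0)
  if (degenerate) {
    return(list(table = tab, or = NA_real_, p = NA_real_,
                positive_lineage = NA_character_, degenerate = TRUE))
  }
  p <- min(1, stats::fisher.test(tab)$p.value)
  or <- (tab[1, 1] * tab[2, 2]) / (tab[1, 2] * tab[2, 1])
  pos_lineage <- if (tab[1, 1] * tab[2, 2] >= tab[1, 2] * tab[2, 1]) "blood" else "microglia"
  list(table = tab, or = or, p = p, positive_lineage = pos_lineage,
       degenerate = FALSE)
}

#' Combine expression tables by multiple factor analysis
#'
#' Each table (cells x shared genes) is scaled by its first singular value,
#' the scaled tables are concatenated over cells, and a PCA is run on the
#' concatenation. The partial inertia of a table is the sum of squared
#' scores of its cells over all retained components; their ratio
#' (table 1 over table 2, in input order) measures how evenly the tables
#' contribute to the combined structure.
#'
#' @param tables list of `tam_expr` objects on the `"z"` scale, or plain
#'   cells-by-genes matrices. A single table degenerates to its plain PCA
#'   (no scaling, `inertia_ratio` is `NA`).
#' @param genes shared gene symbols; defaults to the intersection.
#' @return An object of class `tam_mfa`: `scores`, `loadings`, `sdev`,
#'   `scaling_factors` (first singular values), `partial_inertia`,
#'   `inertia_ratio`, `table_id` (per concatenated cell).
#' @export
mfa_combine <- function(tables, genes = NULL) {
  if (length(tables) < 1) stop("need at least 1 table")
  mats <- lapply(tables, function(t) {
    if (inherits(t, "tam_expr")) {
      m <- t(as.matrix(t$values))
      colnames(m) <- t$genes$symbol
      m
    } else {
      as.matrix(t)
    }
  })
  if (is.null(genes)) genes <- Reduce(intersect, lapply(mats, colnames))
  if (length(genes) == 0) stop("tables share no genes")
  mats <- lapply(mats, function(m) m[, genes, drop = FALSE])
  d1 <- vapply(mats, function(m) svd(scale(m, center = TRUE, scale = FALSE),
                                     nu = 0, nv = 0)$d[1], numeric(1))
  if (any(d1 <= 0)) stop("degenerate table with zero first singular value")
  scaled <- if (length(mats) == 1) mats else Map(function(m, d) m / d, mats, d1)
  xc <- do.call(rbind, scaled)
  table_id <- rep(seq_along(mats), vapply(mats, nrow, integer(1)))
  pc <- stats::prcomp(xc, center = TRUE, scale. = FALSE)
  keep <- which(pc$sdev > max(pc$sdev) * 1e-10)
  scores <- pc$x[, keep, drop = FALSE]
  pi_t <- vapply(seq_along(mats), function(t) sum(scores[table_id == t, ]^2),
                 numeric(1))
  structure(list(scores = scores,
                 loadings = pc$rotation[, keep, drop = FALSE],
                 sdev = pc$sdev[keep],
                 scaling_factors = d1,
                 partial_inertia = pi_t,
                 inertia_ratio = if (length(mats) >= 2) pi_t[1] / pi_t[2] else NA_real_,
                 table_id = table_id),
            class = "tam_mfa")
}

#' @export
print.tam_mfa <- function(x, ...) {
  cat(sprintf("<tam_mfa> %d tables, %d cells; partial-inertia ratio %.3f\n",
              length(x$partial_inertia), nrow(x$scores), x$inertia_ratio))
  invisible(x)
}

#' Consensus clustering of cells
#'
#' A compact consensus scheme in the style of single-cell consensus
#' clustering: Euclidean, Pearson and Spearman cell-cell distance matrices
#' are each transformed two ways (leading principal components of the
#' distance matrix; eigenvectors of its normalized graph Laplacian), k-means
#' with 10 restarts is run over a grid of 4-7% of n leading dimensions, the
#' binary co-clustering matrices are averaged into a consensus matrix, and
#' the consensus is cut by complete-linkage hierarchical clustering at `k`.
#' For cohorts larger than `max_cells`, the consensus is built on a random
#' training subsample and the remaining cells are assigned to the nearest
#' training-cluster centroid.
#'
#' @param expr a `tam_expr` on the `"z"` scale, or a cells-by-genes matrix.
#' @param genes candidate gene symbols (ignored for a plain matrix).
#' @param k number of clusters.
#' @param seed RNG seed (the procedure is deterministic given the seed).
#' @param max_cells training-set ceiling for the consensus matrix.
#' @return An object of class `tam_clusters`: `label` (per-cell integer in
#'   `1..k`), `method`, `consensus` (training-set consensus matrix),
#'   `training_cells`.
#' @export
consensus_cluster <- function(expr, genes = NULL, k = 2, seed = 1L,
                              max_cells = 800) {
  if (inherits(expr, "tam_expr")) {
    if (expr$scale != "z") stop("expr must be on the z scale")
    genes <- genes %||% expr$genes$symbol
    idx <- match(genes, expr$genes$symbol)
    if (anyNA(idx)) stop("unknown genes in candidate list")
    x <- t(as.matrix(expr$values[idx, , drop = FALSE]))
    ids <- expr$cells$cell_id
  } else {
    x <- as.matrix(expr)
    ids <- rownames(x) %||% sprintf("cell%05d", seq_len(nrow(x)))
  }
  n <- nrow(x)
  if (n < 2 * k) stop("need at least 2k cells")
  if (stats::sd(as.vector(x)) == 0) stop("constant expression matrix")
  with_seed(seed, {
    train <- if (n > max_cells) sort(sample(n, max_cells)) else seq_len(n)
    xt <- x[train, , drop = FALSE]
    m <- length(train)
    dists <- list(euclidean = as.matrix(stats::dist(xt)),
                  pearson = 1 - stats::cor(t(xt)),
                  spearman = 1 - stats::cor(t(xt), method = "spearman"))
    d_grid <- unique(pmax(k, round(m * c(0.04, 0.05, 0.06, 0.07))))
    consensus <- matrix(0, m, m)
    n_runs <- 0L
    for (D in dists) {
      D[is.na(D)] <- 0
      for (trans in c("pca", "laplacian")) {
        feats <- if (trans == "pca") {
          stats::prcomp(D, center = TRUE, scale. = TRUE)$x
        } else {
          laplacian_eigen(D)
        }
        for (d in d_grid) {
          d_use <- min(d, ncol(feats))
          cl <- stats::kmeans(feats[, seq_len(d_use), drop = FALSE], centers = k,
                              nstart = 10, iter.max = 100)$cluster
          consensus <- consensus + outer(cl, cl, `==`)
          n_runs <- n_runs + 1L
        }
      }
    }
    consensus <- consensus / n_runs
    hc <- stats::hclust(stats::as.dist(1 - consensus), method = "complete")
    lab_train <- stats::cutree(hc, k = k)
    label <- integer(n)
    label[train] <- lab_train
    if (length(train) < n) {
      centroids <- t(vapply(seq_len(k), function(j) {
        colMeans(xt[lab_train == j, , drop = FALSE])
      }, numeric(ncol(xt))))
      rest <- setdiff(seq_len(n), train)
      dist_to <- vapply(seq_len(k), function(j) {
        rowSums(sweep(x[rest, , drop = FALSE], 2, centroids[j, ])^2)
      }, numeric(length(rest)))
      label[rest] <- max.col(-matrix(dist_to, nrow = length(rest)))
    }
    structure(list(label = stats::setNames(label, ids), method = "consensus",
                   consensus = consensus, training_cells = ids[train]),
              class = "tam_clusters")
  })
}

# Eigenvectors of the symmetric normalized graph Laplacian of the
# exponential affinity of a distance matrix, ordered by increasing
# eigenvalue (the informative end for clustering).
laplacian_eigen <- function(D) {
  A <- exp(-D / max(D))
  dg <- 1 / sqrt(rowSums(A))
  L <- diag(nrow(A)) - (A * dg) * rep(dg, each = nrow(A))
  e <- eigen(L, symmetric = TRUE)
  e$vectors[, order(e$values), drop = FALSE]
}

#' @export
print.tam_clusters <- function(x, ...) {
  cat(sprintf("<tam_clusters:%s> %d cells, %d clusters\n", x$method,
              length(x$label), length(unique(x$label))))
  invisible(x)
}

#' Matthews correlation between two binary partitions
#'
#' Computes the MCC on the 2x2 confusion table, maximized over the two
#' possible matchings of the arbitrary cluster labels. Degenerate
#' single-class inputs give 0 with a warning.
#'
#' @param a,b binary labelings of the same cells (any two-level vectors;
#'   `tam_clusters` objects are accepted).
#' @return MCC in `[-1, 1]` (after matching, in `[0, 1]` for two-cluster
#'   agreement).
#' @export
matthews_correlation <- function(a, b) {
  if (inherits(a, "tam_clusters")) a <- a$label
  if (inherits(b, "tam_clusters")) b <- b$label
  if (length(a) != length(b)) stop("labelings must cover the same cells")
  fa <- factor(a); fb <- factor(b)
  if (nlevels(fa) < 2 || nlevels(fb) < 2) {
    warning("degenerate single-class labeling; MCC set to 0")
    return(0)
  }
  if (nlevels(fa) > 2 || nlevels(fb) > 2) stop("labelings must be binary")
  mcc_of <- function(tab) {
    tp <- as.numeric(tab[1, 1]); tn <- as.numeric(tab[2, 2])
    fp <- as.numeric(tab[1, 2]); fn <- as.numeric(tab[2, 1])
    den <- sqrt((tp + fp) * (tp + fn) * (tn + fp) * (tn + fn))
    if (den == 0) return(0)
    (tp * tn - fp * fn) / den
  }
  tab <- table(fa, fb)
  max(mcc_of(tab), mcc_of(tab[2:1, , drop = FALSE]))
}
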