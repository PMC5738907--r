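# Two-group differential expression between TAM lineages and M1/M2 marker
# co-occurrence statistics.

#' Negative-binomial differential expression between two cell groups
#'
#' A per-gene Wald test on the difference of group log-means under a
#' negative-binomial model: library sizes are normalized by median-of-ratios
#' size factors, per-gene dispersions are estimated by the method of moments
#' within groups and shrunk toward a parametric mean-dispersion trend
#' `a0 + a1/mean` (halfway up when below the trend; raw estimates above the
#' trend are kept, so chance underestimates cannot inflate the statistic).
#' The Wald statistic uses the delta-method variance of a log group mean
#' with the per-group empirical variance floored by the trend prediction,
#' against a t reference with `n1 + n0 - 2` degrees of freedom. P values are
#' BH-adjusted across the tested genes; genes with all-zero counts are
#' excluded.
#'
#' @param counts a [tam_counts()] object or a gene-by-cell matrix.
#' @param groups two-level factor (or coercible) over cells. The reported
#'   fold-change is `numerator` over the other level.
#' @param numerator group level used as the fold-change numerator; defaults
#'   to the second factor level.
#' @param pseudo_mean normalized-count pseudo mean added to group means for
#'   a finite log fold-change when a group is all zero.
#' @return A `data.frame` (class `tam_de`) with one row per tested gene:
#'   `gene`, `base_mean`, `log2fc`, `stat`, `p`, `padj`, `dispersion`.
#' @export
differential_expression <- function(counts, groups, numerator = NULL,
                                    pseudo_mean = 0.5) {
  if (inherits(counts, "tam_counts")) {
    m <- counts$counts
    gene_names <- counts$genes$symbol
  } else {
    m <- counts
    gene_names <- rownames(m) %||% sprintf("gene%05d", seq_len(nrow(m)))
  }
  groups <- factor(groups)
  if (nlevels(groups) != 2) stop("groups must have exactly 2 levels")
  if (any(table(groups) < 5)) stop("need at least 5 cells per group")
  if (length(groups) != ncol(m)) stop("groups length must match cell count")
  numerator <- numerator %||% levels(groups)[2]
  if (!numerator %in% levels(groups)) stop("unknown numerator level")
  denominator <- setdiff(levels(groups), numerator)

  keep <- Matrix::rowSums(m) > 0
  m <- m[keep, , drop = FALSE]
  gene_names <- gene_names[keep]
  sf <- size_factors(m)
  y <- as.matrix(m) / rep(sf, each = nrow(m))

  j1 <- which(groups == numerator)
  j0 <- which(groups == denominator)
  n1 <- length(j1); n0 <- length(j0)
  m1 <- rowMeans(y[, j1, drop = FALSE])
  m0 <- rowMeans(y[, j0, drop = FALSE])
  v1 <- apply(y[, j1, drop = FALSE], 1, stats::var)
  v0 <- apply(y[, j0, drop = FALSE], 1, stats::var)
  base_mean <- (m1 * n1 + m0 * n0) / (n1 + n0)

  # method-of-moments dispersion, pooled within groups, then 50/50 shrinkage
  # toward the parametric trend phi(mu) = a0 + a1/mu
  disp_raw <- pmax(((v1 - m1) * (n1 - 1) + (v0 - m0) * (n0 - 1)) /
                     (m1^2 * (n1 - 1) + m0^2 * (n0 - 1) + 1e-300), 0)
  usable <- disp_raw > 0 & base_mean > 1
  trend <- if (sum(usable) >= 10) {
    fit <- stats::lm(disp_raw[usable] ~ I(1 / base_mean[usable]))
    a0 <- max(stats::coef(fit)[1], 1e-4)
    a1 <- max(stats::coef(fit)[2], 0)
    a0 + a1 / base_mean
  } else {
    rep(max(mean(disp_raw[disp_raw > 0]), 0.01), length(disp_raw))
  }
  # asymmetric shrinkage: genes below the trend move halfway up to it, but
  # a raw dispersion above the trend is kept — shrinking it down understates
  # the Wald SE and inflates the extreme tail
  disp <- pmax(0.5 * disp_raw + 0.5 * trend, disp_raw)

  mu1 <- m1 + pseudo_mean
  mu0 <- m0 + pseudo_mean
  delta <- log(mu1) - log(mu0)
  # per-group variance: empirical, floored by the NB trend prediction so a
  # chance underestimate cannot inflate the statistic; delta-method on the
  # log scale, t reference to account for variance estimation noise
  v1f <- pmax(v1, mu1 + trend * mu1^2)
  v0f <- pmax(v0, mu0 + trend * mu0^2)
  se <- sqrt(v1f / (n1 * mu1^2) + v0f / (n0 * mu0^2))
  stat <- delta / se
  p <- 2 * stats::pt(-abs(stat), df = n1 + n0 - 2)
  out <- data.frame(gene = gene_names, base_mean = base_mean,
                    log2fc = delta / log(2), stat = stat, p = p,
                    padj = bh_adjust(p), dispersion = disp,
                    stringsAsFactors = FALSE)
  attr(out, "numerator") <- numerator
  attr(out, "denominator") <- denominator
  class(out) <- c("tam_de", "data.frame")
  out
}

# Median-of-ratios size factors with a positive-counts geometric mean
# reference, falling back to total-count scaling for degenerate cells.
size_factors <- function(m) {
  m <- as.matrix(m)
  logm <- log(m)
  logm[!is.finite(logm)] <- NA
  ref <- exp(rowMeans(logm, na.rm = TRUE))
  use <- is.finite(ref) & ref > 0 & rowMeans(m > 0) > 0.5
  if (sum(use) < 10) {
    tot <- colSums(m)
    return(tot / mean(tot))
  }
  sf <- apply(m[use, , drop = FALSE] / ref[use], 2, stats::median)
  bad <- !is.finite(sf) | sf <= 0
  if (any(bad)) {
    tot <- colSums(m)
    sf[bad] <- (tot / mean(tot))[bad]
  }
  sf / exp(mean(log(sf)))
}

#' Conditional co-expression fraction
#'
#' Fraction of cells detecting `gene_a` (CPM strictly above
#' `detect_threshold`) that also detect `gene_b`.
#'
#' @param expr a `tam_expr` on the `"cpm"` scale.
#' @param gene_a,gene_b gene symbols.
#' @param detect_threshold CPM detection cutoff.
#' @return A single proportion; `NA` with a warning when no cell expresses
#'   `gene_a`.
#' @export
coexpression_fraction <- function(expr, gene_a, gene_b, detect_threshold = 0) {
  stopifnot(inherits(expr, "tam_expr"))
  if (expr$scale != "cpm") stop("expr must be on the cpm scale")
  ia <- match(gene_a, expr$genes$symbol)
  ib <- match(gene_b, expr$genes$symbol)
  if (is.na(ia) || is.na(ib)) stop("both genes must be present in the matrix")
  a <- as.numeric(expr$values[ia, ]) > detect_threshold
  b <- as.numeric(expr$values[ib, ]) > detect_threshold
  if (!any(a)) {
    warning(sprintf("no cell expresses %s; fraction undefined", gene_a))
    return(NA_real_)
  }
  mean(b[a])
}

#' Detection co-occurrence odds ratios for gene pairs
#'
#' Per pair, detection (CPM strictly above `detect_threshold`) is binarized
#' into a 2x2 table `a` (both), `b` (first only), `c` (second only), `d`
#' (neither). The odds ratio is `(a d)/(b c)`, with the Haldane-Anscombe
#' +0.5 correction applied to all four cells when any is zero; p values come
#' from the two-sided Fisher's exact test and are BH-adjusted across pairs.
#'
#' @param expr a `tam_expr` on the `"cpm"` scale.
#' @param pairs two-column matrix or data frame of gene symbols.
#' @param detect_threshold CPM detection cutoff.
#' @return A `data.frame` (class `tam_or`) with per-pair counts, `or`, `p`,
#'   `padj`, `corrected` (Haldane flag) and the conditional co-expression
#'   fraction `frac_b_given_a`. Pairs with a missing gene are skipped with a
#'   warning.
#' @export
cooccurrence_odds_ratios <- function(expr, pairs, detect_threshold = 0) {
  stopifnot(inherits(expr, "tam_expr"))
  if (expr$scale != "cpm") stop("expr must be on the cpm scale")
  pairs <- as.matrix(pairs)
  if (nrow(pairs) == 0) stop("pairs must be non-empty")
  res <- vector("list", nrow(pairs))
  for (i in seq_len(nrow(pairs))) {
    ga <- pairs[i, 1]; gb <- pairs[i, 2]
    ia <- match(ga, expr$genes$symbol); ib <- match(gb, expr$genes$symbol)
    if (is.na(ia) || is.na(ib)) {
      warning(sprintf("pair (%s, %s) skipped: gene absent", ga, gb))
      next
    }
    da <- as.numeric(expr$values[ia, ]) > detect_threshold
    db <- as.numeric(expr$values[ib, ]) > detect_threshold
    a <- sum(da & db); b <- sum(da & !db); c <- sum(!da & db); d <- sum(!da & !db)
    corrected <- any(c(a, b, c, d) == 0)
    h <- if (corrected) 0.5 else 0
    or <- ((a + h) * (d + h)) / ((b + h) * (c + h))
    # fisher.test can return 1 + eps; clamp to the unit interval
    p <- min(1, stats::fisher.test(matrix(c(a, b, c, d), 2, byrow = TRUE))$p.value)
    res[[i]] <- data.frame(gene_a = ga, gene_b = gb, a = a, b = b, c = c, d = d,
                           or = or, p = p, corrected = corrected,
                           frac_b_given_a = if (a + b > 0) a / (a + b) else NA_real_,
                           stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, res)
  if (is.null(out)) stop("no valid pairs")
  out$padj <- bh_adjust(out$p)
  rownames(out) <- NULL
  class(out) <- c("tam_or", "data.frame")
  out
}

#' Benjamini-Hochberg adjustment
#'
#' Standard step-up adjustment with monotonicity enforcement, preserving the
#' input order.
#'
#' @param p numeric vector of p values in `[0, 1]`.
#' @return Adjusted p values in the input order.
#' @export
bh_adjust <- function(p) {
  if (any(!is.finite(p)) || any(p < 0 | p > 1)) stop("p values must be in [0, 1]")
  stats::p.adjust(p, method = "BH")
}
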