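# Shared fixture builders. All fixtures are generated in code at test time.

# A small cohort configuration that keeps unit tests fast while preserving
# the default statistical structure.
small_config <- function(seed = 1, ...) {
  args <- list(...)
  defaults <- list(n_samples = 4, n_cells_per_sample = 120, n_genes = 600,
                   n_candidate_genes = 80, n_true_signature = 24, seed = seed)
  do.call(sim_config, utils::modifyList(defaults, args))
}

# A hand-built counts container for exact-value tests.
tiny_counts <- function(m = NULL) {
  if (is.null(m)) {
    m <- matrix(c(1, 1, 2,
                  0, 5, 0,
                  3, 0, 0), nrow = 3, byrow = TRUE)
    m <- cbind(m, 0)  # an all-zero cell
  }
  ng <- nrow(m); nc <- ncol(m)
  genes <- data.frame(gene_id = sprintf("G%02d", seq_len(ng)),
                      symbol = sprintf("SYM%02d", seq_len(ng)),
                      chrom = "chr1",
                      start = (seq_len(ng) - 1) * 1e6,
                      end = (seq_len(ng) - 1) * 1e6 + 2e4)
  cells <- data.frame(cell_id = sprintf("c%02d", seq_len(nc)),
                      sample_id = "S01",
                      platform = rep(c("C1", "SS2"), length.out = nc))
  tam_counts(m, genes, cells)
}

# A synthetic signature for stages that consume one without deriving it.
toy_signature <- function(n = 20) {
  signature_gene_set(sprintf("SG%03d", seq_len(n)),
                     rep(c("blood", "microglia"), length.out = n),
                     loading = seq(0.9, 0.3, length.out = n) *
                       rep(c(1, -1), length.out = n))
}

# Exhaustive two-sided Fisher p by hypergeometric enumeration (independent
# oracle for the co-occurrence test). Matches the convention of summing all
# table probabilities not exceeding the observed one (with the customary
# 1 + 1e-7 relative tolerance).
fisher_p_enum <- function(a, b, c, d) {
  m <- a + c; n <- b + d; k <- a + b
  lo <- max(0, k - n); hi <- min(k, m)
  probs <- stats::dhyper(lo:hi, m, n, k)
  obs <- stats::dhyper(a, m, n, k)
  sum(probs[probs <= obs * (1 + 1e-7)])
}

# Brute-force BH step-up from the definition (oracle for bh_adjust).
bh_brute <- function(p) {
  m <- length(p)
  o <- order(p)
  ranked <- p[o] * m / seq_len(m)
  adj <- rev(cummin(rev(ranked)))
  pmin(1, adj)[order(o)]
}
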